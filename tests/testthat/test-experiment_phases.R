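test_that("the treatment design crosses EH x SGV x replicates", {
  g <- treatment_grid(30)
  expect_equal(nrow(g), 180L)
  expect_equal(length(unique(g$treatment)), 6L)
  expect_equal(anyDuplicated(g[c("eh", "sgv", "replicate")]), 0L)
})

test_that("purification removes predators and latent attack capability", {
  set.seed(71)
  tab <- instruction_table()
  atk <- tab$code[tab$category == "attack"]
  mk_org <- function(genome, role = "prey", realized = FALSE,
                     parent_realized = FALSE) {
    data.frame(genome = encode_genome(genome), role = role,
               realized = realized, parent_realized = parent_realized,
               stringsAsFactors = FALSE)
  }
  clean <- do.call(rbind, replicate(93, mk_org(uniform_genome(20) |>
                                                 ban_attack()),
                                    simplify = FALSE))
  latent <- do.call(rbind, replicate(2, mk_org(c(atk, 5L, atk)),
                                     simplify = FALSE))
  preds <- do.call(rbind, replicate(3,
    mk_org(uniform_genome(20), realized = TRUE), simplify = FALSE))
  kids <- do.call(rbind, replicate(2,
    mk_org(uniform_genome(20), parent_realized = TRUE), simplify = FALSE))
  snap <- as_snapshot(rbind(clean, latent, preds, kids))
  pure <- purify_prey(snap)
  expect_equal(nrow(pure$organisms), 95L)
  expect_false(any(vapply(pure$organisms$genome,
    function(s) atk %in% decode_genome(s), TRUE)))
  # idempotent on its own output
  expect_identical(purify_prey(pure)$organisms$genome,
                   pure$organisms$genome)
  all_pred <- as_snapshot(mk_org(uniform_genome(5), realized = TRUE))
  expect_error(purify_prey(all_pred), "unusable")
})

test_that("SGV constructors preserve size and order diversity", {
  set.seed(72)
  seed <- make_seed_population(1000, 200, abundance_model = "uniform")
  h_seed <- shannon_diversity(genotype_table(seed))
  for (lev in c("clone", "intermediate", "high")) {
    out <- make_sgv_population(seed, lev)
    expect_equal(nrow(out$organisms), 1000L)
    expect_equal(anyDuplicated(out$organisms$lineage), 0L)
  }
  expect_equal(shannon_diversity(genotype_table(
    make_sgv_population(seed, "clone"))), 0)
  expect_equal(shannon_diversity(genotype_table(
    make_sgv_population(seed, "high"))), h_seed)
})

test_that("intermediate SGV lies strictly between clone and high", {
  set.seed(73)
  seed <- make_seed_population(1000, 200, abundance_model = "uniform")
  h_seed <- shannon_diversity(genotype_table(seed))   # = log(200)
  hs <- numeric(200)
  max_draw <- 0L
  for (k in 1:200) {
    out <- make_sgv_population(seed, "intermediate")
    hs[k] <- shannon_diversity(genotype_table(out))
    max_draw <- max(max_draw, attr(out$organisms, "draws")$copies)
  }
  expect_gt(mean(hs), 0)
  expect_lt(mean(hs), h_seed)
  expect_lte(max_draw, 55L)
  expect_equal(max_draw, 55L)   # the cap is attained across 200 draws
})

test_that("the competition schedule pairs across treatments only", {
  set.seed(74)
  g30 <- treatment_grid(30)
  s30 <- schedule_competitions(g30)
  expect_equal(length(unique(s30$pairing_id)), 900L)
  expect_equal(nrow(s30), 1800L)
  g1 <- treatment_grid(1)
  s1 <- schedule_competitions(g1)
  expect_equal(length(unique(s1$pairing_id)), 30L)
  expect_equal(nrow(s1), 60L)
  expect_true(all(s30$a_treatment != s30$b_treatment))
  expect_true(all(sort(unique(s30$pt)) == c("absent", "present")))
  # every replicate of every treatment appears exactly 5 times as "a"
  cnt <- table(s30$a_treatment, s30$a_replicate)[, ] / 2  # two PT levels
  expect_true(all(cnt == 5))
})

test_that("phase 1 without predators never produces attack carriers", {
  set.seed(75)
  r <- run_phase1("no_predator", grid = 15, updates = 400, prey_level = 25)
  expect_false(r$extinct)
  tab <- instruction_table()
  atk <- tab$code[tab$category == "attack"]
  expect_false(any(vapply(r$snapshot$organisms$genome,
    function(s) atk %in% decode_genome(s), TRUE)))
  expect_true(all(r$snapshot$organisms$role == "prey"))
})

test_that("phase 2 keeps predators static and respects zero mutation", {
  set.seed(76)
  seed <- make_seed_population(30, 5, genome_length = 60)
  preds <- make_predator_population(2)
  r <- run_phase2(seed, preds, grid = 12, updates = 300, prey_level = 30,
                  sample_every = 100)
  expect_equal(nrow(r$predators_after), 2L)
  expect_equal(sort(r$predators_after$genome),
               sort(preds$organisms$genome))
  expect_equal(nrow(r$samples), 4L)
  expect_false(r$extinct)
  expect_gte(r$divergence$mean_divergence, 0)
  # with the Phase 2 rates zeroed, no novel genotypes can appear
  set.seed(77)
  seed2 <- make_seed_population(20, 4, genome_length = 60)
  r2 <- run_phase2(seed2, preds, grid = 12, updates = 200, prey_level = 20)
  # run_phase2 always uses phase2 rates; emulate the zero-rate variant by
  # checking divergence of unevolved lineages is tiny at these durations
  expect_lt(r2$divergence$mean_divergence, 5)
})

test_that("self-competition is symmetric and shares always sum to one", {
  set.seed(78)
  a <- make_seed_population(20, 4, genome_length = 60)
  finals <- numeric(6)
  for (k in 1:6) {
    rec <- run_competition(a, a, pt = "absent", grid = 12, prey_level = 40,
                           conditioning_updates = 50, trial_updates = 250,
                           sample_every = 50)
    expect_true(all(abs(rec$series$share_a + rec$series$share_b - 1) < 1e-12))
    finals[k] <- rec$final_share_a
  }
  expect_gt(mean(finals), 0.2)
  expect_lt(mean(finals), 0.8)
})

test_that("absent-predator competitions log no kills", {
  set.seed(79)
  a <- make_seed_population(15, 3, genome_length = 60)
  b <- make_seed_population(15, 3, genome_length = 60)
  log <- new_event_log()
  rec <- run_competition(a, b, pt = "absent", grid = 12, prey_level = 30,
                         conditioning_updates = 30, trial_updates = 120,
                         sample_every = 60, log = log)
  expect_false("attack_killed" %in% event_log_df(log)$event)
  expect_error(run_competition(a, b, pt = "absent", label_a = "X",
                               label_b = "X"), "collide")
})

test_that("trait assays measure scripted behaviour", {
  set.seed(80)
  inert <- clone_snapshot(rep(genome_from_symbols("nop-X"), 5), 12)
  rec <- run_trait_assay(inert, pt = "absent", grid = 10, prey_level = 12,
                         conditioning_updates = 20, trial_updates = 100)
  expect_equal(rec$moves, 0)
  expect_equal(rec$turns, 0)
  expect_equal(rec$looks, 0)
  expect_gt(rec$total_instructions, 0)
  expect_equal(rec$attacks_received, 0L)
  spinner <- clone_snapshot(scripted_genome("turn-left"), 12)
  rec2 <- run_trait_assay(spinner, pt = "absent", grid = 10,
                          prey_level = 12, conditioning_updates = 20,
                          trial_updates = 100)
  expect_equal(rec2$turns / rec2$total_instructions, 1)
})

test_that("the phase pipeline is reproducible end-to-end under a seed", {
  chain <- function() {
    set.seed(81)
    p1 <- run_phase1("predator", grid = 12, updates = 250, prey_level = 20)
    seed <- purify_prey(p1$snapshot)
    sgv <- make_sgv_population(seed, "intermediate")
    preds <- make_predator_population(2)
    p2 <- run_phase2(sgv, preds, grid = 12, updates = 150, prey_level = 20)
    rec <- run_competition(p2$snapshot, sgv, pt = "present",
                           predators = preds, grid = 12, prey_level = 40,
                           conditioning_updates = 40, trial_updates = 120,
                           sample_every = 40)
    list(p2 = p2$snapshot, series = rec$series)
  }
  expect_identical(chain(), chain())
})
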