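nopx <- function(n) rep(genome_from_symbols("nop-X"), n)

test_that("a pure-inert genome burns the full budget on noops", {
  s <- lone_organism(nopx(10))
  ev <- execute_update(s$pop, s$i, s$world, s$cfg, collect = TRUE)
  expect_equal(nrow(ev), 30L)
  expect_true(all(ev$kind == "noop"))
  expect_equal(sum(ev$cost), 30L)
  expect_equal(s$pop$total_instr[s$i], 30L)
  expect_equal(s$pop$cnt_moves[s$i] + s$pop$cnt_turns[s$i] +
                 s$pop$cnt_looks[s$i], 0L)
})

test_that("eat then eligible repro charge 1 + 30 cycles", {
  set.seed(41)
  g <- scripted_genome(c("eat", "repro"), pad_to = 2)
  cfg <- sim_config(rates = mutation_rates())
  s <- lone_organism(g, cfg)
  # make the organism eligible: enough resources, old enough
  s$pop$resources[s$i] <- 10
  s$pop$clock <- 200L
  s$pop$reset_update[s$i] <- 0L
  ev <- execute_update(s$pop, s$i, s$world, s$cfg, collect = TRUE)
  expect_equal(ev$kind[1:2], c("ate", "birth_requested"))
  expect_equal(ev$cost[1:2], c(1L, 30L))
  # repro consumed the remaining budget; the 1-cycle overrun is debt
  expect_equal(nrow(ev), 2L)
  expect_equal(s$pop$debt[s$i], 1L)
  expect_equal(s$pop$n, 2L)                       # offspring exists
  expect_equal(s$pop$lineage[2], s$pop$lineage[s$i])
  expect_equal(s$pop$generation[2], 1L)
  # parent reborn: tally and pointer reset, lifetime counters kept
  expect_equal(s$pop$resources[s$i], 0)
  expect_equal(s$pop$ip[s$i], 1L)
  expect_equal(s$pop$cnt_eats[s$i], 1L)
})

test_that("reproduction eligibility boundaries", {
  cfg <- sim_config()
  s <- lone_organism(nopx(5), cfg)
  set_state <- function(res, age) {
    s$pop$resources[s$i] <- res
    s$pop$clock <- age
    s$pop$reset_update[s$i] <- 0L
  }
  set_state(10, 100); expect_true(reproduction_eligible(s$pop, s$i, cfg))
  set_state(9.99, 500); expect_false(reproduction_eligible(s$pop, s$i, cfg))
  set_state(10, 99); expect_false(reproduction_eligible(s$pop, s$i, cfg))
})

test_that("prey bite one unit; predators cannot consume resources", {
  g <- scripted_genome("eat", pad_to = 1)
  s <- lone_organism(g)
  ev <- execute_update(s$pop, s$i, s$world, s$cfg, collect = TRUE)
  expect_equal(ev$kind[1], "ate")
  # first bite took the only unit; later bites in the same update find none
  expect_equal(s$pop$resources[s$i], 1)
  p <- lone_organism(g, role = "predator")
  evp <- execute_update(p$pop, p$i, p$world, p$cfg, collect = TRUE)
  expect_true(all(evp$kind == "noop"))
  expect_equal(p$pop$resources[p$i], 0)
  expect_equal(p$world$resource[6, 6], 1L)        # cell untouched
})

attack_scene <- function(n_prey_extra, min_prey, victim_res = 8) {
  # predator at (5,5) facing E with a prey in the faced cell, plus
  # n_prey_extra background prey elsewhere
  cfg <- sim_config(min_prey = min_prey, rates = mutation_rates())
  world <- new_world(40, 40)
  pop <- new_population()
  pred <- add_organism(pop, scripted_genome("attack", pad_to = 1),
                       x = 5, y = 5, facing = 3, role = "predator",
                       lineage = "P")
  vic <- add_organism(pop, nopx(3), x = 6, y = 5, lineage = "V")
  pop$resources[vic] <- victim_res
  for (k in seq_len(n_prey_extra))
    add_organism(pop, nopx(3), x = 10 + k %% 20, y = 10 + k %/% 20,
                 lineage = "B")
  list(pop = pop, world = world, cfg = cfg, pred = pred, vic = vic)
}

test_that("attacks are fatal only above the minimum-prey threshold", {
  set.seed(42)
  # 1,001 prey with threshold 1,000: fatal, 10 cycles, 10% credit
  s <- attack_scene(1000, min_prey = 1000)
  ev <- execute_update(s$pop, s$pred, s$world, s$cfg, collect = TRUE)
  expect_equal(ev$kind[1], "attack_killed")
  expect_equal(ev$cost[1], 10L)
  expect_false(s$pop$alive[s$vic])
  expect_equal(s$pop$resources[s$pred], 0.8)
  # exactly at the threshold: protected, 1 cycle, victim untouched
  s2 <- attack_scene(999, min_prey = 1000)
  ev2 <- execute_update(s2$pop, s2$pred, s2$world, s2$cfg, collect = TRUE)
  expect_equal(ev2$kind[1], "attack_failed")
  expect_equal(ev2$cost[1], 1L)
  expect_true(s2$pop$alive[s2$vic])
  # failed strikes cost 1 cycle each, so the predator attacks repeatedly
  expect_equal(s2$pop$attacks_received[s2$vic], 30L)
})

test_that("an empty faced cell means a failed attack", {
  cfg <- sim_config(min_prey = 0, rates = mutation_rates())
  world <- new_world(10, 10)
  pop <- new_population()
  pred <- add_organism(pop, scripted_genome("attack", pad_to = 1),
                       x = 5, y = 5, facing = 3, role = "predator",
                       lineage = "P")
  ev <- execute_update(pop, pred, world, cfg, collect = TRUE)
  expect_true(all(ev$kind == "attack_failed"))
})

test_that("executing attack realizes a prey as predator, monotonically", {
  cfg <- sim_config(min_prey = 0, rates = mutation_rates(),
                    prey_attack_execution = TRUE)
  world <- new_world(10, 10)
  pop <- new_population()
  i <- add_organism(pop, scripted_genome("attack", pad_to = 1),
                    x = 2, y = 2, facing = 1, lineage = "A")
  expect_equal(pop$n_prey, 1L)
  execute_update(pop, i, world, cfg)
  expect_true(pop$realized[i])
  expect_equal(pop$n_prey, 0L)                    # no longer counted as prey
  # in attack-banned runs the symbol is inert and nothing is realized
  cfg2 <- sim_config(min_prey = 0, rates = mutation_rates(),
                     prey_attack_execution = FALSE)
  pop2 <- new_population()
  j <- add_organism(pop2, scripted_genome("attack", pad_to = 1),
                    x = 2, y = 2, facing = 1, lineage = "A")
  ev <- execute_update(pop2, j, world, cfg2, collect = TRUE)
  expect_true(all(ev$kind == "noop"))
  expect_false(pop2$realized[j])
})

test_that("conditionals skip the next instruction when false", {
  # if-prey-seen with an empty sensor skips the move
  g <- scripted_genome(c("look", "if-prey-seen", "move"), pad_to = 3)
  s <- lone_organism(g)
  execute_update(s$pop, s$i, s$world, s$cfg)
  expect_equal(s$pop$cnt_moves[s$i], 0L)
  # skipping the move leaves a look/conditional 2-cycle loop
  expect_equal(s$pop$cnt_looks[s$i], 15L)
  # with a prey in the cone the move executes
  s2 <- lone_organism(g)
  add_organism(s2$pop, nopx(1), x = 7, y = 5, lineage = "T")
  execute_update(s2$pop, s2$i, s2$world, s2$cfg)
  expect_gt(s2$pop$cnt_moves[s2$i], 0L)
})

test_that("movement is refused at the grid boundary but costs the cycle", {
  g <- scripted_genome("move", pad_to = 1)
  s <- lone_organism(g, grid = 5, x = 4, y = 2, facing = 3)  # facing E wall
  ev <- execute_update(s$pop, s$i, s$world, s$cfg, collect = TRUE)
  expect_true(all(ev$kind == "move_blocked"))
  expect_equal(s$pop$x[s$i], 4L)
  expect_equal(s$pop$cnt_moves[s$i], 30L)
})

test_that("cycle accounting: per-event costs sum to the budget (with debt)", {
  set.seed(43)
  for (k in 1:10) {
    g <- c(scripted_genome(sample(c("move", "turn-left", "eat", "look"),
                                  6, replace = TRUE)), nopx(4))
    s <- lone_organism(g)
    ev <- execute_update(s$pop, s$i, s$world, s$cfg, collect = TRUE)
    expect_equal(sum(ev$cost) - s$pop$debt[s$i], 30L)
  }
})

test_that("category counters sum to total instructions executed", {
  set.seed(44)
  g <- c(scripted_genome(c("move", "turn-right", "look", "eat")), nopx(3))
  s <- lone_organism(g)
  for (k in 1:5) execute_update(s$pop, s$i, s$world, s$cfg)
  p <- s$pop; i <- s$i
  # 150 instructions walk the 7-instruction loop deterministically:
  # 21 full loops plus positions 1..3
  expect_equal(p$total_instr[i], 150L)
  expect_equal(p$cnt_moves[i], 22L)
  expect_equal(p$cnt_turns[i], 22L)
  expect_equal(p$cnt_looks[i], 22L)
  expect_equal(p$cnt_eats[i], 21L)
  behavioral <- p$cnt_moves[i] + p$cnt_turns[i] + p$cnt_looks[i] +
    p$cnt_eats[i] + p$cnt_repros[i] + p$cnt_attacks[i]
  expect_equal(behavioral, 87L)
})
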