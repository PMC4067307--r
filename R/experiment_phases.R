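# The three-phase experimental design:
#   Phase 1 - open-ended evolution of base populations with (predator EH) or
#             without (no-predator EH) the possibility of predation;
#   Phase 2 - prey purification, standing-genetic-variation construction
#             (clone / intermediate / high), and evolution against a static
#             predator population;
#   Phase 3 - mutation-free pairwise competitions and trait assays against a
#             novel predator, under both predator-present and -absent
#             treatments.

#' Experiment profile: phase-level run parameters
#'
#' The `paper` profile is the full-scale design (251x251 grid, 2,000,000
#' Phase 1 updates, 200,000 Phase 2 updates, prey levels 1,000/2,000, 30
#' replicates per treatment). The `desk` profile scales the grid to 60x60,
#' Phase 1 to 50,000 and Phase 2 to 20,000 updates, and divides prey levels
#' by 10, so the full pipeline runs on a single workstation while keeping
#' every rule of the model intact.
#'
#' @param profile `"desk"` or `"paper"`.
#' @return A named list of phase parameters.
#' @export
experiment_profile <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    list(grid = 251L, phase1_updates = 2000000L, phase2_updates = 200000L,
         prey_level = 1000L, competition_level = 2000L,
         assay_level = 1000L, replicates = 30L,
         conditioning_updates = 1000L, trial_updates = 10000L,
         sample_every = 1000L)
  } else {
    list(grid = 60L, phase1_updates = 50000L, phase2_updates = 20000L,
         prey_level = 100L, competition_level = 200L,
         assay_level = 100L, replicates = 5L,
         conditioning_updates = 1000L, trial_updates = 10000L,
         sample_every = 1000L)
  }
}

#' The full treatment design
#'
#' Crosses evolutionary history (predator / no-predator), standing genetic
#' variation (clone / intermediate / high) and replicate index: at 30
#' replicates this is the 2 x 3 x 30 = 180-population design.
#'
#' @param replicates Replicates per treatment.
#' @return A data.frame with columns `eh`, `sgv`, `replicate` and a
#'   `treatment` label `eh:sgv`.
#' @export
treatment_grid <- function(replicates = 30L) {
  g <- expand.grid(replicate = seq_len(replicates),
                   sgv = c("clone", "intermediate", "high"),
                   eh = c("predator", "no_predator"),
                   stringsAsFactors = FALSE)
  g <- g[, c("eh", "sgv", "replicate")]
  g$treatment <- paste(g$eh, g$sgv, sep = ":")
  g
}

#' Phase 1: open-ended evolution of a base population
#'
#' Seeds nine copies of the hand-written blind-forager ancestor in the
#' centre region of a fresh grid and evolves the population at the high
#' Phase 1 mutation rates (substitution 0.25, insertion and deletion 0.05
#' per reproduction; at most one substitution and one indel event each). In
#' the predator evolutionary history the attack instruction may mutate into
#' genomes and be executed, so predators can arise; in the no-predator
#' history it is excluded from the mutational alphabet and never executes.
#'
#' @param eh `"predator"` or `"no_predator"`.
#' @param grid Grid side length in cells.
#' @param updates Number of updates to run.
#' @param prey_level Population cap and attack-protection threshold.
#' @param sample_every Time-series sampling interval (NULL for none).
#' @param log Optional event log.
#' @return A list with `snapshot` (final population), `samples`
#'   (time series), `extinct` flag and the `cfg` used.
#' @export
run_phase1 <- function(eh = c("predator", "no_predator"), grid = 60L,
                       updates = 50000L, prey_level = 100L,
                       sample_every = NULL, log = NULL) {
  eh <- match.arg(eh)
  allow <- eh == "predator"
  cfg <- sim_config(rates = phase1_rates(attack_allowed = allow),
                    min_prey = prey_level, prey_cap = prey_level,
                    prey_attack_execution = allow)
  world <- new_world(grid, grid)
  pop <- new_population()
  cx <- grid %/% 2L
  anc <- ancestor_genome()
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    add_organism(pop, anc, x = cx + dx, y = cx + dy,
                 facing = ((k - 1L) %% 8L) + 1L,
                 lineage = as.character(k))
  }
  samples <- run_updates(pop, world, cfg, updates,
                         sample_every = sample_every, log = log)
  snap <- snapshot(pop)
  list(snapshot = snap, samples = samples,
       extinct = nrow(snap$organisms) == 0L, cfg = cfg)
}

#' Purify a snapshot into a prey-only seed population
#'
#' Drops every organism classified as a predator (it executed an attack) or
#' whose parent was a predator, then replaces any latent attack instructions
#' in the survivors' genomes with the inert `nop-X`. The result contains
#' prey only with zero attack symbols; applying the operation twice changes
#' nothing.
#'
#' @param snap A `pop_snapshot`.
#' @return A purified `pop_snapshot`.
#' @export
purify_prey <- function(snap) {
  org <- snap$organisms
  keep <- org$role == "prey" & !org$realized & !org$parent_realized
  org <- org[keep, , drop = FALSE]
  if (nrow(org) == 0L)
    stop("purification removed every organism; seed population unusable")
  org$genome <- vapply(org$genome, function(s)
    encode_genome(ban_attack(decode_genome(s))), "")
  org$genotype <- org$genome
  rownames(org) <- NULL
  structure(list(organisms = org, clock = snap$clock),
            class = "pop_snapshot")
}

#' Construct a standing-genetic-variation treatment population
#'
#' All three constructions preserve the seed population's size exactly and
#' assign every organism a fresh unique lineage id:
#' \describe{
#'   \item{clone}{one genotype, sampled abundance-weighted (a random
#'     organism's genotype), duplicated to the seed size;}
#'   \item{intermediate}{repeated draws of a genotype (abundance-weighted,
#'     with replacement), each emitted as `1..max_copies` identical copies
#'     (uniform draw), the final draw truncated to hit the seed size
#'     exactly;}
#'   \item{high}{a verbatim duplicate of the seed population.}
#' }
#'
#' @param seed A prey-only `pop_snapshot`.
#' @param level `"clone"`, `"intermediate"` or `"high"`.
#' @param max_copies Per-draw copy maximum for the intermediate level
#'   (default 55).
#' @param clone_sampling `"organism"` (abundance-weighted, default) or
#'   `"genotype"` (uniform over distinct genotypes).
#' @param lineage_prefix Prefix for the fresh lineage ids.
#' @return A `pop_snapshot` of the same size as `seed`. For the
#'   intermediate level the organism table carries a `draws` attribute
#'   recording each sampling draw (organism picked, copies emitted).
#' @export
make_sgv_population <- function(seed, level = c("clone", "intermediate",
                                                "high"),
                                max_copies = 55L,
                                clone_sampling = c("organism", "genotype"),
                                lineage_prefix = "S") {
  level <- match.arg(level)
  clone_sampling <- match.arg(clone_sampling)
  org <- seed$organisms
  n <- nrow(org)
  stopifnot(n >= 1)
  out <- switch(level,
    high = org,
    clone = {
      g <- if (clone_sampling == "organism")
        org$genome[sample.int(n, 1L)]
      else sample(unique(org$genome), 1L)
      tmpl <- org[match(g, org$genome), , drop = FALSE]
      tmpl[rep(1L, n), , drop = FALSE]
    },
    intermediate = {
      rows <- integer(0)
      draws <- list()
      while (length(rows) < n) {
        pick <- sample.int(n, 1L)            # abundance-weighted via organisms
        copies <- sample.int(max_copies, 1L)
        copies <- min(copies, n - length(rows))
        draws[[length(draws) + 1L]] <- c(pick = pick, copies = copies)
        rows <- c(rows, rep(pick, copies))
      }
      out <- org[rows, , drop = FALSE]
      attr(out, "draws") <- as.data.frame(do.call(rbind, draws))
      out
    })
  out$lineage <- paste0(lineage_prefix, seq_len(nrow(out)))
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(list(organisms = out, clock = 0L), class = "pop_snapshot")
}

#' Phase 2: evolution of prey against a static predator population
#'
#' Injects the constructed prey population and an immortal, sterile copy of
#' the predator population into a fresh grid and evolves the prey at the low
#' Phase 2 mutation rates (substitution 0.001, insertion/deletion 0.005 per
#' reproduction) with the attack instruction banned. Predators never die,
#' reproduce or mutate: on reaching a lifespan cap they reset in place, so
#' predation pressure is constant across replicates. Shannon diversity of
#' the prey genotype table is sampled along the run and each final organism
#' is aligned to its lineage ancestor for the divergence table.
#'
#' @param prey A prey-only `pop_snapshot` (lineage ids identify ancestors).
#' @param predators A predator `pop_snapshot` fixture.
#' @param grid,updates,prey_level,sample_every Run geometry and duration.
#' @param log Optional event log.
#' @return A list with `snapshot`, `samples` (update, n_prey, n_predators,
#'   shannon_H, mean_generation), `divergence` (see [lineage_divergence()]),
#'   `extinct`, and `cfg`.
#' @export
run_phase2 <- function(prey, predators, grid = 60L, updates = 20000L,
                       prey_level = 100L, sample_every = 1000L, log = NULL) {
  cfg <- sim_config(rates = phase2_rates(attack_allowed = FALSE),
                    min_prey = prey_level, prey_cap = prey_level,
                    static_predators = TRUE,
                    prey_attack_execution = FALSE)
  world <- new_world(grid, grid)
  pop <- new_population()
  inject(pop, world, predators, placement = "random", role = "predator",
         static = TRUE)
  inject(pop, world, prey, placement = "random", role = "prey")
  samples <- run_updates(pop, world, cfg, updates,
                         sample_every = sample_every, log = log)
  snap <- snapshot(pop)
  finals <- snap$organisms[snap$organisms$role == "prey", , drop = FALSE]
  final_snap <- structure(list(organisms = finals, clock = snap$clock),
                          class = "pop_snapshot")
  div <- if (nrow(finals) > 0L) lineage_divergence(final_snap, prey)
         else NULL
  list(snapshot = final_snap, samples = samples, divergence = div,
       extinct = nrow(finals) == 0L, cfg = cfg,
       predators_after = snap$organisms[
         snap$organisms$role == "predator", , drop = FALSE])
}

#' Phase 3 competition schedule
#'
#' Pairs each replicate of each treatment with one uniformly chosen
#' replicate from each of the five other treatments (5 pairings per
#' replicate, 6R replicates, i.e. 30R pairings; 900 at R = 30), and emits
#' every pairing under both predator-treatment levels (present / absent),
#' i.e. 2 trials per pairing.
#'
#' @param populations A data.frame with columns `treatment` and `replicate`
#'   (e.g. [treatment_grid()]).
#' @return A data.frame of trials: `a_treatment`, `a_replicate`,
#'   `b_treatment`, `b_replicate`, `pt` (`"present"`/`"absent"`),
#'   `pairing_id`.
#' @export
schedule_competitions <- function(populations) {
  tr <- unique(populations$treatment)
  if (length(tr) < 2L) stop("need at least two treatments")
  reps <- split(populations$replicate, populations$treatment)
  if (any(vapply(reps, length, 0L) < 1L))
    stop("every treatment needs at least one replicate")
  rows <- list()
  for (k in seq_len(nrow(populations))) {
    a_tr <- populations$treatment[k]
    a_rep <- populations$replicate[k]
    for (b_tr in setdiff(tr, a_tr)) {
      cand <- reps[[b_tr]]
      b_rep <- cand[sample.int(length(cand), 1L)]
      rows[[length(rows) + 1L]] <- data.frame(
        a_treatment = a_tr, a_replicate = a_rep,
        b_treatment = b_tr, b_replicate = b_rep,
        stringsAsFactors = FALSE)
    }
  }
  pairings <- do.call(rbind, rows)
  pairings$pairing_id <- seq_len(nrow(pairings))
  out <- rbind(transform(pairings, pt = "present"),
               transform(pairings, pt = "absent"))
  out <- out[order(out$pairing_id, out$pt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

clear_prey <- function(pop) {
  ns <- seq_len(pop$n)
  prey <- which(pop$alive[ns] & pop$role[ns] == 1L)
  pop$alive[prey] <- FALSE
  pop$n_prey <- 0L
  invisible(pop)
}

competitor_counts <- function(pop) {
  ns <- seq_len(pop$n)
  idx <- which(pop$alive[ns] & pop$role[ns] == 1L & !pop$realized[ns])
  c(a = sum(pop$group[idx] == "A", na.rm = TRUE),
    b = sum(pop$group[idx] == "B", na.rm = TRUE))
}

#' Phase 3: pairwise competition under the double-injection protocol
#'
#' Mutation-free competition between two prey populations. Both populations
#' are injected at random positions and run for a conditioning period so
#' that the resource landscape is partially consumed (a fresh grid would be
#' uniformly full); the prey are then discarded and fresh copies of both
#' populations reinjected into the conditioned landscape for the scored
#' trial. The prey level is enforced as both the population cap and the
#' attack-protection threshold, and the relative abundance of the two
#' competitors is recorded at fixed intervals.
#'
#' @param a,b Prey `pop_snapshot`s with distinct labels.
#' @param label_a,label_b Competitor labels for the output.
#' @param pt `"present"` or `"absent"`: whether the predator population is
#'   injected (static) into the arena.
#' @param predators Predator `pop_snapshot` (used when `pt = "present"`).
#' @param grid Grid side length.
#' @param prey_level Enforced prey level (cap and protection threshold).
#' @param conditioning_updates,trial_updates Durations of the two stages.
#' @param sample_every Relative-abundance sampling interval.
#' @param log Optional event log.
#' @return A list of class `competition_record`: `series` (update, n_a, n_b,
#'   share_a, share_b), `final_share_a`, labels and `pt`.
#' @export
run_competition <- function(a, b, pt = c("present", "absent"),
                            predators = NULL,
                            label_a = "A", label_b = "B",
                            grid = 60L, prey_level = 200L,
                            conditioning_updates = 1000L,
                            trial_updates = 10000L,
                            sample_every = 1000L, log = NULL) {
  pt <- match.arg(pt)
  if (identical(label_a, label_b)) stop("competitor labels collide")
  cfg <- sim_config(rates = mutation_rates(0, 0, 0),
                    min_prey = prey_level, prey_cap = prey_level,
                    static_predators = TRUE,
                    prey_attack_execution = FALSE)
  world <- new_world(grid, grid)
  pop <- new_population()
  if (pt == "present") {
    if (is.null(predators)) stop("pt = present requires predators")
    inject(pop, world, predators, role = "predator", static = TRUE)
  }
  inject_pair <- function() {
    inject(pop, world, a, role = "prey", fresh_lineages = TRUE,
           lineage_prefix = "A", group = "A")
    inject(pop, world, b, role = "prey", fresh_lineages = TRUE,
           lineage_prefix = "B", group = "B")
  }
  inject_pair()
  run_updates(pop, world, cfg, conditioning_updates, log = log)
  clear_prey(pop)
  inject_pair()
  series <- list()
  take <- function() {
    cnt <- competitor_counts(pop)
    tot <- sum(cnt)
    data.frame(update = pop$clock - conditioning_updates,
               n_a = cnt[["a"]], n_b = cnt[["b"]],
               share_a = if (tot > 0) cnt[["a"]] / tot else NA_real_,
               share_b = if (tot > 0) cnt[["b"]] / tot else NA_real_)
  }
  series[[1L]] <- take()
  for (t in seq_len(trial_updates)) {
    step(pop, world, cfg, log = log)
    if ((pop$clock - conditioning_updates) %% sample_every == 0L)
      series[[length(series) + 1L]] <- take()
  }
  series <- do.call(rbind, series)
  rownames(series) <- NULL
  structure(list(series = series,
                 final_share_a = series$share_a[nrow(series)],
                 label_a = label_a, label_b = label_b, pt = pt),
            class = "competition_record")
}

#' Phase 3: trait assay of a prey population
#'
#' Mutation-free double-injection run of a single prey population, with the
#' prey count held at `prey_level` via the population cap and the
#' attack-protection threshold. Reports per-prey means of lifetime
#' instruction-category counts (moves, turns, looks, total) over the prey
#' alive at the end of the trial, plus the total number of attacks directed
#' at members of the population (fatal or protected).
#'
#' @param prey A prey `pop_snapshot`.
#' @param population Label recorded in the output.
#' @param stage `"pre_phase2"` or `"post_phase2"`.
#' @inheritParams run_competition
#' @return A list of class `trait_assay_record` with fields `population`,
#'   `pt`, `stage`, `moves`, `turns`, `looks`, `total_instructions`,
#'   `attacks_received`, `n_prey_final`.
#' @export
run_trait_assay <- function(prey, pt = c("present", "absent"),
                            predators = NULL, population = "pop",
                            stage = c("post_phase2", "pre_phase2"),
                            grid = 60L, prey_level = 100L,
                            conditioning_updates = 1000L,
                            trial_updates = 10000L, log = NULL) {
  pt <- match.arg(pt); stage <- match.arg(stage)
  cfg <- sim_config(rates = mutation_rates(0, 0, 0),
                    min_prey = prey_level, prey_cap = prey_level,
                    static_predators = TRUE,
                    prey_attack_execution = FALSE)
  world <- new_world(grid, grid)
  pop <- new_population()
  if (pt == "present") {
    if (is.null(predators)) stop("pt = present requires predators")
    inject(pop, world, predators, role = "predator", static = TRUE)
  }
  inject(pop, world, prey, role = "prey", fresh_lineages = TRUE,
         group = "F")
  run_updates(pop, world, cfg, conditioning_updates, log = log)
  clear_prey(pop)
  attacks_before <- sum(pop$attacks_received[seq_len(pop$n)])
  inject(pop, world, prey, role = "prey", fresh_lineages = TRUE,
         group = "F")
  run_updates(pop, world, cfg, trial_updates, log = log)
  ns <- seq_len(pop$n)
  idx <- which(pop$alive[ns] & pop$role[ns] == 1L)
  prey_slots <- which(pop$role[ns] == 1L & pop$group[ns] %in% "F")
  # attacks on the conditioning cohort are not part of the scored trial
  attacks <- sum(pop$attacks_received[prey_slots]) - attacks_before
  structure(list(
    population = population, pt = pt, stage = stage,
    moves = mean(pop$cnt_moves[idx]),
    turns = mean(pop$cnt_turns[idx]),
    looks = mean(pop$cnt_looks[idx]),
    total_instructions = mean(pop$total_instr[idx]),
    attacks_received = attacks,
    n_prey_final = length(idx)
  ), class = "trait_assay_record")
}
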