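# The update loop: scheduling, births with mutation, deaths, caps,
# minimum-prey protection, static-predator resets, and logging.

#' Simulation configuration
#'
#' Collects every world/organism/predation constant of the model. Defaults
#' are the full-scale values: 30 instruction cycles per update, a 500-update
#' / 15,000-instruction lifespan, reproduction after 10 consumed units and
#' 100 updates, 100-update resource regeneration, 10-cycle successful-attack
#' handling time, a 10% transfer of the victim's resource tally to the
#' attacker, a 1,000-prey attack-protection threshold and a 1,000-prey
#' population cap.
#'
#' @param cycles_per_update Instruction cycles per organism per update.
#' @param max_age_updates Lifespan cap in updates.
#' @param max_instr Lifespan cap in instructions executed.
#' @param repro_resource_threshold Resource units required to reproduce.
#' @param repro_min_age_updates Minimum updates since last rebirth.
#' @param regen_delay Updates until a consumed cell replenishes.
#' @param attack_cost_cycles Handling time of a successful attack.
#' @param predator_gain_fraction Fraction of the victim's tally credited.
#' @param min_prey Attack-protection threshold: attacks are fatal only while
#'   the living prey count exceeds this.
#' @param prey_cap Maximum prey population (enforced at the end of each
#'   update by uniform random removal), or `Inf` for none.
#' @param rates A [mutation_rates()] object.
#' @param static_predators If `TRUE`, injected predators are immortal and
#'   sterile: on reaching a lifespan cap they reset in place instead of
#'   dying.
#' @param prey_attack_execution If `FALSE`, an attack symbol in a prey
#'   genome behaves as a no-op (attack-banned runs).
#' @param view_range Maximum look distance in cells.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(cycles_per_update = 30L,
                       max_age_updates = 500L,
                       max_instr = 15000L,
                       repro_resource_threshold = 10,
                       repro_min_age_updates = 100L,
                       regen_delay = 100L,
                       attack_cost_cycles = 10L,
                       predator_gain_fraction = 0.10,
                       min_prey = 1000L,
                       prey_cap = 1000L,
                       rates = mutation_rates(),
                       static_predators = FALSE,
                       prey_attack_execution = TRUE,
                       view_range = 20L) {
  stopifnot(cycles_per_update >= 1, max_age_updates >= 1, max_instr >= 1,
            repro_min_age_updates >= 0, regen_delay >= 1,
            attack_cost_cycles >= 1, min_prey >= 0,
            predator_gain_fraction >= 0, predator_gain_fraction <= 1,
            inherits(rates, "mutation_rates"))
  structure(list(
    cycles_per_update = as.integer(cycles_per_update),
    max_age_updates = as.integer(max_age_updates),
    max_instr = as.integer(max_instr),
    repro_resource_threshold = repro_resource_threshold,
    repro_min_age_updates = as.integer(repro_min_age_updates),
    regen_delay = as.integer(regen_delay),
    attack_cost_cycles = as.integer(attack_cost_cycles),
    predator_gain_fraction = predator_gain_fraction,
    min_prey = as.integer(min_prey),
    prey_cap = prey_cap,
    rates = rates,
    static_predators = isTRUE(static_predators),
    prey_attack_execution = isTRUE(prey_attack_execution),
    view_range = as.integer(view_range)
  ), class = "sim_config")
}

#' Event log
#'
#' A growable log of discrete demographic events (births, deaths, kills,
#' cap removals, static resets), written out as CSV with [write_event_log()].
#'
#' @return An environment of class `event_log`.
#' @export
new_event_log <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$update <- integer(0); e$id <- integer(0)
  e$event <- character(0); e$detail <- integer(0)
  class(e) <- "event_log"
  e
}

log_event <- function(log, update, id, event, detail = NA_integer_) {
  n <- log$n + 1L
  if (n > length(log$update)) {
    newcap <- max(1024L, 2L * length(log$update))
    log$update <- c(log$update, integer(newcap - length(log$update)))
    log$id <- c(log$id, integer(newcap - length(log$id)))
    log$event <- c(log$event, character(newcap - length(log$event)))
    log$detail <- c(log$detail, integer(newcap - length(log$detail)))
  }
  log$update[n] <- update; log$id[n] <- id
  log$event[n] <- event; log$detail[n] <- detail
  log$n <- n
  invisible(log)
}

#' @rdname new_event_log
#' @param log An event log.
#' @return `event_log_df` returns the log as a data.frame.
#' @export
event_log_df <- function(log) {
  k <- seq_len(log$n)
  data.frame(update = log$update[k], organism_id = log$id[k],
             event = log$event[k], detail = log$detail[k],
             stringsAsFactors = FALSE)
}

living <- function(pop) which(pop$alive[seq_len(pop$n)])

#' Advance the simulation by one update
#'
#' One update: (1) every living organism executes its cycle budget, in a
#' fresh seeded random order (births and kills take effect immediately, so
#' the prey count may transiently exceed the cap within the update);
#' (2) ages advance; organisms at the lifespan caps die, except static
#' organisms, which reset in place; (3) the prey cap is enforced by uniform
#' random removal; (4) resource regeneration ticks; (5) the clock advances.
#'
#' @param pop,world Population and grid (modified in place).
#' @param cfg A [sim_config()].
#' @param log Optional [new_event_log()].
#' @return The population, invisibly.
#' @export
step <- function(pop, world, cfg, log = NULL) {
  idx <- living(pop)
  if (length(idx) > 1L) idx <- idx[sample.int(length(idx))]
  for (i in idx) {
    if (pop$alive[i]) execute_update(pop, i, world, cfg, log = log)
  }
  # aging and lifespan deaths / static resets
  idx <- living(pop)
  pop$age[idx] <- pop$age[idx] + 1L
  capped <- idx[pop$age[idx] >= cfg$max_age_updates |
                pop$total_instr[idx] >= cfg$max_instr]
  for (i in capped) {
    if (pop$static[i]) {
      pop$age[i] <- 0L; pop$total_instr[i] <- 0L
      pop$ip[i] <- 1L; pop$debt[i] <- 0L
      pop$resources[i] <- 0
      pop$sensor_prey[i] <- pop$sensor_pred[i] <- FALSE
      pop$reset_update[i] <- pop$clock
      if (!is.null(log)) log_event(log, pop$clock, pop$id[i], "reset_static")
    } else {
      pop$alive[i] <- FALSE
      if (pop$role[i] == 1L && !pop$realized[i])
        pop$n_prey <- pop$n_prey - 1L
      if (!is.null(log)) log_event(log, pop$clock, pop$id[i], "death_lifespan")
    }
  }
  # prey cap by uniform random removal
  if (is.finite(cfg$prey_cap)) {
    while (pop$n_prey > cfg$prey_cap) {
      ns <- seq_len(pop$n)
      prey <- which(pop$alive[ns] & pop$role[ns] == 1L & !pop$realized[ns])
      victim <- prey[sample.int(length(prey), 1L)]
      pop$alive[victim] <- FALSE
      pop$n_prey <- pop$n_prey - 1L
      if (!is.null(log))
        log_event(log, pop$clock, pop$id[victim], "removed_cap")
    }
  }
  tick_regeneration(world)
  pop$clock <- pop$clock + 1L
  invisible(pop)
}

#' Run a simulation for a set number of updates
#'
#' Applies [step()] `updates` times, optionally sampling a population
#' time-series (prey and predator counts, Shannon diversity of the prey
#' genotype table, mean birth generation) every `sample_every` updates,
#' including the starting state.
#'
#' @inheritParams step
#' @param updates Number of updates to run (>= 0).
#' @param sample_every Sampling interval in updates, or `NULL` for no
#'   samples.
#' @return A data.frame of samples (zero rows when `sample_every` is
#'   `NULL`); the population and world are advanced in place.
#' @export
run_updates <- function(pop, world, cfg, updates, sample_every = NULL,
                        log = NULL) {
  stopifnot(updates >= 0)
  samples <- list()
  take <- function() {
    idx <- living(pop)
    prey <- idx[pop$role[idx] == 1L & !pop$realized[idx]]
    h <- if (length(prey) > 0L)
      shannon_diversity(as.integer(table(pop$genotype[prey]))) else NA_real_
    data.frame(update = pop$clock,
               n_prey = length(prey),
               n_predators = length(idx) - length(prey),
               shannon_H = h,
               mean_generation = if (length(idx)) mean(pop$generation[idx])
                                 else NA_real_)
  }
  if (!is.null(sample_every)) samples[[1L]] <- take()
  if (updates > 0) {
    for (t in seq_len(updates)) {
      step(pop, world, cfg, log = log)
      if (!is.null(sample_every) && pop$clock %% sample_every == 0L)
        samples[[length(samples) + 1L]] <- take()
    }
  }
  if (length(samples) > 0L) do.call(rbind, samples)
  else data.frame(update = integer(), n_prey = integer(),
                  n_predators = integer(), shannon_H = numeric(),
                  mean_generation = numeric())
}

#' Snapshot a population
#'
#' Captures the living roster as a plain data.frame (genomes encoded as
#' strings), detached from the simulation state. Snapshots are the exchange
#' currency between experiment phases and the unit of file I/O.
#'
#' @param pop A population.
#' @return A list of class `pop_snapshot` with elements `organisms`
#'   (data.frame) and `clock`.
#' @export
snapshot <- function(pop) {
  idx <- living(pop)
  org <- data.frame(
    id = pop$id[idx],
    genome = vapply(pop$genomes[idx], encode_genome, ""),
    genotype = pop$genotype[idx],
    lineage = pop$lineage[idx],
    role = ifelse(pop$role[idx] == 2L, "predator", "prey"),
    realized = pop$realized[idx],
    parent_realized = pop$parent_realized[idx],
    x = pop$x[idx], y = pop$y[idx], facing = pop$facing[idx],
    age = pop$age[idx], generation = pop$generation[idx],
    resources = pop$resources[idx],
    group = pop$group[idx],
    stringsAsFactors = FALSE
  )
  rownames(org) <- NULL
  structure(list(organisms = org, clock = pop$clock), class = "pop_snapshot")
}

#' Build a snapshot directly from an organism table
#'
#' @param organisms A data.frame with at least `genome` (encoded strings);
#'   missing roster columns are filled with defaults.
#' @return A `pop_snapshot`.
#' @export
as_snapshot <- function(organisms) {
  n <- nrow(organisms)
  defaults <- list(id = seq_len(n),
                   genotype = organisms$genome,
                   lineage = as.character(seq_len(n)),
                   role = rep("prey", n),
                   realized = rep(FALSE, n),
                   parent_realized = rep(FALSE, n),
                   x = rep(0L, n), y = rep(0L, n),
                   facing = rep(1L, n), age = rep(0L, n),
                   generation = rep(0L, n), resources = rep(0, n),
                   group = rep(NA_character_, n))
  for (f in names(defaults))
    if (is.null(organisms[[f]])) organisms[[f]] <- defaults[[f]]
  organisms <- organisms[, c("id", "genome", "genotype", "lineage", "role",
                             "realized", "parent_realized", "x", "y",
                             "facing", "age", "generation", "resources",
                             "group")]
  structure(list(organisms = organisms, clock = 0L),
            class = "pop_snapshot")
}

#' Inject a snapshot into a live population
#'
#' Adds every organism of the snapshot to `pop`. Placement is either
#' `"random"` (uniform over the grid, the protocol used at every injection
#' of the experiments) or `"keep"` (retain stored coordinates, clipped to
#' the grid).
#'
#' @param pop,world Target population and grid.
#' @param snap A `pop_snapshot`.
#' @param placement `"random"` or `"keep"`.
#' @param role Optional role override (`"prey"`/`"predator"`).
#' @param static Mark injected organisms static (immortal/sterile).
#' @param fresh_lineages If `TRUE`, assign new unique lineage ids
#'   `prefix1..prefixN`.
#' @param lineage_prefix Prefix used when `fresh_lineages`.
#' @param group Optional competitor label applied to all injected organisms.
#' @return The population, invisibly.
#' @export
inject <- function(pop, world, snap, placement = "random", role = NULL,
                   static = FALSE, fresh_lineages = FALSE,
                   lineage_prefix = "L", group = NULL) {
  org <- snap$organisms
  n <- nrow(org)
  if (n == 0L) return(invisible(pop))
  if (placement == "random") {
    xs <- sample.int(world$width, n, replace = TRUE) - 1L
    ys <- sample.int(world$height, n, replace = TRUE) - 1L
    fs <- sample.int(8L, n, replace = TRUE)
  } else {
    xs <- pmin(pmax(org$x, 0L), world$width - 1L)
    ys <- pmin(pmax(org$y, 0L), world$height - 1L)
    fs <- org$facing
  }
  lin <- if (fresh_lineages) paste0(lineage_prefix, seq_len(n))
         else org$lineage
  grp <- if (!is.null(group)) rep(group, n) else org$group
  for (k in seq_len(n)) {
    add_organism(pop, decode_genome(org$genome[k]),
                 x = xs[k], y = ys[k], facing = fs[k],
                 role = if (!is.null(role)) role else org$role[k],
                 lineage = lin[k], generation = 0L,
                 parent_realized = FALSE, static = static,
                 group = grp[k])
  }
  invisible(pop)
}
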