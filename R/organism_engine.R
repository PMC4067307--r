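# Per-organism instruction execution with cycle accounting.
#
# The population is stored columnar (parallel vectors inside an
# environment) so the per-instruction loop touches scalars and the roster
# can grow by slab reallocation. One update gives each organism a budget of
# `cycles_per_update` cycles: ordinary instructions cost 1 cycle, a
# successful reproduction costs 30 (overrunning the budget is charged as
# debt against the next update), a successful attack costs 10 (handling
# time) and a failed attack costs 1.

#' Create an empty population
#'
#' @return An environment of class `population` holding the columnar
#'   organism roster and the update clock.
#' @export
new_population <- function() {
  p <- new.env(parent = emptyenv())
  p$n <- 0L                      # occupied slots
  p$clock <- 0L
  p$next_id <- 1L
  p$n_prey <- 0L                 # living, non-realized prey
  for (f in c("id", "x", "y", "facing", "age", "born", "reset_update",
              "generation", "total_instr", "cnt_moves", "cnt_turns",
              "cnt_looks", "cnt_eats", "cnt_repros", "cnt_attacks",
              "debt", "ip", "attacks_received"))
    assign(f, integer(0), envir = p)
  p$alive <- logical(0); p$realized <- logical(0)
  p$parent_realized <- logical(0); p$static <- logical(0)
  p$sensor_prey <- logical(0); p$sensor_pred <- logical(0)
  p$role <- integer(0)           # 1 prey, 2 predator
  p$resources <- numeric(0)
  p$lineage <- character(0); p$group <- character(0)
  p$genomes <- list(); p$gact <- list(); p$genotype <- character(0)
  class(p) <- "population"
  p
}

pop_reserve <- function(pop, extra) {
  need <- pop$n + extra
  cap <- length(pop$alive)
  if (need <= cap) return(invisible(pop))
  newcap <- max(need, 2L * cap, 64L)
  grow <- function(v, fill) c(v, rep(fill, newcap - length(v)))
  for (f in c("id", "x", "y", "facing", "age", "born", "reset_update",
              "generation", "total_instr", "cnt_moves", "cnt_turns",
              "cnt_looks", "cnt_eats", "cnt_repros", "cnt_attacks",
              "debt", "ip", "attacks_received"))
    assign(f, grow(get(f, envir = pop), 0L), envir = pop)
  for (f in c("alive", "realized", "parent_realized", "static",
              "sensor_prey", "sensor_pred"))
    assign(f, grow(get(f, envir = pop), FALSE), envir = pop)
  pop$role <- grow(pop$role, 1L)
  pop$resources <- grow(pop$resources, 0)
  pop$lineage <- grow(pop$lineage, NA_character_)
  pop$group <- grow(pop$group, NA_character_)
  length(pop$genomes) <- newcap
  length(pop$gact) <- newcap
  pop$genotype <- grow(pop$genotype, NA_character_)
  invisible(pop)
}

#' Add an organism to a population
#'
#' @param pop A [new_population()].
#' @param genome Integer code vector.
#' @param x,y,facing Position (0-based) and facing (1..8).
#' @param role `"prey"` or `"predator"`.
#' @param lineage Lineage id (inherited unchanged by all progeny).
#' @param generation Birth generation (offspring get parent's + 1).
#' @param parent_realized Whether the parent had executed an attack.
#' @param static Static organisms never die or reproduce; they reset.
#' @param group Optional competitor label used in competitions.
#' @param tab Instruction table.
#' @return The new organism's slot index, invisibly.
#' @export
add_organism <- function(pop, genome, x, y, facing = 1L, role = "prey",
                         lineage = NA_character_, generation = 0L,
                         parent_realized = FALSE, static = FALSE,
                         group = NA_character_,
                         tab = default_instructions()) {
  pop_reserve(pop, 1L)
  i <- pop$n + 1L
  pop$n <- i
  pop$id[i] <- pop$next_id; pop$next_id <- pop$next_id + 1L
  pop$alive[i] <- TRUE
  pop$x[i] <- as.integer(x); pop$y[i] <- as.integer(y)
  pop$facing[i] <- as.integer(facing)
  pop$age[i] <- 0L; pop$born[i] <- pop$clock
  pop$reset_update[i] <- pop$clock
  pop$generation[i] <- as.integer(generation)
  pop$role[i] <- if (identical(role, "predator")) 2L else 1L
  pop$realized[i] <- FALSE
  pop$parent_realized[i] <- isTRUE(parent_realized)
  pop$static[i] <- isTRUE(static)
  pop$resources[i] <- 0
  pop$ip[i] <- 1L; pop$debt[i] <- 0L
  pop$total_instr[i] <- 0L
  pop$cnt_moves[i] <- pop$cnt_turns[i] <- pop$cnt_looks[i] <- 0L
  pop$cnt_eats[i] <- pop$cnt_repros[i] <- pop$cnt_attacks[i] <- 0L
  pop$attacks_received[i] <- 0L
  pop$sensor_prey[i] <- pop$sensor_pred[i] <- FALSE
  pop$lineage[i] <- as.character(lineage)
  pop$group[i] <- group
  pop$genomes[[i]] <- as.integer(genome)
  pop$gact[[i]] <- tab$action[genome]
  pop$genotype[i] <- encode_genome(genome, tab)
  if (pop$role[i] == 1L) pop$n_prey <- pop$n_prey + 1L
  invisible(i)
}

is_pred_idx <- function(pop, i) pop$role[i] == 2L | pop$realized[i]

# fast organism scan for the look instruction: any prey / predator in the
# 45-degree sector in front of organism i
look_scan <- function(pop, i, max_range) {
  idx <- which(pop$alive[seq_len(pop$n)])
  idx <- idx[idx != i]
  if (length(idx) == 0L) return(c(FALSE, FALSE))
  rx <- pop$x[idx] - pop$x[i]
  ry <- pop$y[idx] - pop$y[i]
  dist <- pmax(abs(rx), abs(ry))
  near <- dist <= max_range & dist > 0L
  if (!any(near)) return(c(FALSE, FALSE))
  idx <- idx[near]; rx <- rx[near]; ry <- ry[near]
  f <- pop$facing[i]
  face_ang <- atan2(-FACING_DY[f], FACING_DX[f])
  ang <- atan2(-ry, rx)
  diff <- abs(((ang - face_ang + pi) %% (2 * pi)) - pi)
  seen <- idx[diff <= pi / 8]
  if (length(seen) == 0L) return(c(FALSE, FALSE))
  pred <- is_pred_idx(pop, seen)
  c(any(!pred), any(pred))
}

#' Execute one update's worth of instructions for one organism
#'
#' Runs the organism's genome from its current execution pointer (wrapping
#' at the genome end) until its cycle budget for this update is exhausted.
#' Reproduction, if eligible, creates the offspring immediately: the child
#' genome passes through [mutate_on_copy()], is placed in the faced cell
#' (or the parent's cell if that is out of bounds), inherits the lineage,
#' and the parent is "reborn" (execution pointer, sensor, resource tally and
#' the age-since-rebirth marker reset; lifetime trait counters kept). An
#' attack kills the prey in the faced cell only while the living prey count
#' exceeds `cfg$min_prey`; the attacker is credited 10% of the victim's
#' resource tally. Executing an attack (successful or not) marks the
#' organism as a realized predator.
#'
#' @param pop,world Population and grid (both modified in place).
#' @param i Slot index of the organism.
#' @param cfg A [sim_config()].
#' @param log Optional event log (see [new_event_log()]).
#' @param collect If `TRUE`, return a data.frame of per-instruction events
#'   with their cycle costs (for unit-level inspection; slower).
#' @return Invisibly `NULL`, or the event data.frame when `collect = TRUE`.
#' @export
execute_update <- function(pop, i, world, cfg, log = NULL, collect = FALSE) {
  budget <- cfg$cycles_per_update - pop$debt[i]
  pop$debt[i] <- 0L
  if (budget <= 0L) {
    pop$debt[i] <- -budget
    return(invisible(NULL))
  }
  gact <- pop$gact[[i]]
  L <- length(gact)
  ip <- pop$ip[i]
  x <- pop$x[i]; y <- pop$y[i]; facing <- pop$facing[i]
  res <- pop$resources[i]
  total <- pop$total_instr[i]
  moves <- pop$cnt_moves[i]; turns <- pop$cnt_turns[i]
  looks <- pop$cnt_looks[i]; eats <- pop$cnt_eats[i]
  repros <- pop$cnt_repros[i]; attacks <- pop$cnt_attacks[i]
  is_static <- pop$static[i]
  events <- if (collect) list() else NULL
  ev <- function(kind, cost) {
    if (collect) events[[length(events) + 1L]] <<- list(kind = kind,
                                                        cost = cost)
  }
  while (budget > 0L && pop$alive[i]) {
    a <- gact[ip]
    advance <- 1L
    cost <- 1L
    if (a == ACTION_INERT) {
      ev("noop", 1L)
    } else if (a == ACTION_MOVE) {
      nx <- x + FACING_DX[facing]; ny <- y + FACING_DY[facing]
      if (nx >= 0L && nx < world$width && ny >= 0L && ny < world$height) {
        x <- nx; y <- ny
        ev("moved", 1L)
      } else ev("move_blocked", 1L)
      moves <- moves + 1L
    } else if (a == ACTION_TURN_L || a == ACTION_TURN_R) {
      facing <- turn(facing, if (a == ACTION_TURN_L) -1L else 1L)
      turns <- turns + 1L
      ev("turned", 1L)
    } else if (a == ACTION_LOOK) {
      pop$x[i] <- x; pop$y[i] <- y; pop$facing[i] <- facing
      seen <- look_scan(pop, i, cfg$view_range)
      pop$sensor_prey[i] <- seen[1L]
      pop$sensor_pred[i] <- seen[2L]
      looks <- looks + 1L
      ev("looked", 1L)
    } else if (a == ACTION_EAT) {
      if (pop$role[i] == 2L || pop$realized[i]) {
        ev("noop", 1L)            # predators cannot consume resources
      } else {
        if (world$resource[y + 1L, x + 1L] == 1L) {
          world$resource[y + 1L, x + 1L] <- 0L
          world$timer[y + 1L, x + 1L] <- world$regen_delay
          res <- res + 1
          ev("ate", 1L)
        } else ev("ate_nothing", 1L)
        eats <- eats + 1L
      }
    } else if (a == ACTION_REPRO) {
      eligible <- !is_static &&
        res >= cfg$repro_resource_threshold &&
        (pop$clock - pop$reset_update[i]) >= cfg$repro_min_age_updates
      if (eligible) {
        # sync parent state, then birth (may trigger roster growth)
        pop$x[i] <- x; pop$y[i] <- y; pop$facing[i] <- facing
        child <- mutate_on_copy(pop$genomes[[i]], cfg$rates)
        bx <- x + FACING_DX[facing]; by <- y + FACING_DY[facing]
        if (bx < 0L || bx >= world$width || by < 0L || by >= world$height) {
          bx <- x; by <- y
        }
        add_organism(pop, child, bx, by, facing = facing,
                     role = if (pop$role[i] == 2L) "predator" else "prey",
                     lineage = pop$lineage[i],
                     generation = pop$generation[i] + 1L,
                     parent_realized = pop$realized[i] || pop$role[i] == 2L,
                     static = FALSE, group = pop$group[i])
        gact <- pop$gact[[i]]   # list may have been reallocated
        if (!is.null(log))
          log_event(log, pop$clock, pop$id[i], "birth",
                    pop$id[pop$n])
        repros <- repros + 1L
        # parent reborn: internal state reset, lifetime counters kept
        res <- 0
        ip <- 0L                 # advanced to 1 below
        pop$sensor_prey[i] <- pop$sensor_pred[i] <- FALSE
        pop$reset_update[i] <- pop$clock
        cost <- cfg$cycles_per_update
        ev("birth_requested", cost)
      } else ev("repro_failed", 1L)
    } else if (a == ACTION_ATTACK) {
      allowed <- pop$role[i] == 2L || cfg$prey_attack_execution
      if (!allowed) {
        ev("noop", 1L)
      } else {
        if (pop$role[i] == 1L && !pop$realized[i]) {
          pop$realized[i] <- TRUE
          pop$n_prey <- pop$n_prey - 1L   # no longer counts as prey
        }
        attacks <- attacks + 1L
        tx <- x + FACING_DX[facing]; ty <- y + FACING_DY[facing]
        victim <- 0L
        if (tx >= 0L && tx < world$width && ty >= 0L && ty < world$height) {
          ns <- seq_len(pop$n)
          cand <- which(pop$alive[ns] & pop$x[ns] == tx & pop$y[ns] == ty &
                        pop$role[ns] == 1L & !pop$realized[ns])
          cand <- cand[cand != i]
          if (length(cand) > 0L) {
            victim <- cand[sample.int(length(cand), 1L)]
            pop$attacks_received[victim] <- pop$attacks_received[victim] + 1L
          }
        }
        if (victim > 0L && pop$n_prey > cfg$min_prey) {
          pop$alive[victim] <- FALSE
          pop$n_prey <- pop$n_prey - 1L
          res <- res + cfg$predator_gain_fraction * pop$resources[victim]
          if (!is.null(log))
            log_event(log, pop$clock, pop$id[i], "attack_killed",
                      pop$id[victim])
          cost <- cfg$attack_cost_cycles
          ev("attack_killed", cost)
        } else {
          ev("attack_failed", 1L)
        }
      }
    } else {                      # conditionals
      cond <- if (a == ACTION_IF_PREY) pop$sensor_prey[i]
              else if (a == ACTION_IF_PRED) pop$sensor_pred[i]
              else world$resource[y + 1L, x + 1L] == 1L
      if (!cond) advance <- 2L
      ev("conditional", 1L)
    }
    total <- total + 1L
    budget <- budget - cost
    ip <- ((ip + advance - 1L) %% L) + 1L
  }
  if (budget < 0L) pop$debt[i] <- -budget
  pop$x[i] <- x; pop$y[i] <- y; pop$facing[i] <- facing
  pop$ip[i] <- ip
  pop$resources[i] <- res
  pop$total_instr[i] <- total
  pop$cnt_moves[i] <- moves; pop$cnt_turns[i] <- turns
  pop$cnt_looks[i] <- looks; pop$cnt_eats[i] <- eats
  pop$cnt_repros[i] <- repros; pop$cnt_attacks[i] <- attacks
  if (collect) {
    data.frame(kind = vapply(events, `[[`, "", "kind"),
               cost = vapply(events, function(e) as.integer(e$cost), 0L),
               stringsAsFactors = FALSE)
  } else invisible(NULL)
}

#' Reproduction eligibility
#'
#' An organism may reproduce once it has consumed at least
#' `repro_resource_threshold` resource units (default 10) since its last
#' rebirth and at least `repro_min_age_updates` updates (default 100) have
#' passed since its birth or last reproduction.
#'
#' @param pop,i Population and slot index.
#' @param cfg A [sim_config()].
#' @return Logical.
#' @export
reproduction_eligible <- function(pop, i, cfg) {
  !pop$static[i] &&
    pop$resources[i] >= cfg$repro_resource_threshold &&
    (pop$clock - pop$reset_update[i]) >= cfg$repro_min_age_updates
}
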