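#!/usr/bin/env Rscript
# Phase 3a: pairwise competitions between the evolved Phase 2 populations.
#
# Every replicate of every treatment is paired with one random replicate of
# each other treatment; each pairing runs under both predator-treatment
# levels with the double-injection protocol (a conditioning run consumes
# part of the resource landscape before the scored trial) and zero mutation
# rates. The novel Phase 3 predator uses about half the visual-sensor
# aggressiveness of the Phase 2 predator.

suppressPackageStartupMessages(library(digiprey))
dir.create("results/phase3", recursive = TRUE, showWarnings = FALSE)

grid <- 24L; prey_level <- 60L
conditioning <- 200L; trial <- 1000L; sample_every <- 200L
replicates <- 3L
cfg <- default_config()
set.seed(501)
predators3 <- make_predator_population(6, aggressiveness = 0.5)

pops <- treatment_grid(replicates)
sched <- schedule_competitions(pops)
cat(sprintf("schedule: %d pairings, %d trials\n",
            length(unique(sched$pairing_id)), nrow(sched)))

load_pop <- function(tr, rep) {
  parts <- strsplit(tr, ":", fixed = TRUE)[[1]]
  read_snapshot(sprintf("results/phase2/%s_%s_r%d.fa",
                        parts[1], parts[2], rep))
}

long <- list(); outcomes <- list()
for (k in seq_len(nrow(sched))) {
  row <- sched[k, ]
  a <- load_pop(row$a_treatment, row$a_replicate)
  b <- load_pop(row$b_treatment, row$b_replicate)
  rec <- run_competition(a, b, pt = row$pt, predators = predators3,
                         grid = grid, prey_level = prey_level,
                         conditioning_updates = conditioning,
                         trial_updates = trial,
                         sample_every = sample_every)
  s <- rec$series
  long[[k]] <- data.frame(trial_id = k, pairing_id = row$pairing_id,
                          pt = row$pt, update = s$update,
                          a_treatment = row$a_treatment,
                          b_treatment = row$b_treatment,
                          share_a = s$share_a, share_b = s$share_b)
  outcomes[[k]] <- data.frame(trial_id = k, pairing_id = row$pairing_id,
                              pt = row$pt,
                              a_treatment = row$a_treatment,
                              a_replicate = row$a_replicate,
                              b_treatment = row$b_treatment,
                              b_replicate = row$b_replicate,
                              final_share_a = rec$final_share_a)
  if (k %% 20 == 0) cat(sprintf("  %d / %d trials\n", k, nrow(sched)))
}
outcomes <- do.call(rbind, outcomes)
write_report(do.call(rbind, long), "results/phase3/competition_series.csv",
             cfg)
write_report(outcomes, "results/phase3/competition_outcomes.csv", cfg)

# directional sanity: do predator-EH populations win cross-EH pairings?
eh_of <- function(tr) sub(":.*$", "", tr)
cross <- outcomes[eh_of(outcomes$a_treatment) !=
                  eh_of(outcomes$b_treatment), ]
pred_share <- ifelse(eh_of(cross$a_treatment) == "predator",
                     cross$final_share_a, 1 - cross$final_share_a)
for (lev in c("present", "absent")) {
  sel <- cross$pt == lev
  cat(sprintf(
    "PT=%s: predator-EH mean final share %.3f; wins %d / %d cross-EH trials\n",
    lev, mean(pred_share[sel]), sum(pred_share[sel] > 0.5), sum(sel)))
}
cat("wrote results/phase3/\n")
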