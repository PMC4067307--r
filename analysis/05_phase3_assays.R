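#!/usr/bin/env Rscript
# Phase 3b: trait assays of the starting and final Phase 2 populations.
#
# Each replicate is assayed mutation-free, pre- and post-Phase 2, under
# both predator-treatment levels, with the prey count held constant via the
# population cap and the attack-protection threshold. Per-prey lifetime
# proportions of moves, turns and looks (and attacks received) quantify the
# behavioral change attributable to Phase 2 evolution.

suppressPackageStartupMessages(library(digiprey))
dir.create("results/phase3", recursive = TRUE, showWarnings = FALSE)

grid <- 24L; prey_level <- 40L
conditioning <- 200L; trial <- 800L
replicates <- 3L
cfg <- default_config()
set.seed(601)
predators3 <- make_predator_population(6, aggressiveness = 0.5)

records <- list(); deltas <- list()
for (eh in c("predator", "no_predator")) {
  for (sgv in c("clone", "intermediate", "high")) {
    for (rep in seq_len(replicates)) {
      label <- sprintf("%s:%s:r%d", eh, sgv, rep)
      pre_pop <- read_snapshot(sprintf("results/phase2/%s_%s_r%d_start.fa",
                                       eh, sgv, rep))
      post_pop <- read_snapshot(sprintf("results/phase2/%s_%s_r%d.fa",
                                        eh, sgv, rep))
      for (pt in c("present", "absent")) {
        pre <- run_trait_assay(pre_pop, pt = pt, predators = predators3,
                               population = label, stage = "pre_phase2",
                               grid = grid, prey_level = prey_level,
                               conditioning_updates = conditioning,
                               trial_updates = trial)
        post <- run_trait_assay(post_pop, pt = pt, predators = predators3,
                                population = label, stage = "post_phase2",
                                grid = grid, prey_level = prey_level,
                                conditioning_updates = conditioning,
                                trial_updates = trial)
        for (rec in list(pre, post))
          records[[length(records) + 1L]] <-
            data.frame(population = rec$population, eh = eh, sgv = sgv,
                       replicate = rep, pt = rec$pt, stage = rec$stage,
                       moves = rec$moves, turns = rec$turns,
                       looks = rec$looks,
                       total_instructions = rec$total_instructions,
                       attacks_received = rec$attacks_received)
        d <- trait_deltas(pre, post)
        d$eh <- eh; d$sgv <- sgv; d$replicate <- rep
        deltas[[length(deltas) + 1L]] <- d
      }
    }
  }
  cat(sprintf("assayed EH=%s\n", eh))
}
records <- do.call(rbind, records)
deltas <- do.call(rbind, deltas)
write_report(records, "results/phase3/assay_records.csv", cfg)
write_report(deltas, "results/phase3/trait_deltas.csv", cfg)
write_lmm_input(deltas, "results/phase3/lmm_input.csv")
cat("wrote results/phase3/assay_records.csv, trait_deltas.csv, ",
    "lmm_input.csv\n", sep = "")
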