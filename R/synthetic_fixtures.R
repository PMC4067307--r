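# Generators for populations with the statistical structure the analysis
# assumes (genotype-abundance seed populations, neutral mutation-
# accumulation lineages, scripted behavioral genomes), so every pipeline
# stage is testable without running full open-ended evolution.

#' Random genome with specified behavioral instruction densities
#'
#' Each position is drawn independently: with probability equal to its
#' density a position carries the corresponding behavioral symbol, otherwise
#' an inert no-op chosen uniformly. Densities are per-symbol fractions and
#' must sum to at most 1.
#'
#' @param length Genome length (instructions).
#' @param density Named numeric vector of per-symbol fractions, e.g.
#'   `c(move = 0.2, eat = 0.1, repro = 0.05)`. Names must be instruction
#'   symbols.
#' @param allow_attack If `FALSE`, the attack symbol may not appear even if
#'   listed.
#' @param tab Instruction table.
#' @return An integer code vector.
#' @export
random_genome <- function(length, density = c(move = 0.1, eat = 0.1,
                                              repro = 0.05),
                          allow_attack = TRUE,
                          tab = default_instructions()) {
  stopifnot(length >= 1, sum(density) <= 1)
  codes <- genome_from_symbols(names(density), tab)
  if (!allow_attack) {
    keep <- codes != attack_code(tab)
    codes <- codes[keep]; density <- density[keep]
  }
  nops <- tab$code[tab$category == "inert"]
  probs <- c(density, 1 - sum(density))
  pick <- sample.int(length(probs), length, replace = TRUE, prob = probs)
  out <- integer(length)
  beh <- pick <= length(codes)
  out[beh] <- codes[pick[beh]]
  out[!beh] <- nops[sample.int(length(nops), sum(!beh), replace = TRUE)]
  out
}

#' Generate a seed prey population
#'
#' Emulates the genotype-abundance structure of an evolved prey population:
#' `n_genotypes` random genomes with the given behavioral densities,
#' expanded to `n_organisms` organisms under an abundance model, each
#' organism carrying a unique lineage id. Evolved populations are typically
#' dominated by a few genotypes with a rare tail, which the geometric model
#' reproduces; `uniform` gives equal abundances and `empirical` uses a
#' supplied abundance vector.
#'
#' @param n_organisms,n_genotypes Population and genotype counts
#'   (`n_genotypes <= n_organisms`).
#' @param abundance_model `"geometric"`, `"uniform"` or `"empirical"`.
#' @param theta Geometric-model parameter in (0, 1): genotype i has weight
#'   proportional to `theta * (1 - theta)^(i-1)`; realized abundances are a
#'   multinomial draw (every genotype is first given one copy so all
#'   `n_genotypes` are represented).
#' @param abundances Abundance vector for the empirical model (must sum to
#'   `n_organisms`).
#' @param genome_length Genome length.
#' @param density Behavioral densities for [random_genome()].
#' @param allow_attack Whether attack symbols may appear in genomes.
#' @return A `pop_snapshot` of prey with unique lineage ids.
#' @export
make_seed_population <- function(n_organisms, n_genotypes,
                                 abundance_model = c("geometric", "uniform",
                                                     "empirical"),
                                 theta = 0.1,
                                 abundances = NULL,
                                 genome_length = 100L,
                                 density = c(move = 0.1, eat = 0.1,
                                             repro = 0.05),
                                 allow_attack = FALSE) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_genotypes >= 1, n_genotypes <= n_organisms)
  genomes <- replicate(n_genotypes,
                       random_genome(genome_length, density,
                                     allow_attack = allow_attack),
                       simplify = FALSE)
  ab <- switch(abundance_model,
    uniform = {
      base <- n_organisms %/% n_genotypes
      rem <- n_organisms %% n_genotypes
      base + c(rep(1L, rem), rep(0L, n_genotypes - rem))
    },
    geometric = {
      stopifnot(theta > 0, theta < 1)
      w <- theta * (1 - theta)^(seq_len(n_genotypes) - 1)
      extra <- n_organisms - n_genotypes
      add <- if (extra > 0)
        as.integer(stats::rmultinom(1, extra, prob = w)) else 0L
      rep(1L, n_genotypes) + add
    },
    empirical = {
      if (is.null(abundances) || sum(abundances) != n_organisms ||
          length(abundances) != n_genotypes)
        stop("empirical model needs abundances of length n_genotypes ",
             "summing to n_organisms")
      as.integer(abundances)
    })
  g_idx <- rep(seq_len(n_genotypes), times = ab)
  org <- data.frame(
    genome = vapply(genomes, encode_genome, "")[g_idx],
    stringsAsFactors = FALSE
  )
  snap <- as_snapshot(org)
  snap$organisms$lineage <- as.character(seq_len(nrow(org)))
  snap
}

#' Neutral mutation-accumulation lineage
#'
#' Applies [mutate_on_copy()] `generations` times to an ancestor: pure
#' mutation accumulation with no selection. At the low per-generation rates
#' of the standing-variation evolution phase (substitution 0.001, insertion
#' and deletion 0.005 each) this yields about 5% alignment divergence from
#' the ancestor after 500 generations on a length-100 genome, matching the
#' expected divergence of a bacterial genome over the same number of
#' generations.
#'
#' @param ancestor Integer code vector.
#' @param generations Number of sequential reproductions (>= 0).
#' @param rates A [mutation_rates()] object.
#' @return The descendant genome.
#' @export
neutral_lineage <- function(ancestor, generations, rates) {
  stopifnot(generations >= 0)
  g <- ancestor
  for (k in seq_len(generations)) g <- mutate_on_copy(g, rates)
  g
}

#' Deterministic scripted genome
#'
#' Builds a genome that executes the given instruction symbols as a loop,
#' optionally padded with inert no-ops to a target length. Used for the
#' hand-written ancestor, predator fixtures, and engine-test oracles.
#'
#' @param symbols Character vector of instruction symbols (the loop body).
#' @param pad_to Optional total length; the remainder is `nop-X`.
#' @param tab Instruction table.
#' @return An integer code vector.
#' @export
scripted_genome <- function(symbols, pad_to = NULL,
                            tab = default_instructions()) {
  g <- genome_from_symbols(symbols, tab)
  if (!is.null(pad_to)) {
    stopifnot(pad_to >= length(g))
    g <- c(g, rep(nop_x_code(tab), pad_to - length(g)))
  }
  g
}

#' The hand-written ancestor genome
#'
#' A blind forager that walks, feeds, periodically turns (so it does not
#' park against the grid boundary) and repeatedly attempts reproduction,
#' padded with inert no-ops to length 100. It carries no sensor use and no
#' attack capability. Nine copies of this genome seed every open-ended
#' evolution run.
#'
#' @return An integer code vector of length 100.
#' @export
ancestor_genome <- function() {
  scripted_genome(c("move", "eat", "move", "eat", "move", "eat",
                    "turn-left", "repro"), pad_to = 100L)
}

#' Scripted predator population fixture
#'
#' Builds `n` identical pursuit predators: a loop of look, conditional
#' attack and movement. The `aggressiveness` knob scales how much of the
#' loop is spent looking and attacking versus idling, standing in for the
#' between-replicate variation in evolved predator sensor usage: the
#' standing-variation phase uses an aggressive (high-look) predator
#' population, the competition phase a novel predator with about half the
#' visual-sensor usage.
#'
#' @param n Number of predators.
#' @param aggressiveness In (0, 1]: fraction of the genome devoted to the
#'   pursuit loop; the remainder is inert. `1` looks every 6 instructions;
#'   `0.5` has half the per-instruction look/attack rate.
#' @param genome_length Total genome length.
#' @return A `pop_snapshot` of predators.
#' @export
make_predator_population <- function(n, aggressiveness = 1,
                                     genome_length = 60L) {
  stopifnot(n >= 1, aggressiveness > 0, aggressiveness <= 1)
  loop <- c("look", "if-prey-seen", "attack", "move", "turn-left", "move")
  reps <- max(1L, floor(genome_length * aggressiveness / length(loop)))
  body <- rep(loop, reps)
  g <- scripted_genome(body, pad_to = max(genome_length, length(body)))
  org <- data.frame(genome = rep(encode_genome(g), n),
                    role = rep("predator", n),
                    stringsAsFactors = FALSE)
  snap <- as_snapshot(org)
  snap$organisms$lineage <- paste0("P", seq_len(n))
  snap
}
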