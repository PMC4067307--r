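# Instruction alphabet, genomes, and the mutation-on-copy operator.
#
# Genomes are stored as integer vectors of instruction codes (indices into
# the instruction table); this keeps the execution engine and the mutation
# operator cheap while symbols/characters are only materialised at the I/O
# boundary.

#' The instruction alphabet
#'
#' Builds the fixed 60-symbol instruction table: 10 behavioral instructions
#' (movement, turning, looking, feeding, reproduction, attack and three
#' conditionals) plus `n_inert` inert no-op variants, among which `nop-X` is
#' the designated "do nothing" replacement symbol used when attack
#' instructions are stripped from prey genomes. Each symbol also carries a
#' single printable ASCII character used to serialise genomes as FASTA
#' sequences.
#'
#' The alphabet size is 60 by construction (10 + 50); `n_inert` exists so
#' that tests can exercise small alphabets, not as a tuning knob.
#'
#' @param n_inert Number of inert no-op symbols (default 50).
#' @return A data.frame with columns `code`, `symbol`, `category`, `action`,
#'   `char`. Categories are one of `move`, `turn_left`, `turn_right`, `look`,
#'   `eat`, `repro`, `attack`, `conditional`, `inert`.
#' @export
instruction_table <- function(n_inert = 50L) {
  n_inert <- as.integer(n_inert)
  stopifnot(n_inert >= 1L)
  behav <- data.frame(
    symbol = c("move", "turn-left", "turn-right", "look", "eat", "repro",
               "attack", "if-prey-seen", "if-predator-seen",
               "if-resource-here"),
    category = c("move", "turn_left", "turn_right", "look", "eat", "repro",
                 "attack", "conditional", "conditional", "conditional"),
    # action ids consumed by the execution engine
    action = 1:10,
    stringsAsFactors = FALSE
  )
  nops <- data.frame(
    symbol = c("nop-X", sprintf("nop-%02d", seq_len(n_inert - 1L))),
    category = "inert",
    action = ACTION_INERT,
    stringsAsFactors = FALSE
  )
  tab <- rbind(behav, nops)
  tab$code <- seq_len(nrow(tab))
  chars <- c(LETTERS, letters, as.character(0:9))
  if (nrow(tab) > length(chars))
    stop("alphabet larger than the serialisation character set")
  tab$char <- chars[tab$code]
  tab[, c("code", "symbol", "category", "action", "char")]
}

# engine action ids (see instruction_table)
ACTION_MOVE <- 1L; ACTION_TURN_L <- 2L; ACTION_TURN_R <- 3L
ACTION_LOOK <- 4L; ACTION_EAT <- 5L; ACTION_REPRO <- 6L
ACTION_ATTACK <- 7L; ACTION_IF_PREY <- 8L; ACTION_IF_PRED <- 9L
ACTION_IF_RES <- 10L; ACTION_INERT <- 11L

# cached default table and derived lookup vectors
.instr_cache <- new.env(parent = emptyenv())

default_instructions <- function() {
  if (is.null(.instr_cache$tab)) {
    tab <- instruction_table()
    .instr_cache$tab <- tab
    .instr_cache$action <- tab$action
    .instr_cache$chars <- tab$char
    .instr_cache$code_of_char <- stats::setNames(tab$code, tab$char)
    .instr_cache$code_of_symbol <- stats::setNames(tab$code, tab$symbol)
  }
  .instr_cache$tab
}

attack_code <- function(tab = default_instructions()) {
  tab$code[tab$category == "attack"]
}

nop_x_code <- function(tab = default_instructions()) {
  tab$code[tab$symbol == "nop-X"]
}

#' Convert between genomes, symbol vectors and encoded strings
#'
#' A genome is an integer vector of instruction codes. `genome_from_symbols`
#' looks symbols up in the instruction table; `genome_symbols` inverts that;
#' `encode_genome`/`decode_genome` map to and from the single-character
#' serialisation used in snapshot files.
#'
#' @param symbols Character vector of instruction symbols.
#' @param genome Integer vector of instruction codes.
#' @param string Single encoded string.
#' @param tab Instruction table (defaults to the 60-symbol alphabet).
#' @return `genome_from_symbols` and `decode_genome` return an integer code
#'   vector; `genome_symbols` a character vector; `encode_genome` a string.
#' @export
genome_from_symbols <- function(symbols, tab = default_instructions()) {
  codes <- match(symbols, tab$symbol)
  if (anyNA(codes))
    stop("unknown instruction symbol(s): ",
         paste(unique(symbols[is.na(codes)]), collapse = ", "))
  as.integer(tab$code[codes])
}

#' @rdname genome_from_symbols
#' @export
genome_symbols <- function(genome, tab = default_instructions()) {
  tab$symbol[genome]
}

#' @rdname genome_from_symbols
#' @export
encode_genome <- function(genome, tab = default_instructions()) {
  paste(tab$char[genome], collapse = "")
}

#' @rdname genome_from_symbols
#' @export
decode_genome <- function(string, tab = default_instructions()) {
  chars <- strsplit(string, "", fixed = TRUE)[[1]]
  codes <- match(chars, tab$char)
  if (anyNA(codes))
    stop("unknown genome character(s): ",
         paste(unique(chars[is.na(codes)]), collapse = ", "))
  as.integer(codes)
}

#' Genotype identity
#'
#' The canonical genotype digest of a genome: two organisms share a genotype
#' exactly when their instruction sequences are identical. The digest is the
#' encoded sequence string itself, which is deterministic, collision-free and
#' directly inspectable.
#'
#' @inheritParams genome_from_symbols
#' @return A string identifying the genotype.
#' @export
genotype_id <- function(genome, tab = default_instructions()) {
  encode_genome(genome, tab)
}

#' Mutation rates
#'
#' Per-reproduction probabilities of a single substitution, insertion and
#' deletion, plus whether the attack instruction may be drawn as a
#' substitution/insertion replacement. The open-ended evolution phase uses
#' (0.25, 0.05, 0.05); the standing-variation evolution phase uses
#' (0.001, 0.005, 0.005), calibrated so that 500 generations of neutral
#' accumulation yield about 5% alignment divergence on a length-100 genome.
#'
#' @param p_sub,p_ins,p_del Probabilities in \[0, 1\].
#' @param attack_allowed If `FALSE`, the attack symbol is excluded from the
#'   replacement alphabet so it can never mutate into a genome.
#' @return A list with class `mutation_rates`.
#' @export
mutation_rates <- function(p_sub = 0, p_ins = 0, p_del = 0,
                           attack_allowed = TRUE) {
  for (p in c(p_sub, p_ins, p_del))
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
      stop("mutation probabilities must lie in [0, 1]")
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 attack_allowed = isTRUE(attack_allowed)),
            class = "mutation_rates")
}

#' Phase-specific mutation-rate presets
#'
#' @param attack_allowed Passed through to [mutation_rates()].
#' @return A `mutation_rates` object.
#' @export
phase1_rates <- function(attack_allowed = TRUE) {
  mutation_rates(0.25, 0.05, 0.05, attack_allowed = attack_allowed)
}

#' @rdname phase1_rates
#' @export
phase2_rates <- function(attack_allowed = FALSE) {
  mutation_rates(0.001, 0.005, 0.005, attack_allowed = attack_allowed)
}

#' Mutate a genome during the copy process
#'
#' Applies the per-reproduction mutation model: at most one substitution
#' (probability `p_sub`; uniform position; replacement drawn uniformly from
#' the full alphabet, so the same symbol may be redrawn) and at most one
#' indel event. Insertion and deletion fire independently with `p_ins` and
#' `p_del`; if both fire in the same reproduction one of the two is chosen
#' uniformly and the other discarded. A deletion that would empty the genome
#' is suppressed (length never drops below 1). With `attack_allowed = FALSE`
#' the attack symbol is excluded from substitution and insertion draws.
#'
#' Randomness comes from R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param parent Integer code vector (the parent genome).
#' @param rates A [mutation_rates()] object.
#' @param tab Instruction table.
#' @param detail If `TRUE`, return a list with the child genome and which
#'   operators fired (used for mutation-calibration instrumentation).
#' @return The child genome, or a list `(genome, sub_fired, indel)` where
#'   `indel` is one of `"none"`, `"ins"`, `"del"`, `"del_suppressed"`.
#' @export
mutate_on_copy <- function(parent, rates, tab = default_instructions(),
                           detail = FALSE) {
  n_alpha <- nrow(tab)
  draw_pool <- if (rates$attack_allowed) seq_len(n_alpha)
               else setdiff(seq_len(n_alpha), attack_code(tab))
  child <- parent
  sub_fired <- stats::runif(1) < rates$p_sub
  if (sub_fired) {
    pos <- sample.int(length(child), 1L)
    child[pos] <- draw_pool[sample.int(length(draw_pool), 1L)]
  }
  ins_fired <- stats::runif(1) < rates$p_ins
  del_fired <- stats::runif(1) < rates$p_del
  indel <- "none"
  if (ins_fired && del_fired) {
    if (stats::runif(1) < 0.5) del_fired <- FALSE else ins_fired <- FALSE
  }
  if (ins_fired) {
    pos <- sample.int(length(child) + 1L, 1L)   # insert before pos
    sym <- draw_pool[sample.int(length(draw_pool), 1L)]
    child <- append(child, sym, after = pos - 1L)
    indel <- "ins"
  } else if (del_fired) {
    if (length(child) > 1L) {
      pos <- sample.int(length(child), 1L)
      child <- child[-pos]
      indel <- "del"
    } else {
      indel <- "del_suppressed"
    }
  }
  if (detail) list(genome = child, sub_fired = sub_fired, indel = indel)
  else child
}

#' Strip attack instructions from a genome
#'
#' Replaces every attack instruction with the inert `nop-X` symbol, leaving
#' length and all other positions unchanged. Used when purifying prey
#' populations so that no latent attack capability survives. Idempotent.
#'
#' @inheritParams mutate_on_copy
#' @return The genome with zero attack symbols.
#' @export
ban_attack <- function(genome, tab = default_instructions()) {
  genome[genome == attack_code(tab)] <- nop_x_code(tab)
  genome
}
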