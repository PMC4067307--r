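# Diversity and divergence metrics: Shannon's index on genotype-abundance
# tables, global-alignment divergence between a genome and its lineage
# ancestor, and trait-proportion deltas between assay stages.

#' Genotype-abundance table of a population snapshot
#'
#' @param snapshot A population snapshot (see [snapshot()]).
#' @return A data.frame with columns `genotype` and `abundance`, sorted by
#'   decreasing abundance, with attribute `total` (number of organisms).
#' @export
genotype_table <- function(snapshot) {
  tab <- table(snapshot$organisms$genotype)
  out <- data.frame(genotype = names(tab), abundance = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- sum(out$abundance)
  out
}

#' Shannon diversity of a genotype-abundance table
#'
#' Computes H = -sum(p_i * log(p_i)) over genotype frequencies. Natural log
#' by default; the base is exposed because the index is sometimes reported
#' in bits.
#'
#' @param abundance Positive abundances (one per genotype), or a data.frame
#'   with an `abundance` column as returned by [genotype_table()].
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return Shannon's H.
#' @export
shannon_diversity <- function(abundance, base = exp(1)) {
  if (is.data.frame(abundance)) abundance <- abundance$abundance
  if (length(abundance) == 0L) stop("empty genotype table")
  if (any(abundance <= 0)) stop("abundances must be positive")
  p <- abundance / sum(abundance)
  -sum(p * log(p, base = base))
}

#' Global alignment of two genomes
#'
#' Needleman-Wunsch global alignment under a linear gap penalty (defaults:
#' match +1, mismatch -1, gap -1) with deterministic tie-breaking
#' (diagonal > up > left). Percent identity is matches divided by alignment
#' length, so gap columns count as non-matches; divergence is
#' 100 - identity. Alignment is required because insertions and deletions
#' change genome length, so positionwise comparison is meaningless.
#'
#' @param g1,g2 Integer code vectors (non-empty).
#' @param match,mismatch,gap Scoring weights.
#' @return A list with `score`, `matches`, `length` (alignment columns),
#'   `percent_identity` and `divergence` (both on the 0-100 scale).
#' @export
global_align <- function(g1, g2, match = 1, mismatch = -1, gap = -1) {
  if (length(g1) == 0L || length(g2) == 0L) stop("empty genome")
  res <- .nw_align_c(as.integer(g1), as.integer(g2), match, mismatch, gap)
  pid <- 100 * res$matches / res$length
  list(score = res$score, matches = res$matches, length = res$length,
       percent_identity = pid, divergence = 100 - pid)
}

#' Divergence of each organism from its lineage ancestor
#'
#' Every founder of an evolution run carries a unique lineage id inherited
#' by all its progeny; this aligns each genome in `final` to the genome its
#' lineage had in `ancestors` and reports percent divergence per organism
#' plus the population mean.
#'
#' @param final,ancestors Population snapshots; every lineage id present in
#'   `final` must exist in `ancestors`.
#' @param ... Scoring weights passed to [global_align()].
#' @return A list with `table` (data.frame: id, lineage, divergence) and
#'   `mean_divergence`.
#' @export
lineage_divergence <- function(final, ancestors, ...) {
  fo <- final$organisms
  ao <- ancestors$organisms
  idx <- match(fo$lineage, ao$lineage)
  if (anyNA(idx)) {
    orphans <- unique(fo$lineage[is.na(idx)])
    stop("lineage id(s) absent from ancestors: ",
         paste(orphans, collapse = ", "))
  }
  div <- vapply(seq_len(nrow(fo)), function(i) {
    global_align(decode_genome(fo$genome[i]),
                 decode_genome(ao$genome[idx[i]]), ...)$divergence
  }, numeric(1))
  tab <- data.frame(id = fo$id, lineage = fo$lineage, divergence = div,
                    stringsAsFactors = FALSE)
  list(table = tab, mean_divergence = mean(div))
}

#' Change in trait proportions between two assay stages
#'
#' Converts lifetime instruction counts to proportions of total instructions
#' executed (e.g. moves / total) and subtracts the pre-evolution proportions
#' from the post-evolution proportions, per trait. Also reports the raw
#' change in total instructions and in attacks received.
#'
#' @param pre,post Trait-assay records (see [run_trait_assay()]) for the same
#'   population and predator-treatment level.
#' @return A one-row data.frame with `d_moves`, `d_turns`, `d_looks`
#'   (proportion deltas), `d_total` and `d_attacks_received`.
#' @export
trait_deltas <- function(pre, post) {
  if (!identical(pre$population, post$population) ||
      !identical(pre$pt, post$pt))
    stop("pre and post assay records describe different populations")
  prop <- function(rec, what) rec[[what]] / rec$total_instructions
  data.frame(
    population = pre$population, pt = pre$pt,
    d_moves = prop(post, "moves") - prop(pre, "moves"),
    d_turns = prop(post, "turns") - prop(pre, "turns"),
    d_looks = prop(post, "looks") - prop(pre, "looks"),
    d_total = post$total_instructions - pre$total_instructions,
    d_attacks_received = post$attacks_received - pre$attacks_received,
    stringsAsFactors = FALSE
  )
}
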