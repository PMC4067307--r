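# Permutational multivariate ANOVA (PerMANOVA) implemented from its
# definition: Gower-centred distance-matrix decomposition, sequential
# (Type I) sums of squares via projection matrices, pseudo-F ratios, and
# p-values from free random permutation of observations. Also percentile-
# bootstrap summaries of trait deltas.

#' Model (hat) projection matrix
#' @noRd
hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' PerMANOVA on a multivariate response
#'
#' Partitions the total sum of squared distances among model terms fitted
#' sequentially (Type I, in the order given), computes a pseudo-F per term
#' against the residual, and assesses significance by freely permuting the
#' rows of the response. The Gower-centred inner-product matrix
#' `G = -0.5 * C * D^2 * C` carries the decomposition:
#' `SS(term) = trace(H_k G) - trace(H_{k-1} G)` for nested hat matrices
#' `H`, and permuting observations is equivalent to conjugating `G` by the
#' permutation. The p-value convention is
#' `(1 + #(F* >= F)) / (1 + n_perm)`, so the smallest attainable p with 999
#' permutations is 0.001.
#'
#' @param response Numeric matrix (rows = trials) or data.frame of numeric
#'   columns; e.g. the final relative abundances of the two competitors.
#' @param factors A data.frame of factor columns (e.g. SGV, EH, PT), one row
#'   per response row.
#' @param terms Character vector of model terms in fitting order, each
#'   either a factor name or an interaction like `"SGV:EH"`.
#' @param n_perm Number of random permutations (default 999).
#' @param method Distance: `"euclidean"` or `"bray"` (Bray-Curtis).
#' @param permutations Optional integer matrix of row permutations (one
#'   permutation per row), overriding `n_perm`; useful for exhaustive
#'   enumeration or for sharing permutations with another implementation.
#' @return A list of class `permanova_result`: `table` (data.frame with Df,
#'   SumOfSqs, F, p per term plus Residual and Total rows) and
#'   `n_permutations`.
#' @export
permanova <- function(response, factors, terms, n_perm = 999,
                      method = c("euclidean", "bray"),
                      permutations = NULL) {
  method <- match.arg(method)
  Y <- as.matrix(response)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  stopifnot(n == nrow(factors), n >= 3)
  for (f in names(factors)) factors[[f]] <- factor(factors[[f]])
  D <- if (method == "euclidean") as.matrix(stats::dist(Y))
       else {
    if (any(Y < 0)) stop("Bray-Curtis needs non-negative responses")
    num <- as.matrix(stats::dist(Y, method = "manhattan"))
    tot <- outer(rowSums(Y), rowSums(Y), "+")
    out <- num / tot; out[tot == 0] <- 0; out
  }
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C

  # nested design matrices, one per sequential term
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  X <- matrix(1, n, 1)
  rank_prev <- 1L
  for (k in seq_along(terms)) {
    mm <- stats::model.matrix(stats::as.formula(paste("~", terms[k])),
                              data = factors)
    X <- cbind(X, mm[, -1, drop = FALSE])
    q <- qr(X)
    if (q$rank <= rank_prev)
      stop("term ", terms[k], " adds no estimable contrasts ",
           "(empty design cells?)")
    hats[[k]] <- hat_matrix(X)
    dfs[k] <- q$rank - rank_prev
    rank_prev <- q$rank
  }
  df_resid <- n - rank_prev
  if (df_resid <= 0) stop("no residual degrees of freedom")

  ss_from_G <- function(Gm) {
    tr <- sum(diag(Gm))
    h_tr <- vapply(hats, function(H) sum(H * Gm), 0)
    ss <- diff(c(0, h_tr))
    c(ss, tr - h_tr[length(h_tr)], tr)   # terms, residual, total
  }
  obs <- ss_from_G(G)
  ss_terms <- obs[seq_along(terms)]
  ss_resid <- obs[length(terms) + 1L]
  ss_total <- obs[length(terms) + 2L]
  f_obs <- (ss_terms / dfs) / (ss_resid / df_resid)

  if (is.null(permutations)) {
    stopifnot(n_perm >= 1)
    permutations <- t(replicate(n_perm, sample.int(n)))
  }
  n_perm <- nrow(permutations)
  exceed <- numeric(length(terms))
  for (p in seq_len(n_perm)) {
    pr <- permutations[p, ]
    sp <- ss_from_G(G[pr, pr])
    fp <- (sp[seq_along(terms)] / dfs) / (sp[length(terms) + 1L] / df_resid)
    exceed <- exceed + (fp >= f_obs)
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  tab <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(dfs, df_resid, n - 1L),
    SumOfSqs = c(ss_terms, ss_resid, ss_total),
    F = c(f_obs, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, n_permutations = n_perm, method = method),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PerMANOVA (", x$method, " distance, ", x$n_permutations,
      " permutations)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Group means of trait deltas with bootstrap confidence intervals
#'
#' Per-group mean and percentile-bootstrap 95% confidence interval (2,000
#' resamples by default) for each requested response column. Groups with a
#' single replicate get an `NA` interval with a warning.
#'
#' @param deltas A data.frame of per-replicate deltas.
#' @param grouping Character vector of grouping column names.
#' @param vars Character vector of response columns (default: the numeric
#'   columns not in `grouping`).
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @return A data.frame with one row per group x variable: mean, lower,
#'   upper, n.
#' @export
summarize_deltas <- function(deltas, grouping, vars = NULL, n_boot = 2000,
                             conf = 0.95) {
  if (is.null(vars))
    vars <- setdiff(names(deltas)[vapply(deltas, is.numeric, TRUE)],
                    grouping)
  key <- interaction(deltas[grouping], drop = TRUE, sep = ":")
  alpha <- (1 - conf) / 2
  out <- list()
  for (g in levels(key)) {
    sub <- deltas[key == g, , drop = FALSE]
    for (v in vars) {
      x <- sub[[v]]
      if (length(x) < 2L) {
        warning("group ", g, " has a single replicate; CI omitted")
        lo <- hi <- NA_real_
      } else {
        bm <- vapply(seq_len(n_boot), function(b)
          mean(x[sample.int(length(x), replace = TRUE)]), 0)
        qs <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
        lo <- qs[1]; hi <- qs[2]
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, variable = v, mean = mean(x), lower = lo, upper = hi,
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a tidy table for external mixed-model fitting
#'
#' The trait-delta analysis of the full design uses linear mixed-effects
#' models with replicate-level random intercepts and slopes, which are fit
#' with standard model-fitting software outside this package. This writes
#' the per-replicate delta table in the long layout those fits expect.
#'
#' @param deltas Per-replicate delta data.frame (must carry `population`,
#'   `pt` and the delta columns).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_lmm_input <- function(deltas, path) {
  utils::write.csv(deltas, path, row.names = FALSE)
  invisible(path)
}
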