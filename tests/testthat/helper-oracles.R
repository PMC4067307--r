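# Independent oracles and small fixture builders shared across tests.

# Exhaustive global-alignment score by plain recursion over all alignments.
# Independent of the DP implementation; only usable for short sequences.
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    gap = -1) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (a[i] == b[j]) match else mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(a), length(b))
}

# Sector membership decided by vector geometry (dot product against the
# facing unit vector), independent of the bearing arithmetic in the package.
oracle_sector <- function(width, height, x, y, facing, max_range) {
  fx <- c(0, 1, 1, 1, 0, -1, -1, -1)[facing]
  fy <- c(-1, -1, 0, 1, 1, 1, 0, -1)[facing]
  nf <- sqrt(fx^2 + fy^2)
  out <- NULL
  for (cx in 0:(width - 1)) for (cy in 0:(height - 1)) {
    rx <- cx - x; ry <- cy - y
    if (rx == 0 && ry == 0) next
    d <- max(abs(rx), abs(ry))
    if (d > max_range) next
    cosang <- (rx * fx + ry * fy) / (sqrt(rx^2 + ry^2) * nf)
    if (cosang >= cos(22.5 * pi / 180))
      out <- rbind(out, data.frame(x = cx, y = cy, dist = d))
  }
  if (is.null(out)) data.frame(x = integer(), y = integer(),
                               dist = integer())
  else out[order(out$dist, out$y, out$x), , drop = FALSE]
}

# A uniformly random genome over the full alphabet.
uniform_genome <- function(len, n_alpha = 60L) {
  sample.int(n_alpha, len, replace = TRUE)
}

# One organism alone on a small grid; returns list(pop, world, cfg, i).
lone_organism <- function(genome, cfg = sim_config(), grid = 11L,
                          x = 5L, y = 5L, facing = 3L, role = "prey") {
  world <- new_world(grid, grid, regen_delay = cfg$regen_delay)
  pop <- new_population()
  i <- add_organism(pop, genome, x = x, y = y, facing = facing, role = role,
                    lineage = "1")
  list(pop = pop, world = world, cfg = cfg, i = i)
}

# Snapshot of n identical prey carrying the given genome.
clone_snapshot <- function(genome, n, lineage_prefix = "L") {
  org <- data.frame(genome = rep(encode_genome(genome), n),
                    stringsAsFactors = FALSE)
  snap <- as_snapshot(org)
  snap$organisms$lineage <- paste0(lineage_prefix, seq_len(n))
  snap
}

# All permutations of 1..n as a list (n small).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}
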