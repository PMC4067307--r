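make_design <- function(n, seed = 1, effect = 0) {
  set.seed(seed)
  fac <- data.frame(
    SGV = rep(c("clone", "intermediate", "high"), length.out = n),
    EH = rep(c("predator", "no_predator"), length.out = n, each = 3),
    PT = rep(c("present", "absent"), each = n / 2)
  )
  Y <- matrix(stats::rnorm(n * 2), n, 2)
  Y[fac$EH == "predator", 1] <- Y[fac$EH == "predator", 1] + effect
  list(Y = Y, fac = fac)
}

test_that("sums of squares are conserved and deterministic", {
  d <- make_design(24, seed = 91, effect = 1)
  set.seed(1)
  r1 <- permanova(d$Y, d$fac, c("SGV", "EH", "PT"), n_perm = 99)
  set.seed(1)
  r2 <- permanova(d$Y, d$fac, c("SGV", "EH", "PT"), n_perm = 99)
  expect_identical(r1, r2)
  tab <- r1$table
  ss <- tab$SumOfSqs
  expect_equal(sum(ss[1:4]), ss[5], tolerance = 1e-9)
  expect_equal(sum(tab$Df[1:4]), 24 - 1)
  expect_true(all(tab$p[1:3] >= 1 / 100 & tab$p[1:3] <= 1))
})

test_that("a single response column and 2-level factor reduce to ANOVA F", {
  set.seed(92)
  for (k in 1:50) {
    n <- sample(c(8, 12, 16), 1)
    g <- rep(c("a", "b"), n / 2)
    y <- stats::rnorm(n) + (g == "a") * stats::runif(1, 0, 2)
    r <- permanova(matrix(y, ncol = 1), data.frame(G = g), "G", n_perm = 1)
    f_aov <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(r$table$F[1], f_aov, tolerance = 1e-10)
  }
})

test_that("permutation p agrees with exhaustive enumeration at n = 6", {
  set.seed(93)
  y <- matrix(stats::rnorm(12), 6, 2)
  fac <- data.frame(G = rep(c("a", "b"), 3))
  all_perm <- do.call(rbind, lapply(
    combinat_perms(6), function(p) p))
  exact <- permanova(y, fac, "G", permutations = all_perm)
  set.seed(94)
  mc <- permanova(y, fac, "G", n_perm = 999)
  p_exact <- exact$table$p[1]
  p_mc <- mc$table$p[1]
  # Monte Carlo error of a 999-permutation estimate of p_exact
  expect_lt(abs(p_mc - p_exact), 4 * sqrt(p_exact * (1 - p_exact) / 999) +
              2 / 999)
})

test_that("perfectly separated groups reach the minimum attainable p", {
  y <- matrix(c(rep(0, 10), rep(50, 10)), ncol = 1)
  y <- y + stats::rnorm(20, sd = 1e-3)
  fac <- data.frame(G = rep(c("a", "b"), each = 10))
  set.seed(95)
  r <- permanova(y, fac, "G", n_perm = 999)
  expect_equal(r$table$p[1], 0.001)
})

test_that("empty design cells are rejected with an informative error", {
  d <- make_design(12, seed = 96)
  fac <- d$fac
  fac$SGV <- fac$EH          # perfectly confounded factors
  expect_error(permanova(d$Y, fac, c("SGV", "EH"), n_perm = 9),
               "no estimable contrasts")
})

test_that("results match an independent implementation exactly", {
  skip_if_not_installed("vegan")
  d <- make_design(24, seed = 97, effect = 1)
  perm <- t(replicate(199, sample.int(24)))
  mine <- permanova(d$Y, d$fac, c("SGV", "EH", "PT", "SGV:EH"),
                    permutations = perm)
  ad <- vegan::adonis2(d$Y ~ SGV + EH + PT + SGV:EH, data = d$fac,
                       method = "euclidean", permutations = perm,
                       by = "terms")
  expect_equal(mine$table$SumOfSqs[1:4], ad$SumOfSqs[1:4],
               tolerance = 1e-10)
  expect_equal(mine$table$F[1:4], ad$F[1:4], tolerance = 1e-10)
  expect_equal(mine$table$p[1:4], ad$`Pr(>F)`[1:4])
})

test_that("Bray-Curtis distances are supported", {
  skip_if_not_installed("vegan")
  set.seed(98)
  Y <- matrix(stats::runif(24 * 3), 24, 3)
  fac <- data.frame(G = rep(c("a", "b"), 12))
  perm <- t(replicate(99, sample.int(24)))
  mine <- permanova(Y, fac, "G", method = "bray", permutations = perm)
  ad <- vegan::adonis2(Y ~ G, data = fac, method = "bray",
                       permutations = perm, by = "terms")
  expect_equal(mine$table$F[1], ad$F[1], tolerance = 1e-10)
})

test_that("bootstrap delta summaries behave at the edges", {
  df <- data.frame(grp = rep(c("a", "b"), each = 4),
                   d_moves = c(rep(0.5, 4), 1:4))
  set.seed(99)
  s <- summarize_deltas(df, "grp", vars = "d_moves", n_boot = 200)
  a <- s[s$group == "a", ]
  expect_equal(a$mean, 0.5)
  expect_equal(a$lower, 0.5)
  expect_equal(a$upper, 0.5)
  b <- s[s$group == "b", ]
  expect_equal(b$mean, 2.5)
  expect_lt(b$lower, b$mean); expect_gt(b$upper, b$mean)
  # permutation invariance of the group means
  df2 <- df[sample(nrow(df)), ]
  set.seed(99)
  s2 <- summarize_deltas(df2, "grp", vars = "d_moves", n_boot = 200)
  expect_equal(s2$mean[order(s2$group)], s$mean[order(s$group)])
  single <- data.frame(grp = c("a", "a", "b"), v = c(1, 2, 3))
  expect_warning(summarize_deltas(single, "grp", vars = "v", n_boot = 50),
                 "single replicate")
})

test_that("bootstrap intervals cover a known mean at near-nominal rate", {
  set.seed(100)
  hits <- 0L
  n_sim <- 300L
  for (k in seq_len(n_sim)) {
    x <- stats::rnorm(30, mean = 1, sd = 1)
    df <- data.frame(grp = "g", v = x)
    s <- suppressWarnings(summarize_deltas(df, "grp", vars = "v",
                                           n_boot = 300))
    if (s$lower <= 1 && s$upper >= 1) hits <- hits + 1L
  }
  cover <- hits / n_sim
  # percentile bootstrap at n = 30 runs slightly under nominal
  expect_gt(cover, 0.95 - 4 * sqrt(0.95 * 0.05 / n_sim) - 0.02)
  expect_lte(cover, 1)
})
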