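test_that("Euclidean distances match a brute-force double loop", {
  X <- matrix(c(1, 1, 1, 1), 2, 2, byrow = TRUE)
  expect_true(all(euclidean_matrix(X) == 0))
  expect_equal(euclidean_matrix(matrix(c(2, 7)))[1, 2], 5)
  set.seed(51)
  for (case in 1:100) {
    X <- matrix(rnorm(8 * 5), 8, 5)
    expect_equal(unname(euclidean_matrix(X)), brute_euclidean(X),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # column normalisation: z-scored columns, constant column rejected
  X <- cbind(rnorm(6), rnorm(6, sd = 100))
  Dn <- euclidean_matrix(X, normalize_columns = TRUE)
  expect_equal(unname(Dn), brute_euclidean(scale(X)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(euclidean_matrix(cbind(1:5, rep(2, 5)),
                                normalize_columns = TRUE), "constant")
})

test_that("Bray-Curtis dissimilarities follow the definition", {
  X <- rbind(c(3, 1, 4), c(3, 1, 4))
  expect_true(all(bray_curtis_matrix(X, fourth_root = FALSE) == 0))
  Xd <- rbind(c(5, 0, 2), c(0, 3, 0))
  expect_equal(bray_curtis_matrix(Xd, fourth_root = FALSE)[1, 2], 1)
  expect_equal(bray_curtis_matrix(rbind(c(1, 3), c(2, 1)),
                                  fourth_root = FALSE)[1, 2], 3 / 7)
  set.seed(52)
  C <- matrix(rpois(40, 5) + 1, 8, 5)
  expect_equal(unname(bray_curtis_matrix(C, fourth_root = TRUE)),
               brute_bray(C^0.25), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(bray_curtis_matrix(rbind(c(0, 0), c(1, 2))), "all-zero")
  expect_error(bray_curtis_matrix(rbind(c(-1, 2), c(1, 2))), "non-negative")
})

test_that("one-way pseudo-F equals classical ANOVA F on univariate data", {
  set.seed(53)
  for (case in 1:20) {
    g <- rep(c("a", "b", "c"), times = sample(3:6, 3, replace = TRUE))
    y <- rnorm(length(g)) + as.numeric(factor(g)) * runif(1, 0, 1.5)
    pm <- permanova_oneway(euclidean_matrix(matrix(y)), g, n_perm = 0)
    expect_equal(pm$table$pseudo_F[1], aov_oneway_F(y, g), tolerance = 1e-9)
    expect_equal(sum(pm$table$SS[1:2]), pm$table$SS[3], tolerance = 1e-9)
  }
})

test_that("one-way permutation p is well behaved", {
  set.seed(54)
  y <- c(rnorm(5), rnorm(5, 4))
  g <- rep(c("a", "b"), each = 5)
  D <- euclidean_matrix(matrix(y))
  pm1 <- permanova_oneway(D, g, n_perm = 499, seed = 9)
  pm2 <- permanova_oneway(D, g, n_perm = 499, seed = 9)
  expect_identical(pm1$table$p_perm, pm2$table$p_perm)
  expect_gte(pm1$table$p_perm[1], 1 / 500)
  expect_error(permanova_oneway(D, c(rep("a", 9), "b")), "two members")
  # all observations identical: degenerate, no test
  Dz <- euclidean_matrix(matrix(rep(1, 10)))
  expect_true(permanova_oneway(Dz, g, n_perm = 99)$degenerate)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on 2x3 designs", {
  set.seed(55)
  for (case in 1:5) {
    y <- rnorm(6) + rep(c(0, runif(1, 0, 3)), each = 3)
    g <- rep(c("a", "b"), each = 3)
    D <- euclidean_matrix(matrix(y))
    p_exact <- enumerate_twogroup_p(D, g)
    p_mc <- permanova_oneway(D, g, n_perm = 9999, seed = case)$table$p_perm[1]
    expect_lt(abs(p_mc - p_exact), 0.02)
  }
})

test_that("nested pseudo-F ratios equal the classical nested ANOVA", {
  set.seed(56)
  for (case in 1:20) {
    a <- sample(3:5, 1); b <- sample(2:4, 1); r <- sample(2:4, 1)
    cy <- rep(sprintf("C%d", seq_len(a)), each = b * r)
    ti <- rep(sprintf("C%dT%d", rep(seq_len(a), each = b), seq_len(b)), each = r)
    y <- rnorm(a * b * r) + rep(rnorm(a, sd = runif(1, 0, 2)), each = b * r) +
      rep(rnorm(a * b, sd = runif(1, 0, 2)), each = r)
    pn <- permanova_nested(euclidean_matrix(matrix(y)), cy, ti, n_perm = 0)
    ref <- aov_nested_F(y, cy, ti)
    expect_equal(pn$table$pseudo_F[1], unname(ref["F_cy"]), tolerance = 1e-9)
    expect_equal(pn$table$pseudo_F[2], unname(ref["F_ti"]), tolerance = 1e-9)
    expect_equal(sum(pn$table$SS[1:3]), pn$table$SS[4], tolerance = 1e-9)
  }
  # nesting violations and degenerate data are reported
  cy <- rep(c("C1", "C2"), each = 4)
  ti_bad <- rep(c("T1", "T2"), times = 4)   # T1 occurs in both cycles
  D <- euclidean_matrix(matrix(rnorm(8)))
  expect_error(permanova_nested(D, cy, ti_bad, 99), "nested")
  ti_ok <- rep(c("C1T1", "C1T2", "C2T1", "C2T2"), each = 2)
  Dz <- euclidean_matrix(matrix(rep(2, 8)))
  expect_true(permanova_nested(Dz, cy, ti_ok, n_perm = 9)$degenerate)
})

test_that("a pure time-within-cycle signal is attributed to the nested term", {
  res <- vapply(1:40, function(s) {
    fs <- generate_field_survey(beta_current = 0, beta_zoo = 0,
                                cycle_sd = 0, time_sd = 10, seed = 900 + s)
    D <- euclidean_matrix(matrix(fs$expansion_pct))
    pn <- permanova_nested(D, fs$cycle, fs$time, n_perm = 199, seed = s)
    c(ti = pn$table$p_perm[2] <= 0.05, cy = pn$table$p_perm[1] <= 0.05)
  }, logical(2))
  expect_gte(mean(res["ti", ] & !res["cy", ]), 0.75)
  expect_gte(mean(res["ti", ]), 0.9)
})

test_that("two-way SS partition equals classical two-way ANOVA", {
  set.seed(57)
  for (case in 1:20) {
    a <- sample(2:4, 1); b <- sample(2:4, 1); r <- sample(2:4, 1)
    fa <- rep(sprintf("a%d", seq_len(a)), each = b * r)
    fb <- rep(rep(sprintf("b%d", seq_len(b)), each = r), a)
    y <- rnorm(a * b * r) + as.numeric(factor(fa)) * runif(1, 0, 2) +
      as.numeric(factor(fa)) * as.numeric(factor(fb)) * runif(1, 0, 1)
    pt <- permanova_twoway(euclidean_matrix(matrix(y)), fa, fb, n_perm = 0)
    ref <- aov_twoway(y, fa, fb)
    expect_equal(pt$table$SS[1:4], ref[, "Sum Sq"], tolerance = 1e-9)
    expect_equal(pt$table$pseudo_F[1:3], ref[1:3, "F value"], tolerance = 1e-9)
    expect_equal(sum(pt$table$SS[1:4]), pt$table$SS[5], tolerance = 1e-9)
    # swapping factor roles swaps the main-effect SS, interaction unchanged
    sw <- permanova_twoway(euclidean_matrix(matrix(y)), fb, fa, n_perm = 0)
    expect_equal(sw$table$SS[1], pt$table$SS[2], tolerance = 1e-9)
    expect_equal(sw$table$SS[2], pt$table$SS[1], tolerance = 1e-9)
    expect_equal(sw$table$SS[3], pt$table$SS[3], tolerance = 1e-9)
  }
  expect_error(permanova_twoway(euclidean_matrix(matrix(rnorm(6))),
                                rep(c("a", "b"), 3), rep(c("x", "y", "z"), 2),
                                n_perm = 9), "balanced")
})

test_that("one-way pseudo-F matches vegan's adonis2 on multivariate data", {
  set.seed(58)
  X <- matrix(rnorm(60), 20, 3)
  g <- rep(c("u", "v"), each = 10)
  D <- euclidean_matrix(X)
  mine <- permanova_oneway(D, g, n_perm = 999, seed = 2)
  ref <- vegan::adonis2(stats::as.dist(D) ~ g, permutations = 999)
  expect_equal(mine$table$pseudo_F[1], ref$F[1], tolerance = 1e-9)
  expect_equal(mine$table$SS[1], ref$SumOfSqs[1], tolerance = 1e-9)
})

test_that("pairwise tests report t, permutation and Monte-Carlo p per pair", {
  # mirrored groups: zero among-group SS, t = 0, permutation p near 1
  y <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  pw <- pairwise_tests(euclidean_matrix(matrix(y)), g, n_perm = 499, seed = 1)
  expect_equal(pw$t, 0, tolerance = 1e-9)
  expect_gte(pw$p_perm, 0.95)

  # five cycles give choose(5, 2) = 10 pairs
  set.seed(59)
  y5 <- rnorm(20)
  g5 <- rep(sprintf("C%d", 1:5), each = 4)
  pw5 <- pairwise_tests(euclidean_matrix(matrix(y5)), g5,
                        n_perm = 99, seed = 1, n_mc = 99)
  expect_equal(nrow(pw5), 10)

  # two groups of 3: 10 unique relabellings, flagged; the permutation p
  # bottoms out near 1/10 while the Monte-Carlo p can go lower
  ysep <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  pws <- pairwise_tests(euclidean_matrix(matrix(ysep)), g,
                        n_perm = 9999, seed = 3)
  expect_equal(pws$unique_perms, 10)
  expect_true(pws$low_perms)
  expect_lt(abs(pws$p_perm - 0.1), 0.02)
  expect_lt(pws$p_mc, pws$p_perm)
})

test_that("SIMPER contributions decompose the average Bray-Curtis dissimilarity", {
  set.seed(60)
  z <- generate_zooplankton_counts(seed = 13)
  sim <- simper(z$counts, z$cycle)
  for (nm in names(sim)) {
    s <- sim[[nm]]
    expect_equal(sum(s$contributions$contribution_pct),
                 s$average_dissimilarity_pct, tolerance = 1e-12)
    expect_true(all(diff(s$contributions$contribution_pct) <= 1e-12))
    expect_equal(s$contributions$cumulative_rel_pct[nrow(s$contributions)],
                 100, tolerance = 1e-9)
    # the pair's average dissimilarity equals the mean inter-group
    # Bray-Curtis distance computed independently
    gs <- strsplit(nm, "_vs_")[[1]]
    D <- bray_curtis_matrix(z$counts)
    i <- which(z$cycle == gs[1]); j <- which(z$cycle == gs[2])
    expect_equal(s$average_dissimilarity_pct, 100 * mean(D[i, j]),
                 tolerance = 1e-9)
  }

  # a taxon exclusive to one group dominates the pair's contributions
  X <- rbind(c(10, 5, 0), c(12, 6, 0), c(10, 5, 40), c(11, 6, 45))
  colnames(X) <- c("taxA", "taxB", "taxC")
  se <- simper(X, c("g1", "g1", "g2", "g2"), fourth_root = FALSE)
  expect_identical(se$g1_vs_g2$contributions$taxon[1], "taxC")

  # two-samples-per-group toy table against a hand computation of the
  # four inter-group pairs
  Y <- rbind(c(1, 2), c(2, 1), c(4, 0), c(3, 3))
  colnames(Y) <- c("u", "v")
  sh <- simper(Y, c("A", "A", "B", "B"), fourth_root = FALSE)
  hand <- matrix(0, 2, 2)  # pairs x taxa
  pairs <- list(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
  contrib <- c(u = 0, v = 0)
  for (p in pairs) {
    denom <- sum(Y[p[1], ] + Y[p[2], ])
    contrib <- contrib + abs(Y[p[1], ] - Y[p[2], ]) / denom
  }
  contrib <- 100 * contrib / 4
  got <- sh$A_vs_B$contributions
  expect_equal(got$contribution_pct[match(c("u", "v"), got$taxon)],
               unname(contrib), tolerance = 1e-12)
  expect_equal(sh$A_vs_B$average_dissimilarity_pct, sum(contrib),
               tolerance = 1e-12)
})

test_that("SIMPER ordering and averages agree with vegan's implementation", {
  z <- generate_zooplankton_counts(seed = 17)
  keep <- z$cycle %in% c("C1", "C5")
  mine <- simper(z$counts[keep, ], droplevels(z$cycle[keep]))
  ref <- vegan::simper(z$counts[keep, ]^0.25, droplevels(z$cycle[keep]),
                       permutations = 0)
  ref_sum <- summary(ref)[[1]]
  expect_equal(mine$C1_vs_C5$average_dissimilarity_pct,
               100 * sum(ref_sum$average), tolerance = 1e-9)
  expect_identical(mine$C1_vs_C5$contributions$taxon, rownames(ref_sum))
})

test_that("series summaries use the sample standard deviation", {
  s <- summarize_series(c(1, 2, 3))
  expect_equal(unname(s), c(1, 3, 2, 1))
  expect_equal(unname(summarize_series(rep(7, 5))["sd"]), 0)
  expect_equal(unname(summarize_series(c(NA, 2, 4))[c("mean", "min")]), c(3, 2))
})
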