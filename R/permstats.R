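# Distance-based permutational statistics: Euclidean and Bray-Curtis
# matrices, one-way / nested / two-way crossed PERMANOVA, pairwise tests
# with Monte-Carlo p-values, SIMPER, and series summaries.

# ---- distance matrices ------------------------------------------------------

check_distance_matrix <- function(D, metric) {
  abort_if(!isSymmetric(unname(D), tol = 1e-10), "distance matrix not symmetric")
  abort_if(any(diag(D) != 0), "distance matrix diagonal not zero")
  abort_if(any(D < -1e-12), "negative dissimilarities")
  if (metric == "bray_curtis") {
    abort_if(any(D > 1 + 1e-12), "Bray-Curtis values must lie in [0, 1]")
  }
  invisible(D)
}

#' Euclidean distance matrix, optionally on normalised columns
#'
#' Pairwise Euclidean distances between sample rows. With
#' `normalize_columns = TRUE` each column is z-scored (mean 0, SD 1) first,
#' the convention used for variables on different measurement scales (e.g. a
#' seston-composition table mixing chlorophyll and protein concentrations).
#'
#' @param table Numeric matrix or data frame, samples in rows.
#' @param normalize_columns Z-score columns before computing distances.
#' @return n x n numeric matrix with attribute `metric = "euclidean"`.
#' @export
euclidean_matrix <- function(table, normalize_columns = FALSE) {
  m <- as.matrix(table)
  abort_if(!is.numeric(m), "table must be numeric")
  if (normalize_columns) {
    sds <- apply(m, 2, stats::sd)
    abort_if(any(sds == 0), "constant column cannot be normalised")
    m <- scale(m)
  }
  D <- as.matrix(stats::dist(m, method = "euclidean"))
  attr(D, "metric") <- "euclidean"
  check_distance_matrix(D, "euclidean")
}

#' Bray-Curtis dissimilarity matrix on (optionally fourth-root) counts
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed after an optional
#' fourth-root transform that down-weights the most abundant taxa.
#'
#' @param counts Non-negative matrix or data frame, samples in rows; every
#'   sample must have at least one positive entry.
#' @param fourth_root Apply x^(1/4) before the dissimilarity (default TRUE).
#' @return n x n numeric matrix with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis_matrix <- function(counts, fourth_root = TRUE) {
  m <- as.matrix(counts)
  abort_if(!is.numeric(m), "counts must be numeric")
  abort_if(any(m < 0), "counts must be non-negative")
  abort_if(any(rowSums(m) == 0),
           "all-zero sample: Bray-Curtis dissimilarity undefined")
  if (fourth_root) m <- m^0.25
  D <- as.matrix(vegan::vegdist(m, method = "bray"))
  attr(D, "metric") <- "bray_curtis"
  check_distance_matrix(D, "bray_curtis")
}

# ---- PERMANOVA core ---------------------------------------------------------

# SS_total = (1/n) sum_{i<j} d_ij^2
ss_total_from_d2 <- function(D2) sum(D2) / (2 * nrow(D2))

# SS within groups = sum_g (1/n_g) sum_{i<j in g} d_ij^2
ss_within_groups <- function(D2, groups) {
  s <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

# Vectorised permutation distribution of SS_within under column-wise
# permuted labels. `perm_labels` is an n x n_perm integer matrix of group
# indices; returns a vector of SS_within per permutation.
ss_within_batch <- function(D2, perm_labels, group_sizes) {
  n_perm <- ncol(perm_labels)
  ssw <- numeric(n_perm)
  for (g in seq_along(group_sizes)) {
    B <- matrix(as.numeric(perm_labels == g), nrow(perm_labels), n_perm)
    ssw <- ssw + colSums(B * (D2 %*% B)) / (2 * group_sizes[g])
  }
  ssw
}

permanova_table <- function(terms, df, ss, ms, f, p, n_perm, design,
                            degenerate = FALSE) {
  tab <- data.frame(term = terms, df = df, SS = ss, MS = ms,
                    pseudo_F = f, p_perm = p, n_perm = n_perm)
  structure(list(table = tab, design = design, degenerate = degenerate),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s design)%s\n", x$design,
              if (x$degenerate) " -- DEGENERATE (zero total SS)" else ""))
  print(format(x$table, digits = 5), row.names = FALSE)
  invisible(x)
}

#' One-way PERMANOVA
#'
#' Distance-based one-way permutational ANOVA: the total sum of squares
#' (1/n) sum_{i<j} d_ij^2 is split into among- and within-group parts and
#' pseudo-F = (SS_among / (a-1)) / (SS_within / (n-a)) is referred to its
#' permutation distribution under random relabelling of samples. On
#' Euclidean distances from univariate data the pseudo-F equals the
#' classical ANOVA F.
#'
#' @param D Distance matrix (n x n).
#' @param groups Factor (or coercible) of group labels, length n; at least
#'   two groups with at least two members each.
#' @param n_perm Number of permutations (default 9999; 0 skips the test and
#'   reports only the partition).
#' @param seed Integer seed for the permutations.
#' @return A `permanova` object; p-value is (1 + #\{F* >= F\}) / (1 + n_perm).
#' @export
permanova_oneway <- function(D, groups, n_perm = 9999, seed = 1) {
  D <- as.matrix(D)
  groups <- droplevels(as.factor(groups))
  n <- nrow(D)
  abort_if(length(groups) != n, "groups length must match distance matrix")
  a <- nlevels(groups)
  abort_if(a < 2, "need at least two groups")
  sizes <- table(groups)
  abort_if(any(sizes < 2), "every group needs at least two members")
  D2 <- D^2
  sst <- ss_total_from_d2(D2)
  ssw <- ss_within_groups(D2, groups)
  ssa <- sst - ssw
  df_a <- a - 1; df_r <- n - a
  if (sst <= .Machine$double.eps * n) {
    return(permanova_table(c("groups", "residual", "total"),
                           c(df_a, df_r, n - 1), c(0, 0, 0),
                           c(NA, NA, NA), c(NA, NA, NA), c(NA, NA, NA),
                           n_perm, "oneway", degenerate = TRUE))
  }
  f_obs <- (ssa / df_a) / (ssw / df_r)
  p <- NA_real_
  if (n_perm > 0) {
    gi <- as.integer(groups)
    perm_labels <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample(gi), integer(n))
    })
    ssw_perm <- ss_within_batch(D2, perm_labels, as.numeric(sizes))
    f_perm <- ((sst - ssw_perm) / df_a) / (ssw_perm / df_r)
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  }
  permanova_table(c("groups", "residual", "total"),
                  c(df_a, df_r, n - 1),
                  c(ssa, ssw, sst),
                  c(ssa / df_a, ssw / df_r, NA),
                  c(f_obs, NA, NA), c(p, NA, NA), n_perm, "oneway")
}

#' Nested PERMANOVA (fixed factor with a nested random factor)
#'
#' Two-level hierarchical design such as Cycle with Time nested in Cycle:
#' SS is partitioned hierarchically (among cycles; among time cells within
#' cycles; residual within cells). The upper-level F uses the nested mean
#' square as denominator (F_Cy = MS_Cy / MS_Ti(Cy)), the nested F uses the
#' residual (F_Ti = MS_Ti(Cy) / MS_res). Permutation respects
#' exchangeability: whole time cells are permuted across cycles for the
#' upper-level test; observations are permuted within cycles for the nested
#' test.
#'
#' @param D Distance matrix.
#' @param cycles Upper-level factor, length n.
#' @param times Nested factor; every level must occur in exactly one cycle.
#'   Design must be balanced (equal cells per cycle, equal replicates).
#' @param n_perm,seed Permutation settings.
#' @return A `permanova` object with terms `cycle`, `time(cycle)`,
#'   `residual`, `total`.
#' @export
permanova_nested <- function(D, cycles, times, n_perm = 9999, seed = 1) {
  D <- as.matrix(D)
  cycles <- droplevels(as.factor(cycles))
  times <- droplevels(as.factor(times))
  n <- nrow(D)
  abort_if(length(cycles) != n || length(times) != n,
           "factor lengths must match distance matrix")
  # nesting: each time level inside exactly one cycle
  map <- table(times, cycles) > 0
  abort_if(any(rowSums(map) != 1),
           "times must be nested: each time level in exactly one cycle")
  a <- nlevels(cycles)
  b_per <- table(colSums(map))
  abort_if(length(b_per) != 1, "unbalanced: unequal time cells per cycle")
  b <- as.integer(names(b_per))
  cell_sizes <- table(times)
  abort_if(length(unique(cell_sizes)) != 1, "unbalanced cell sizes")
  r <- as.integer(cell_sizes[1])
  abort_if(a < 2 || b < 2 || r < 2,
           "need >= 2 cycles, >= 2 cells per cycle, >= 2 replicates")

  D2 <- D^2
  sst <- ss_total_from_d2(D2)
  ssw_cy <- ss_within_groups(D2, cycles)
  ssw_cell <- ss_within_groups(D2, times)
  ss_cy <- sst - ssw_cy
  ss_ti <- ssw_cy - ssw_cell
  ss_res <- ssw_cell
  df_cy <- a - 1; df_ti <- a * (b - 1); df_res <- a * b * (r - 1)
  terms <- c("cycle", "time(cycle)", "residual", "total")
  if (sst <= .Machine$double.eps * n) {
    return(permanova_table(terms, c(df_cy, df_ti, df_res, n - 1),
                           rep(0, 4), rep(NA, 4), rep(NA, 4), rep(NA, 4),
                           n_perm, "nested", degenerate = TRUE))
  }
  ms_cy <- ss_cy / df_cy; ms_ti <- ss_ti / df_ti; ms_res <- ss_res / df_res
  f_cy <- ms_cy / ms_ti
  f_ti <- ms_ti / ms_res
  p_cy <- p_ti <- NA_real_
  if (n_perm > 0) {
    # cell-level squared-distance cross sums: Q[c1, c2] = sum d^2 over pairs
    cell_idx <- split(seq_len(n), times)
    n_cells <- length(cell_idx)
    Q <- matrix(0, n_cells, n_cells)
    for (i in seq_len(n_cells)) for (j in seq_len(n_cells)) {
      Q[i, j] <- sum(D2[cell_idx[[i]], cell_idx[[j]]])
    }
    cell_cycle <- apply(map, 1, which)       # cycle index of each cell
    n_cy_obs <- b * r
    p_cy <- with_seed(seed, {
      f_perm <- vapply(seq_len(n_perm), function(k) {
        perm_cy <- sample(cell_cycle)
        ssw_cy_p <- 0
        for (cy in seq_len(a)) {
          cells <- which(perm_cy == cy)
          ssw_cy_p <- ssw_cy_p + sum(Q[cells, cells]) / (2 * n_cy_obs)
        }
        ss_cy_p <- sst - ssw_cy_p
        ss_ti_p <- ssw_cy_p - ssw_cell
        (ss_cy_p / df_cy) / (ss_ti_p / df_ti)
      }, numeric(1))
      (1 + sum(f_perm >= f_cy)) / (1 + n_perm)
    })
    # nested test: shuffle observations across cells within each cycle
    cyc_idx <- split(seq_len(n), cycles)
    ti_int <- as.integer(times)
    p_ti <- with_seed(seed + 1L, {
      perm_labels <- vapply(seq_len(n_perm), function(k) {
        lab <- ti_int
        for (ci in cyc_idx) lab[ci] <- sample(lab[ci])
        lab
      }, integer(n))
      ssw_cell_p <- ss_within_batch(D2, perm_labels,
                                    as.numeric(table(ti_int)))
      f_perm <- ((ssw_cy - ssw_cell_p) / df_ti) / (ssw_cell_p / df_res)
      (1 + sum(f_perm >= f_ti)) / (1 + n_perm)
    })
  }
  permanova_table(terms, c(df_cy, df_ti, df_res, n - 1),
                  c(ss_cy, ss_ti, ss_res, sst),
                  c(ms_cy, ms_ti, ms_res, NA),
                  c(f_cy, f_ti, NA, NA),
                  c(p_cy, p_ti, NA, NA), n_perm, "nested")
}

# Projector onto the column space of a factor's indicator matrix
# (block-mean projector).
factor_projector <- function(f) {
  U <- stats::model.matrix(~ f - 1)
  U %*% diag(1 / colSums(U)) %*% t(U)
}

#' Two-way crossed PERMANOVA with interaction
#'
#' Balanced two-factor factorial: sums of squares come from the trace of the
#' term projectors applied to the Gower-centred inner-product matrix
#' G = -(1/2) J D^2 J, which reduces to the classical two-way ANOVA
#' partition on Euclidean univariate data. All F ratios use the residual
#' mean square. Main-effect p-values use unrestricted permutation of
#' samples; the interaction p-value permutes residuals of the reduced
#' (main-effects-only) model (Freedman-Lane).
#'
#' @param D Distance matrix.
#' @param factor_a,factor_b Crossed factors, length n; design must be
#'   balanced with at least two replicates per cell.
#' @param n_perm,seed Permutation settings.
#' @param term_labels Optional length-2 character vector naming the two
#'   factors in the output table; defaults to the supplied expressions when
#'   those are simple names, otherwise `A` and `B`.
#' @return A `permanova` object with terms `A`, `B`, `A:B`, `residual`,
#'   `total`.
#' @export
permanova_twoway <- function(D, factor_a, factor_b, n_perm = 9999, seed = 1,
                             term_labels = NULL) {
  if (is.null(term_labels)) {
    term_labels <- c(deparse(substitute(factor_a))[1],
                     deparse(substitute(factor_b))[1])
    if (any(nchar(term_labels) > 24 | grepl("[^A-Za-z0-9._$]", term_labels))) {
      term_labels <- c("A", "B")
    }
  }
  abort_if(length(term_labels) != 2, "term_labels must have length 2")
  name_a <- term_labels[1]
  name_b <- term_labels[2]
  D <- as.matrix(D)
  fa <- droplevels(as.factor(factor_a))
  fb <- droplevels(as.factor(factor_b))
  n <- nrow(D)
  abort_if(length(fa) != n || length(fb) != n,
           "factor lengths must match distance matrix")
  cell <- interaction(fa, fb, drop = FALSE)
  cs <- table(cell)
  abort_if(length(unique(cs)) != 1 || any(cs < 2),
           "design must be balanced and crossed with >= 2 replicates per cell")
  a <- nlevels(fa); b <- nlevels(fb); r <- as.integer(cs[1])

  D2 <- D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D2 %*% J
  H1 <- matrix(1 / n, n, n)
  HA <- factor_projector(fa); HB <- factor_projector(fb)
  Hcell <- factor_projector(cell)
  PA <- HA - H1; PB <- HB - H1
  PAB <- Hcell - HA - HB + H1
  Pres <- diag(n) - Hcell

  ss <- function(P, M) max(sum(P * M), 0)  # tr(P M) for symmetric P, M
  sst <- sum(diag(G))
  ss_a <- ss(PA, G); ss_b <- ss(PB, G); ss_ab <- ss(PAB, G)
  ss_res <- ss(Pres, G)
  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b
  df_res <- a * b * (r - 1)
  terms <- c(name_a, name_b, paste0(name_a, ":", name_b), "residual", "total")
  if (sst <= .Machine$double.eps * n) {
    return(permanova_table(terms, c(df_a, df_b, df_ab, df_res, n - 1),
                           rep(0, 5), rep(NA, 5), rep(NA, 5), rep(NA, 5),
                           n_perm, "twoway", degenerate = TRUE))
  }
  ms_res <- ss_res / df_res
  f_a <- (ss_a / df_a) / ms_res
  f_b <- (ss_b / df_b) / ms_res
  f_ab <- (ss_ab / df_ab) / ms_res
  p_a <- p_b <- p_ab <- NA_real_
  if (n_perm > 0) {
    # main effects: unrestricted sample permutation
    main <- with_seed(seed, {
      fa_perm <- numeric(n_perm); fb_perm <- numeric(n_perm)
      for (k in seq_len(n_perm)) {
        pi <- sample.int(n)
        Gp <- G[pi, pi]
        res_p <- max(sum(Pres * Gp), 0) / df_res
        fa_perm[k] <- (max(sum(PA * Gp), 0) / df_a) / res_p
        fb_perm[k] <- (max(sum(PB * Gp), 0) / df_b) / res_p
      }
      c((1 + sum(fa_perm >= f_a)) / (1 + n_perm),
        (1 + sum(fb_perm >= f_b)) / (1 + n_perm))
    })
    p_a <- main[1]; p_b <- main[2]
    # interaction: Freedman-Lane permutation of reduced-model residuals.
    # With Q = I - (HA + HB - H1), E = Q G Q; because PAB and Pres are
    # orthogonal to the reduced-model space, the permuted statistic only
    # needs E reindexed.
    Qr <- diag(n) - (HA + HB - H1)
    E <- Qr %*% G %*% Qr
    p_ab <- with_seed(seed + 1L, {
      f_perm <- vapply(seq_len(n_perm), function(k) {
        pi <- sample.int(n)
        Ep <- E[pi, pi]
        (max(sum(PAB * Ep), 0) / df_ab) /
          (max(sum(Pres * Ep), 0) / df_res)
      }, numeric(1))
      (1 + sum(f_perm >= f_ab)) / (1 + n_perm)
    })
  }
  permanova_table(terms, c(df_a, df_b, df_ab, df_res, n - 1),
                  c(ss_a, ss_b, ss_ab, ss_res, sst),
                  c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab, ms_res, NA),
                  c(f_a, f_b, f_ab, NA, NA),
                  c(p_a, p_b, p_ab, NA, NA), n_perm, "twoway")
}

#' Pairwise permutational tests with Monte-Carlo p-values
#'
#' For every pair of group levels, a two-group PERMANOVA gives
#' t = sqrt(pseudo-F) and a permutation p-value. Because small groups admit
#' few unique relabellings (choose(n1 + n2, n1), halved for equal sizes),
#' a Monte-Carlo p-value is also reported, obtained by comparing t with
#' random draws from the t distribution with n1 + n2 - 2 degrees of freedom
#' (an asymptotic reference, flagged in the output); pairs with fewer than
#' 100 unique relabellings are flagged.
#'
#' @param D Distance matrix.
#' @param groups Group factor, length n.
#' @param n_perm Permutations per pair (default 9999).
#' @param seed Integer seed.
#' @param n_mc Monte-Carlo reference draws (default 9999).
#' @return Data frame: `group1`, `group2`, `t`, `df`, `p_perm`, `p_mc`,
#'   `unique_perms`, `low_perms` (TRUE when unique relabellings < 100).
#' @export
pairwise_tests <- function(D, groups, n_perm = 9999, seed = 1, n_mc = 9999) {
  D <- as.matrix(D)
  groups <- droplevels(as.factor(groups))
  abort_if(nlevels(groups) < 2, "need at least two groups")
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    idx <- which(groups %in% c(g1, g2))
    sub <- permanova_oneway(D[idx, idx], groups[idx],
                            n_perm = n_perm, seed = seed + k)
    f <- sub$table$pseudo_F[1]
    t_obs <- if (is.na(f)) NA_real_ else sqrt(max(f, 0))
    n1 <- sum(groups[idx] == g1); n2 <- sum(groups[idx] == g2)
    uniq <- choose(n1 + n2, n1) / (if (n1 == n2) 2 else 1)
    df <- n1 + n2 - 2
    p_mc <- if (is.na(t_obs)) NA_real_ else with_seed(seed + 1000L + k, {
      draws <- abs(stats::rt(n_mc, df))
      (1 + sum(draws >= t_obs)) / (1 + n_mc)
    })
    out[[k]] <- data.frame(group1 = g1, group2 = g2, t = t_obs, df = df,
                           p_perm = sub$table$p_perm[1], p_mc = p_mc,
                           unique_perms = uniq, low_perms = uniq < 100)
  }
  do.call(rbind, out)
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' For each pair of groups the average Bray-Curtis dissimilarity over all
#' inter-group sample pairs is decomposed into per-taxon contributions
#' delta_i = mean over pairs of |x_i - y_i| / sum_k (x_k + y_k). The
#' contributions sum exactly to the pair's average dissimilarity.
#'
#' @param counts Non-negative samples x taxa matrix.
#' @param groups Group factor, length nrow(counts).
#' @param fourth_root Apply x^(1/4) before the decomposition (default TRUE,
#'   matching the dissimilarities used for the accompanying tests).
#' @return Object of class `simper_result`: list keyed `<g1>_vs_<g2>`, each
#'   with `average_dissimilarity_pct` and `contributions` (data frame:
#'   `taxon`, `contribution_pct` in dissimilarity percent points,
#'   `contribution_rel_pct` relative share, `cumulative_rel_pct`; sorted
#'   descending).
#' @export
simper <- function(counts, groups, fourth_root = TRUE) {
  m <- as.matrix(counts)
  abort_if(any(m < 0), "counts must be non-negative")
  groups <- droplevels(as.factor(groups))
  abort_if(nrow(m) != length(groups), "groups length must match counts rows")
  abort_if(nlevels(groups) < 2, "need at least two groups")
  abort_if(any(rowSums(m) == 0), "all-zero sample: dissimilarity undefined")
  if (fourth_root) m <- m^0.25
  taxa <- colnames(m)
  if (is.null(taxa)) taxa <- sprintf("taxon_%02d", seq_len(ncol(m)))
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  res <- list()
  for (k in seq_len(ncol(pairs))) {
    g1 <- which(groups == pairs[1, k])
    g2 <- which(groups == pairs[2, k])
    contrib <- numeric(ncol(m))
    for (i in g1) for (j in g2) {
      denom <- sum(m[i, ] + m[j, ])
      contrib <- contrib + abs(m[i, ] - m[j, ]) / denom
    }
    contrib <- 100 * contrib / (length(g1) * length(g2))
    avg <- sum(contrib)
    ord <- order(-contrib)
    df <- data.frame(taxon = taxa[ord],
                     contribution_pct = contrib[ord],
                     contribution_rel_pct = 100 * contrib[ord] / avg,
                     cumulative_rel_pct = cumsum(100 * contrib[ord] / avg))
    rownames(df) <- NULL
    res[[sprintf("%s_vs_%s", pairs[1, k], pairs[2, k])]] <-
      list(average_dissimilarity_pct = avg, contributions = df)
  }
  structure(res, class = "simper_result")
}

#' @export
print.simper_result <- function(x, ...) {
  cat("SIMPER decomposition\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: average dissimilarity %.2f%%; top taxon %s (%.2f%%)\n",
                nm, x[[nm]]$average_dissimilarity_pct,
                x[[nm]]$contributions$taxon[1],
                x[[nm]]$contributions$contribution_pct[1]))
  }
  invisible(x)
}

#' Summary statistics of an environmental series
#'
#' Minimum, maximum, mean and sample standard deviation (n - 1 denominator),
#' the form in which field covariates are reported.
#'
#' @param values Numeric vector (NAs dropped).
#' @return Named numeric vector `min`, `max`, `mean`, `sd`.
#' @export
summarize_series <- function(values) {
  values <- values[!is.na(values)]
  abort_if(length(values) < 1, "no values to summarise")
  c(min = min(values), max = max(values),
    mean = mean(values), sd = stats::sd(values))
}
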