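# Independent oracles and small fixture builders used across the suite.
# Each oracle deliberately uses a different algorithm than the package
# implementation it checks.

# Connected components by morphological reconstruction: grow each seed by
# repeated 8-neighbour dilation intersected with the foreground until a
# fixpoint. Independent of the package's queue-based flood fill.
flood_fill_oracle <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  dilate8 <- function(b) {
    out <- b
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- matrix(FALSE, h, w)
      rs <- max(1, 1 + dr):min(h, h + dr)
      cs <- max(1, 1 + dc):min(w, w + dc)
      sh[rs, cs] <- b[rs - dr, cs - dc]
      out <- out | sh
    }
    out
  }
  remaining <- fg
  comps <- list()
  while (any(remaining)) {
    seed <- matrix(FALSE, h, w)
    seed[which(remaining)[1]] <- TRUE
    repeat {
      grown <- dilate8(seed) & fg
      if (identical(grown, seed)) break
      seed <- grown
    }
    comps[[length(comps) + 1L]] <- which(seed)
    remaining <- remaining & !seed
  }
  comps
}

# Brute-force double-loop distance matrices.
brute_euclidean <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
  D
}

brute_bray <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sum(abs(X[i, ] - X[j, ])) / sum(X[i, ] + X[j, ])
  }
  D
}

# Classical ANOVA pseudo-F references for 1-D responses.
aov_oneway_F <- function(y, g) {
  summary(stats::aov(y ~ factor(g)))[[1]]$`F value`[1]
}

aov_nested_F <- function(y, cy, ti) {
  a <- stats::anova(stats::aov(y ~ factor(cy) + factor(ti)))
  ms <- a[, "Mean Sq"]
  c(F_cy = ms[1] / ms[2], F_ti = ms[2] / ms[3])
}

aov_twoway <- function(y, a, b) {
  stats::anova(stats::aov(y ~ factor(a) * factor(b)))
}

# Exact one-way permutation p for two groups of equal size: enumerate every
# relabelling (choose(n, n1) label assignments) and count F* >= F.
enumerate_twogroup_p <- function(D, groups) {
  groups <- as.factor(groups)
  n <- nrow(D)
  lev <- levels(groups)
  n1 <- sum(groups == lev[1])
  f_obs <- permanova_oneway(D, groups, n_perm = 0)$table$pseudo_F[1]
  sel <- utils::combn(n, n1)
  f_all <- apply(sel, 2, function(idx) {
    g <- rep(lev[2], n)
    g[idx] <- lev[1]
    permanova_oneway(D, g, n_perm = 0)$table$pseudo_F[1]
  })
  mean(f_all >= f_obs - 1e-12)
}

# A small scene with well-separated polyps for imaging tests.
tiny_scene <- function(n_polyps = 3, seed = 7) {
  scene_model(image_width_px = 120, image_height_px = 90, n_polyps = n_polyps,
              max_radius_px = c(5, 9), n_branches = 2, branch_width_px = 6,
              seed = seed)
}

# Build a mask with discs at given centres/radii (1-based row/col centres).
disc_mask <- function(h, w, centres, radii,
                      value = 2L) {
  m <- matrix(0L, h, w)
  for (k in seq_len(nrow(centres))) {
    for (r in 1:h) for (cc in 1:w) {
      if ((r - centres[k, 1])^2 + (cc - centres[k, 2])^2 <= radii[k]^2) {
        m[r, cc] <- value
      }
    }
  }
  m
}

runif_seeded <- function(n, seed) {
  set.seed(seed)
  stats::runif(n)
}

# Pixel-wise F1 of predicted vs true open-polyp class.
open_f1 <- function(pred, truth) {
  tp <- sum(pred == 2L & truth == 2L)
  fp <- sum(pred == 2L & truth != 2L)
  fn <- sum(pred != 2L & truth == 2L)
  2 * tp / (2 * tp + fp + fn)
}
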