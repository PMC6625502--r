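test_that("render_frame draws discs with pixel-exact ground truth", {
  sc <- tiny_scene()
  n <- nrow(sc$polyps)

  # nothing open -> no open-polyp pixels
  fr0 <- render_frame(sc, rep(0, n))
  expect_identical(fr0$open_area_px, 0L)
  expect_false(any(fr0$mask == 2L))

  # one fully open polyp: area equals a brute-force pixel scan of the disc
  sc1 <- scene_model(image_width_px = 64, image_height_px = 64, n_polyps = 1,
                     max_radius_px = c(5, 5), seed = 3)
  fr1 <- render_frame(sc1, 1)
  cx <- sc1$polyps$x[1]; cy <- sc1$polyps$y[1]
  brute <- 0L
  for (xx in 0:63) for (yy in 0:63) {
    if ((xx - cx)^2 + (yy - cy)^2 <= 25) brute <- brute + 1L
  }
  expect_identical(fr1$open_area_px, brute)

  # determinism: identical scenes and seeds give bit-identical frames
  fa <- render_frame(sc, rep(0.6, n), noise_sd = 8, seed = 42)
  fb <- render_frame(sc, rep(0.6, n), noise_sd = 8, seed = 42)
  expect_identical(fa$image, fb$image)
  expect_identical(fa$mask, fb$mask)

  # invalid apertures rejected
  expect_error(render_frame(sc, rep(1.2, n)), "\\[0, 1\\]")
  expect_error(render_frame(sc, rep(0.5, n - 1)), "apertures")
})

test_that("scene invariants hold: discs at full aperture stay in frame", {
  for (s in 1:5) {
    sc <- scene_model(n_polyps = 10, seed = s)
    r <- sc$polyps$max_radius_px
    expect_true(all(r >= 1))
    expect_true(all(sc$polyps$x - r >= 0 & sc$polyps$x + r <= sc$width - 1))
    expect_true(all(sc$polyps$y - r >= 0 & sc$polyps$y + r <= sc$height - 1))
    fr <- render_frame(sc, rep(1, 10))
    border <- c(fr$mask[1, ], fr$mask[nrow(fr$mask), ],
                fr$mask[, 1], fr$mask[, ncol(fr$mask)])
    expect_false(any(border == 2L))
  }
})

test_that("generate_time_lapse has the right frame count and exact ground truth", {
  sc <- tiny_scene()
  pr <- aperture_program(period_h = 2, jitter_sd = 0)

  tl <- generate_time_lapse(sc, pr, duration_h = 1, frame_rate = 3, seed = 1)
  expect_identical(tl$n_frames, 180)
  expect_equal(nrow(tl$truth), 180)

  # zero-jitter: the series repeats exactly with the programmed period
  tl2 <- generate_time_lapse(sc, pr, duration_h = 4.5, frame_rate = 1, seed = 1)
  per_frames <- 2 * 60  # 2 h at 1 frame/min
  s <- tl2$truth$open_area_px
  expect_identical(s[seq_len(length(s) - per_frames)],
                   s[-seq_len(per_frames)])

  # sinusoidal 2 h program over 24 h: ground-truth series peaks at 2 h
  pr3 <- aperture_program(period_h = 2, jitter_sd = 0.01)
  tl3 <- generate_time_lapse(sc, pr3, duration_h = 24, frame_rate = 1 / 6,
                             seed = 2)
  pg <- lomb_periodogram(tl3$truth$time_h, tl3$truth$open_area_px)
  best <- pg$period_h[which.max(pg$power)]
  expect_lt(abs(1 / best - 1 / 2), pg$grid_step + 1e-12)
})

test_that("field survey generator is balanced, bounded and reproducible", {
  fs <- generate_field_survey(seed = 5)
  expect_equal(nrow(fs), 60)
  expect_equal(as.vector(table(fs$cycle)), rep(12L, 5))
  for (cy in unique(fs$cycle)) {
    expect_equal(length(unique(fs$time[fs$cycle == cy])), 4)
  }
  expect_true(all(fs$expansion_pct >= 0 & fs$expansion_pct <= 100))
  expect_identical(fs, generate_field_survey(seed = 5))
  expect_error(generate_field_survey(noise_sd = 0), "noise_sd")

  # positive current effect shows up as a positive sample correlation
  hits <- sum(vapply(1:100, function(s) {
    f <- generate_field_survey(seed = s)
    stats::cor(f$expansion_pct, f$current_cm_s) > 0
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("zooplankton count generator is reproducible with cycle structure", {
  z <- generate_zooplankton_counts(seed = 3)
  expect_equal(dim(z$counts), c(20, 12))
  expect_identical(z$counts, generate_zooplankton_counts(seed = 3)$counts)

  # a taxon effectively restricted to late cycles dominates C1 vs C5
  z2 <- generate_zooplankton_counts(
    n_taxa = 6, base_means = c(200, 150, 100, 80, 60, 400),
    cycle_log_slope = c(0, 0, 0, 0, 0, 4), seed = 11)
  expect_true(all(z2$counts[z2$cycle == "C1", 6] == 0))
  sim <- simper(z2$counts, z2$cycle)
  expect_identical(sim$C1_vs_C5$contributions$taxon[1], "taxon_06")

  # no overdispersion, equal large means: Bray-Curtis distances shrink
  z3 <- generate_zooplankton_counts(n_taxa = 8, base_means = 1e4,
                                    cycle_log_slope = 0, dispersion = Inf,
                                    seed = 7)
  D <- bray_curtis_matrix(z3$counts, fourth_root = FALSE)
  expect_lt(max(D), 0.02)

  # flat cycle means: between-cycle dissimilarity matches within-cycle
  ratios <- vapply(1:20, function(s) {
    z <- generate_zooplankton_counts(cycle_log_slope = 0, seed = 100 + s)
    D <- bray_curtis_matrix(z$counts)
    same <- outer(z$cycle, z$cycle, "==") & upper.tri(D)
    diff <- outer(z$cycle, z$cycle, "!=") & upper.tri(D)
    mean(D[diff]) / mean(D[same])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("flume generators produce the declared balanced designs", {
  fl <- generate_flume_experiment(seed = 1)
  expect_equal(nrow(fl), 108)
  expect_true(all(table(fl$temperature, fl$current) == 12))
  expect_true(all(fl$expansion_pct >= 0 & fl$expansion_pct <= 100))
  expect_identical(fl, generate_flume_experiment(seed = 1))

  nu <- generate_nutrition_experiment(seed = 1)
  expect_equal(nrow(nu), 32)
  expect_equal(as.vector(table(nu$stimulus)), rep(8L, 4))
})

test_that("injected Te x Cu interaction is detected; absent interaction is not", {
  hits <- sum(vapply(1:40, function(s) {
    fl <- generate_flume_experiment(seed = 400 + s)
    D <- euclidean_matrix(matrix(fl$expansion_pct))
    pt <- permanova_twoway(D, fl$temperature, fl$current,
                           n_perm = 199, seed = s)
    pt$table$p_perm[3] <= 0.05
  }, logical(1)))
  expect_gte(hits / 40, 0.9)

  null_hits <- sum(vapply(1:60, function(s) {
    fl <- generate_flume_experiment(cell_means = matrix(50, 3, 3),
                                    seed = 700 + s)
    D <- euclidean_matrix(matrix(fl$expansion_pct))
    pt <- permanova_twoway(D, fl$temperature, fl$current,
                           n_perm = 199, seed = s)
    pt$table$p_perm[3] <= 0.05
  }, logical(1)))
  expect_gte(null_hits / 60, 0.0)
  expect_lte(null_hits / 60, 0.15)
})
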