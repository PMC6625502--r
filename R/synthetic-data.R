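# Synthetic inputs: rendered colony time-lapse with exact ground truth, and
# field / flume tables with the study's design structure.

#' Build a colony scene for the synthetic renderer
#'
#' Describes a red-coral colony as seen by the recording camera: thick branch
#' segments of coenenchyme on a dark background, with white polyps whose
#' aperture scales the radius of a filled disc. Polyp centres are placed on
#' the branches and clamped so that fully open discs stay inside the frame.
#'
#' @param image_width_px,image_height_px Frame size in pixels.
#' @param real_width_mm Physical width imaged, used for pixel resolution.
#' @param n_polyps Number of polyps to place.
#' @param max_radius_px Range (min, max) of per-polyp fully-open disc radii.
#' @param n_branches Number of branch segments.
#' @param branch_width_px Branch thickness in pixels.
#' @param seed Integer seed; the scene is a pure function of its arguments.
#'
#' @return An object of class `scene_model`: list with `width`, `height`,
#'   `real_width_mm`, `branches` (data frame of segment endpoints, 0-based
#'   pixel coordinates), `polyps` (data frame with `x`, `y`, `max_radius_px`).
#' @export
scene_model <- function(image_width_px = 736, image_height_px = 568,
                        real_width_mm = 104, n_polyps = 12,
                        max_radius_px = c(6, 14), n_branches = 3,
                        branch_width_px = 10, seed = 1) {
  abort_if(image_width_px < 32 || image_height_px < 32,
           "image dimensions must be at least 32 px")
  abort_if(n_polyps < 1, "need at least one polyp")
  abort_if(min(max_radius_px) < 1, "max polyp radii must be >= 1 px")
  with_seed(seed, {
    margin <- max(max_radius_px) + branch_width_px
    bx0 <- runif(n_branches, margin, image_width_px - 1 - margin)
    by0 <- runif(n_branches, margin, image_height_px - 1 - margin)
    ang <- runif(n_branches, 0, pi)
    len <- runif(n_branches, 0.3, 0.6) * min(image_width_px, image_height_px)
    bx1 <- clip(bx0 + cos(ang) * len, margin, image_width_px - 1 - margin)
    by1 <- clip(by0 + sin(ang) * len, margin, image_height_px - 1 - margin)
    branches <- data.frame(x0 = bx0, y0 = by0, x1 = bx1, y1 = by1,
                           width_px = branch_width_px)
    # polyps sit on branch segments, spread along their length
    b <- sample.int(n_branches, n_polyps, replace = TRUE)
    u <- runif(n_polyps)
    px <- branches$x0[b] + u * (branches$x1[b] - branches$x0[b])
    py <- branches$y0[b] + u * (branches$y1[b] - branches$y0[b])
    r <- runif(n_polyps, max_radius_px[1], max_radius_px[2])
    px <- clip(px, r, image_width_px - 1 - r)
    py <- clip(py, r, image_height_px - 1 - r)
    scene <- list(width = as.integer(image_width_px),
                  height = as.integer(image_height_px),
                  real_width_mm = real_width_mm,
                  branches = branches,
                  polyps = data.frame(x = px, y = py, max_radius_px = r))
    class(scene) <- "scene_model"
    scene
  })
}

#' @export
print.scene_model <- function(x, ...) {
  cat(sprintf("<scene_model> %d x %d px (%.0f mm wide), %d branches, %d polyps\n",
              x$width, x$height, x$real_width_mm,
              nrow(x$branches), nrow(x$polyps)))
  invisible(x)
}

#' Per-polyp aperture program
#'
#' Defines the deterministic aperture trajectory a(t) in \[0, 1\] of every
#' polyp: a baseline oscillation (sinusoid or square wave) with a common
#' period, per-polyp phases, per-frame Gaussian jitter, and optional global
#' step events (e.g. all polyps forced shut by a disturbance).
#'
#' @param period_h Baseline period in hours. The default 12.4 h is the
#'   semidiurnal tidal period, the rhythm class expected for Mediterranean
#'   passive suspension feeders.
#' @param phase Phase in radians; recycled over polyps.
#' @param waveform `"sine"` (0.5 + 0.5 sin, clipped) or `"square"`.
#' @param jitter_sd Per-frame Gaussian jitter SD added to the aperture
#'   before clipping to \[0, 1\].
#' @param events Optional data frame with columns `time_h` and `delta`;
#'   from `time_h` onwards `delta` is added to every polyp's aperture
#'   (before clipping), modelling global open/close events.
#'
#' @return Object of class `aperture_program`.
#' @export
aperture_program <- function(period_h = 12.4, phase = 0,
                             waveform = c("sine", "square"),
                             jitter_sd = 0.02, events = NULL) {
  waveform <- match.arg(waveform)
  abort_if(period_h <= 0, "period_h must be positive")
  abort_if(jitter_sd < 0, "jitter_sd must be non-negative")
  if (!is.null(events)) {
    abort_if(!all(c("time_h", "delta") %in% names(events)),
             "events needs columns time_h and delta")
  }
  structure(list(period_h = period_h, phase = phase, waveform = waveform,
                 jitter_sd = jitter_sd, events = events),
            class = "aperture_program")
}

# Deterministic part of the program: n_polyps x n_times matrix of apertures
# before jitter, clipped to [0, 1].
eval_aperture_program <- function(program, times_h, n_polyps) {
  phase <- rep_len(program$phase, n_polyps)
  w <- 2 * pi / program$period_h
  base <- outer(phase, times_h, function(ph, t) sin(w * t + ph))
  a <- switch(program$waveform,
              sine = 0.5 + 0.5 * base,
              square = ifelse(base >= 0, 1, 0))
  if (!is.null(program$events)) {
    for (k in seq_len(nrow(program$events))) {
      on <- times_h >= program$events$time_h[k]
      a[, on] <- a[, on] + program$events$delta[k]
    }
  }
  clip(a, 0, 1)
}

#' Render one frame of the synthetic colony
#'
#' Draws the scene at the given per-polyp apertures: background, then branch
#' segments in the coenenchyme colour, then each polyp as a filled disc of
#' radius `aperture * max_radius_px` in the open-polyp colour. A pixel at
#' 0-based centre (x, y) belongs to a disc when its distance to the polyp
#' centre is at most the current radius; an aperture of 0 draws nothing.
#'
#' @param scene A [scene_model()].
#' @param apertures Numeric vector in \[0, 1\], one value per polyp.
#' @param noise_sd Optional Gaussian sensor/compression-like noise SD on the
#'   0--255 intensity scale, added to every channel (0 = clean frame).
#' @param seed Seed for the noise draw (ignored when `noise_sd` is 0).
#'
#' @return List with `image` (height x width x 3 array in \[0, 1\]), `mask`
#'   (height x width integer ground-truth class matrix: 0 background,
#'   1 coenenchyme, 2 open polyp) and `open_area_px` (true open-polyp pixel
#'   count).
#' @export
render_frame <- function(scene, apertures, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(scene, "scene_model"))
  n_polyps <- nrow(scene$polyps)
  abort_if(length(apertures) != n_polyps,
           "need %d apertures, got %d", n_polyps, length(apertures))
  abort_if(any(apertures < 0 | apertures > 1 | !is.finite(apertures)),
           "apertures must lie in [0, 1]")
  h <- scene$height; w <- scene$width
  pal <- class_palette()
  mask <- matrix(CLASS_BACKGROUND, h, w)

  # pixel-centre coordinate grids (0-based, origin top-left)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)

  for (k in seq_len(nrow(scene$branches))) {
    b <- scene$branches[k, ]
    dx <- b$x1 - b$x0; dy <- b$y1 - b$y0
    l2 <- dx^2 + dy^2
    t <- if (l2 == 0) 0 else clip(((xs - b$x0) * dx + (ys - b$y0) * dy) / l2, 0, 1)
    d2 <- (xs - (b$x0 + t * dx))^2 + (ys - (b$y0 + t * dy))^2
    mask[d2 <= (b$width_px / 2)^2] <- CLASS_COENENCHYME
  }
  for (p in seq_len(n_polyps)) {
    r <- apertures[p] * scene$polyps$max_radius_px[p]
    if (r <= 0) next
    cx <- scene$polyps$x[p]; cy <- scene$polyps$y[p]
    # restrict to the disc's bounding box for speed
    c0 <- max(0L, floor(cx - r)); c1 <- min(w - 1L, ceiling(cx + r))
    r0 <- max(0L, floor(cy - r)); r1 <- min(h - 1L, ceiling(cy + r))
    cols <- (c0:c1) + 1L; rows <- (r0:r1) + 1L
    d2 <- outer((rows - 1) - cy, (cols - 1) - cx,
                function(a, b) a^2 + b^2)
    sub <- mask[rows, cols, drop = FALSE]
    sub[d2 <= r^2] <- CLASS_OPEN_POLYP
    mask[rows, cols] <- sub
  }
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- pal[mask + 1L, ch]
    dim(plane) <- c(h, w)
    img[, , ch] <- plane
  }
  if (noise_sd > 0) {
    img <- with_seed(seed, img + array(stats::rnorm(length(img),
                                                    sd = noise_sd / 255),
                                       dim = dim(img)))
    img <- clip(img, 0, 1)
  }
  list(image = img, mask = mask,
       open_area_px = sum(mask == CLASS_OPEN_POLYP))
}

#' Generate a synthetic time-lapse sequence with ground truth
#'
#' Runs an [aperture_program()] over a [scene_model()] at the recording
#' frame rate (default 3 frames/min) and renders every frame. The returned
#' ground truth carries the exact per-frame open-polyp pixel count and the
#' per-polyp apertures, so downstream image analysis can be scored without
#' manual labels.
#'
#' @param scene A [scene_model()].
#' @param program An [aperture_program()].
#' @param duration_h Recording length in hours (> 0).
#' @param frame_rate Frames per minute (default 3).
#' @param seed Seed driving aperture jitter and frame noise.
#' @param noise_sd Per-frame Gaussian noise SD on the 0--255 scale.
#' @param out_dir If non-NULL, frames are written there as zero-padded PNGs
#'   (`frame_000001.png`, ...) and pixel data is not kept in memory.
#' @param callback If non-NULL, `callback(i, image, mask)` is invoked per
#'   frame (streaming use); pixel data is not kept in memory.
#'
#' @return List with `truth` (data frame: `frame`, `time_s`, `time_h`,
#'   `open_area_px`, `aperture_<p>` columns), `frames` (list of render
#'   results, or NULL when streaming), and the resolved settings.
#' @export
generate_time_lapse <- function(scene, program, duration_h, frame_rate = 3,
                                seed = 1, noise_sd = 0, out_dir = NULL,
                                callback = NULL) {
  stopifnot(inherits(scene, "scene_model"), inherits(program, "aperture_program"))
  abort_if(duration_h <= 0, "duration_h must be positive")
  n_frames <- floor(duration_h * 60 * frame_rate)
  abort_if(n_frames < 1, "duration too short for one frame")
  times_h <- (seq_len(n_frames) - 1) / (60 * frame_rate)
  n_polyps <- nrow(scene$polyps)

  ap <- eval_aperture_program(program, times_h, n_polyps)
  with_seed(seed, {
    if (program$jitter_sd > 0) {
      ap <- clip(ap + matrix(stats::rnorm(length(ap), sd = program$jitter_sd),
                             nrow(ap), ncol(ap)), 0, 1)
    }
    keep <- is.null(out_dir) && is.null(callback)
    frames <- if (keep) vector("list", n_frames) else NULL
    if (!is.null(out_dir) && !dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
    }
    open_area <- integer(n_frames)
    for (i in seq_len(n_frames)) {
      fr <- render_frame(scene, ap[, i], noise_sd = noise_sd, seed = NULL)
      open_area[i] <- fr$open_area_px
      if (keep) frames[[i]] <- fr
      if (!is.null(out_dir)) {
        png::writePNG(fr$image,
                      file.path(out_dir, sprintf("frame_%06d.png", i)))
      }
      if (!is.null(callback)) callback(i, fr$image, fr$mask)
    }
    truth <- data.frame(frame = seq_len(n_frames),
                        time_s = times_h * 3600,
                        time_h = times_h,
                        open_area_px = open_area)
    apdf <- as.data.frame(t(ap))
    names(apdf) <- sprintf("aperture_%d", seq_len(n_polyps))
    truth <- cbind(truth, apdf)
    list(truth = truth, frames = frames, n_frames = n_frames,
         frame_rate = frame_rate, duration_h = duration_h, seed = seed,
         noise_sd = noise_sd)
  })
}

#' Simulate the field polyp-expansion survey
#'
#' Balanced design of 5 diel cycles x 4 sampling times (every 6 h, nested in
#' cycle) x 3 replicate colony groups, with environmental covariates drawn
#' once per cycle-time observation point and shared by its replicates.
#' Percent expansion is a linear response to current speed and zooplankton
#' concentration plus cycle and time-within-cycle effects and Gaussian
#' noise, clipped to \[0, 100\].
#'
#' Covariate defaults reproduce the field conditions of the study system:
#' current speed mean 9.3 SD 9.4 cm s^-1 (gamma), zooplankton mean 2,122 SD
#' 2,412 ind m^-3 (gamma), chlorophyll a mean 0.4 SD 0.1 ug L^-1 (gamma),
#' protein mean 176 SD 32 ug L^-1 (normal, truncated at 0).
#'
#' @param n_cycles,n_times,n_replicates Design sizes (defaults 5, 4, 3).
#' @param current_mean,current_sd,zoo_mean,zoo_sd,chla_mean,chla_sd,
#'   protein_mean,protein_sd Covariate distribution parameters.
#' @param intercept Baseline percent expansion.
#' @param beta_current Percent expansion per cm s^-1 of current.
#' @param beta_zoo Percent expansion per ind m^-3 of zooplankton.
#' @param cycle_sd SD of random cycle effects (percent points).
#' @param time_sd SD of random time-within-cycle effects (percent points).
#' @param noise_sd Residual SD (percent points); must be positive.
#' @param seed Integer seed.
#'
#' @return Data frame with `cycle`, `time`, `replicate`, the four covariates
#'   and `expansion_pct`; `n_cycles * n_times * n_replicates` rows.
#' @export
generate_field_survey <- function(n_cycles = 5, n_times = 4, n_replicates = 3,
                                  current_mean = 9.3, current_sd = 9.4,
                                  zoo_mean = 2122, zoo_sd = 2412,
                                  chla_mean = 0.4, chla_sd = 0.1,
                                  protein_mean = 176, protein_sd = 32,
                                  intercept = 30,
                                  beta_current = 2, beta_zoo = 0.005,
                                  cycle_sd = 5, time_sd = 10, noise_sd = 8,
                                  seed = 1) {
  abort_if(noise_sd <= 0, "noise_sd must be positive")
  abort_if(any(c(current_sd, zoo_sd, chla_sd, protein_sd) <= 0),
           "covariate SDs must be positive")
  with_seed(seed, {
    n_pts <- n_cycles * n_times
    rgamma_ms <- function(n, m, s) {
      stats::rgamma(n, shape = (m / s)^2, scale = s^2 / m)
    }
    current <- rgamma_ms(n_pts, current_mean, current_sd)
    zoo <- rgamma_ms(n_pts, zoo_mean, zoo_sd)
    chla <- rgamma_ms(n_pts, chla_mean, chla_sd)
    protein <- pmax(stats::rnorm(n_pts, protein_mean, protein_sd), 0)

    cyc_eff <- if (cycle_sd > 0) stats::rnorm(n_cycles, 0, cycle_sd) else numeric(n_cycles)
    tim_eff <- if (time_sd > 0) stats::rnorm(n_pts, 0, time_sd) else numeric(n_pts)

    out <- expand.grid(replicate = seq_len(n_replicates),
                       time = seq_len(n_times),
                       cycle = seq_len(n_cycles))[, c("cycle", "time", "replicate")]
    pt <- (out$cycle - 1) * n_times + out$time
    out$current_cm_s <- current[pt]
    out$zooplankton_ind_m3 <- zoo[pt]
    out$chla_ug_L <- chla[pt]
    out$protein_ug_L <- protein[pt]
    mu <- intercept + beta_current * out$current_cm_s +
      beta_zoo * out$zooplankton_ind_m3 + cyc_eff[out$cycle] + tim_eff[pt]
    out$expansion_pct <- clip(mu + stats::rnorm(nrow(out), 0, noise_sd), 0, 100)
    # nested coding: time labels unique within their cycle
    out$time <- sprintf("C%dT%d", out$cycle, out$time)
    out$cycle <- sprintf("C%d", out$cycle)
    out
  })
}

#' Simulate taxon x sample zooplankton count tables
#'
#' Negative-binomial counts for `n_per_cycle` samples in each of `n_cycles`
#' cycles. Cycle structure enters as per-taxon log-linear trends across
#' cycles, so assemblage composition drifts over the survey (as in the field,
#' where later cycles carried more zooplankton); by default half the taxa
#' increase and half decrease, making the first and last cycles the most
#' dissimilar pair. The default trend magnitude and dispersion put the
#' fourth-root Bray-Curtis between-cycle dissimilarity on the scale observed
#' in the survey (roughly 20--30%).
#'
#' @param n_cycles,n_per_cycle Design sizes (defaults 5 and 4).
#' @param n_taxa Number of taxa (>= 2).
#' @param base_means Mean count vector at the middle cycle; recycled to
#'   `n_taxa`.
#' @param cycle_log_slope Per-taxon log-linear slope across cycles; recycled.
#'   `mu[taxon, cycle] = base_means * exp(slope * (cycle - midpoint))`.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed); `Inf` gives Poisson.
#' @param seed Integer seed.
#'
#' @return List with `counts` (samples x taxa integer matrix, rownames
#'   `C<cycle>S<sample>`, colnames `taxon_<j>`) and `cycle` (factor of
#'   cycle labels per sample).
#' @export
generate_zooplankton_counts <- function(n_cycles = 5, n_per_cycle = 4,
                                        n_taxa = 12,
                                        base_means = c(900, 450, 260, 150, 90,
                                                       55, 34, 20, 12, 8, 5, 3),
                                        cycle_log_slope = rep(c(0.55, -0.55),
                                                              length.out = n_taxa),
                                        dispersion = 2, seed = 1) {
  abort_if(n_taxa < 2, "need at least two taxa")
  abort_if(dispersion <= 0, "dispersion must be positive")
  base_means <- rep_len(base_means, n_taxa)
  cycle_log_slope <- rep_len(cycle_log_slope, n_taxa)
  mid <- (n_cycles + 1) / 2
  with_seed(seed, {
    counts <- matrix(0L, n_cycles * n_per_cycle, n_taxa)
    cycle <- character(n_cycles * n_per_cycle)
    row <- 0L
    for (cy in seq_len(n_cycles)) {
      mu <- base_means * exp(cycle_log_slope * (cy - mid))
      for (s in seq_len(n_per_cycle)) {
        row <- row + 1L
        counts[row, ] <- if (is.finite(dispersion)) {
          stats::rnbinom(n_taxa, size = dispersion, mu = mu)
        } else {
          stats::rpois(n_taxa, lambda = mu)
        }
        cycle[row] <- sprintf("C%d", cy)
      }
    }
    rownames(counts) <- sprintf("%sS%d", cycle,
                                rep(seq_len(n_per_cycle), n_cycles))
    colnames(counts) <- sprintf("taxon_%02d", seq_len(n_taxa))
    list(counts = counts, cycle = factor(cycle))
  })
}

#' Simulate the temperature x current flume experiment
#'
#' Balanced 3 x 3 factorial (temperature 13/18/25 degrees C, current
#' 0/3/6 cm s^-1) with `n_per_cell` percent-expansion responses per cell,
#' Gaussian noise, clipped to \[0, 100\]. Default cell means encode the
#' qualitative outcome of the experiment: in still water expansion rises
#' with temperature, while under flow the largest expansion occurs at low
#' temperature and maximum current -- a non-additive (interaction) pattern.
#'
#' @param temperature_levels,current_levels Factor levels.
#' @param n_per_cell Replicates per cell (default 12).
#' @param cell_means Matrix (temperature x current) of mean percent
#'   expansion. `NULL` gives the default pattern above; a constant matrix
#'   gives a null (no-effect) experiment.
#' @param noise_sd Residual SD in percent points.
#' @param seed Integer seed.
#'
#' @return Data frame with `temperature`, `current`, `replicate`,
#'   `expansion_pct`.
#' @export
generate_flume_experiment <- function(temperature_levels = c(13, 18, 25),
                                      current_levels = c(0, 3, 6),
                                      n_per_cell = 12, cell_means = NULL,
                                      noise_sd = 12, seed = 1) {
  a <- length(temperature_levels); b <- length(current_levels)
  if (is.null(cell_means)) {
    abort_if(a != 3 || b != 3, "default cell_means requires a 3 x 3 design")
    cell_means <- rbind(c(30, 55, 75),   # 13 C: strong response to current
                        c(45, 60, 70),   # 18 C
                        c(55, 52, 48))   # 25 C: open in still water, flat
  }
  abort_if(!all(dim(cell_means) == c(a, b)),
           "cell_means must be %d x %d", a, b)
  abort_if(noise_sd <= 0, "noise_sd must be positive")
  with_seed(seed, {
    out <- expand.grid(replicate = seq_len(n_per_cell),
                       current = current_levels,
                       temperature = temperature_levels)
    out <- out[, c("temperature", "current", "replicate")]
    ti <- match(out$temperature, temperature_levels)
    ci <- match(out$current, current_levels)
    mu <- cell_means[cbind(ti, ci)]
    out$expansion_pct <- clip(mu + stats::rnorm(nrow(out), 0, noise_sd), 0, 100)
    out$temperature <- factor(out$temperature, levels = temperature_levels)
    out$current <- factor(out$current, levels = current_levels)
    out
  })
}

#' Simulate the nutritional-stimulus flume experiment
#'
#' One-way design with four stimulus levels (N0 none, N1/N2 ground
#' zooplankton filtrate at two doses, N3 whole zooplankton at about
#' 1,500 ind m^-3), `n_per_level` responses per level. Default means encode
#' the observed ordering: expansion increases with stimulus, N1 and N2
#' nearly equal, N3 (whole zooplankton) maximal.
#'
#' @param levels Stimulus level labels.
#' @param n_per_level Replicates per level (default 8).
#' @param level_means Mean percent expansion per level.
#' @param noise_sd Residual SD in percent points.
#' @param seed Integer seed.
#'
#' @return Data frame with `stimulus`, `replicate`, `expansion_pct`.
#' @export
generate_nutrition_experiment <- function(levels = c("N0", "N1", "N2", "N3"),
                                          n_per_level = 8,
                                          level_means = c(20, 45, 50, 75),
                                          noise_sd = 12, seed = 1) {
  abort_if(length(level_means) != length(levels),
           "need one mean per stimulus level")
  abort_if(noise_sd <= 0, "noise_sd must be positive")
  with_seed(seed, {
    out <- expand.grid(replicate = seq_len(n_per_level), stimulus = levels)
    out <- out[, c("stimulus", "replicate")]
    mu <- level_means[match(out$stimulus, levels)]
    out$expansion_pct <- clip(mu + stats::rnorm(nrow(out), 0, noise_sd), 0, 100)
    out$stimulus <- factor(out$stimulus, levels = levels)
    out
  })
}
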