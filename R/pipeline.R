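# End-to-end orchestration: simulate -> quantify -> rhythms -> stats, with
# manifests that make every output re-derivable from config + seed.

write_manifest <- function(out_dir, step, config) {
  manifest <- c(list(step = step,
                     package = "polypwatch",
                     version = as.character(utils::packageVersion("polypwatch")),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                config)
  yaml::write_yaml(manifest, file.path(out_dir, sprintf("%s_manifest.yaml", step)))
  invisible(manifest)
}

#' Simulate all pipeline inputs
#'
#' Generates the selected synthetic datasets into `out_dir`: field survey
#' table, temperature x current flume table, nutritional-stimulus table,
#' zooplankton count table, and optionally a rendered time-lapse (PNG frames
#' plus ground-truth CSV). A YAML manifest echoing the full configuration
#' and package version is written alongside.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; each dataset derives its own fixed offset from
#'   it, so any subset of outputs is reproducible.
#' @param what Character vector of datasets to generate; any of `"field"`,
#'   `"flume"`, `"nutrition"`, `"zooplankton"`, `"video"`.
#' @param video Named list of overrides for the time-lapse part:
#'   `duration_h`, `frame_rate`, `noise_sd`, `n_polyps`, `width`, `height`,
#'   `period_h`.
#' @return Invisibly, a named list of the generated objects / paths.
#' @export
run_simulate <- function(out_dir, seed = 1,
                         what = c("field", "flume", "nutrition", "zooplankton"),
                         video = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  what <- match.arg(what, c("field", "flume", "nutrition", "zooplankton",
                            "video"), several.ok = TRUE)
  out <- list()
  if ("field" %in% what) {
    field <- generate_field_survey(seed = seed + 11L)
    utils::write.csv(field, file.path(out_dir, "field_survey.csv"),
                     row.names = FALSE)
    out$field <- field
  }
  if ("flume" %in% what) {
    flume <- generate_flume_experiment(seed = seed + 23L)
    utils::write.csv(flume, file.path(out_dir, "flume_te_cu.csv"),
                     row.names = FALSE)
    out$flume <- flume
  }
  if ("nutrition" %in% what) {
    nutrition <- generate_nutrition_experiment(seed = seed + 37L)
    utils::write.csv(nutrition, file.path(out_dir, "flume_nutrition.csv"),
                     row.names = FALSE)
    out$nutrition <- nutrition
  }
  if ("zooplankton" %in% what) {
    zoo <- generate_zooplankton_counts(seed = seed + 41L)
    zt <- data.frame(sample = rownames(zoo$counts), cycle = zoo$cycle,
                     zoo$counts, check.names = FALSE)
    utils::write.csv(zt, file.path(out_dir, "zooplankton_counts.csv"),
                     row.names = FALSE)
    out$zooplankton <- zoo
  }
  vdefaults <- list(duration_h = 24, frame_rate = 1 / 3, noise_sd = 0,
                    n_polyps = 8, width = 368, height = 284, period_h = 12.4)
  vcfg <- utils::modifyList(vdefaults, video)
  if ("video" %in% what) {
    scene <- scene_model(image_width_px = vcfg$width,
                         image_height_px = vcfg$height,
                         real_width_mm = 104,
                         n_polyps = vcfg$n_polyps, seed = seed + 53L)
    program <- aperture_program(period_h = vcfg$period_h,
                                phase = seq(0, 1, length.out = vcfg$n_polyps))
    frames_dir <- file.path(out_dir, "frames")
    tl <- generate_time_lapse(scene, program,
                              duration_h = vcfg$duration_h,
                              frame_rate = vcfg$frame_rate,
                              seed = seed + 67L, noise_sd = vcfg$noise_sd,
                              out_dir = frames_dir)
    utils::write.csv(tl$truth, file.path(out_dir, "video_ground_truth.csv"),
                     row.names = FALSE)
    out$video <- list(scene = scene, truth = tl$truth,
                      frames_dir = frames_dir)
  }
  write_manifest(out_dir, "simulate",
                 list(seed = seed, what = what, video = vcfg))
  invisible(out)
}

#' Quantify polyp activity from a frame directory
#'
#' Segments every frame, derives the open-area / activity-index /
#' normalised / percent-expansion series, and counts tracked regions. The
#' percent-expansion references follow the calibration convention: the
#' series minimum (experiments start with all polyps closed) and the
#' observed maximum.
#'
#' @param frames_dir Directory of PNG frames (zero-padded order).
#' @param out_csv Optional path for the activity CSV.
#' @param frame_interval_s Seconds between frames (default 20, i.e. 3
#'   frames/min).
#' @param denoise Apply morphological cleanup before labelling.
#' @param min_area_px Minimum region area for labelling/tracking.
#' @param track Also run region tracking (default TRUE; disable for long
#'   sequences where only the area series is needed).
#' @return List with `activity` (data frame) and `tracks` (a
#'   `region_tracks` or NULL).
#' @export
run_quantify <- function(frames_dir, out_csv = NULL, frame_interval_s = 20,
                         denoise = FALSE, min_area_px = 5, track = TRUE) {
  frames <- read_frame_dir(frames_dir)
  masks <- lapply(frames, segment_frame, denoise = denoise)
  act <- activity_table(masks,
                        time_s = (seq_along(masks) - 1) * frame_interval_s)
  tracks <- NULL
  if (track) {
    regions <- lapply(masks, label_regions, min_area_px = min_area_px)
    tracks <- track_regions(regions)
  }
  if (!is.null(out_csv)) {
    utils::write.csv(act, out_csv, row.names = FALSE)
    write_manifest(dirname(out_csv), "quantify",
                   list(frames_dir = frames_dir, n_frames = length(frames),
                        frame_interval_s = frame_interval_s,
                        denoise = denoise, min_area_px = min_area_px,
                        n_tracks = if (is.null(tracks)) NA else
                          nrow(tracks$tracks)))
  }
  message(sprintf("quantified %d frame(s); %s track(s)", length(frames),
                  if (is.null(tracks)) "no" else nrow(tracks$tracks)))
  list(activity = act, tracks = tracks)
}

#' Rhythm detection on an activity table
#'
#' Runs the Lomb periodogram on the maximum-normalised open-area series and
#' extracts significant peaks.
#'
#' @param activity Data frame with `time_s` and `open_area_px` columns (as
#'   from [run_quantify()]), or a path to such a CSV.
#' @param alpha Peak significance level (default 0.01).
#' @param out_csv Optional path; writes the periodogram CSV (frequency,
#'   period, power, p) with the three threshold levels echoed in a header
#'   comment, plus a `_peaks.csv` companion.
#' @param ... Passed to [lomb_periodogram()].
#' @return List with `periodogram` and `peaks`.
#' @export
run_rhythms <- function(activity, alpha = 0.01, out_csv = NULL, ...) {
  if (is.character(activity)) activity <- utils::read.csv(activity)
  abort_if(!all(c("time_s", "open_area_px") %in% names(activity)),
           "activity needs time_s and open_area_px columns")
  norm <- normalize_activity(activity$open_area_px)
  pg <- lomb_periodogram(activity$time_s / 3600, norm, ...)
  peaks <- detect_peaks(pg, alpha = alpha)
  if (!is.null(out_csv)) {
    con <- file(out_csv, "w")
    writeLines(sprintf("# power thresholds: p=0.1 %.4f, p=0.01 %.4f, p=0.001 %.4f",
                       pg$thresholds[1], pg$thresholds[2], pg$thresholds[3]),
               con)
    utils::write.csv(data.frame(frequency_c_per_h = pg$frequency,
                                period_h = pg$period_h, power = pg$power),
                     con, row.names = FALSE)
    close(con)
    utils::write.csv(peaks, sub("\\.csv$", "_peaks.csv", out_csv),
                     row.names = FALSE)
  }
  list(periodogram = pg, peaks = peaks)
}

#' Run the permutational analysis appropriate to a design
#'
#' Dispatches on the declared design: `"oneway"` (e.g. nutritional stimuli
#' or zooplankton cycles), `"nested"` (cycle / time-within-cycle field
#' survey), `"twoway"` (temperature x current flume factorial). Euclidean
#' distances are used for response tables; Bray-Curtis on fourth-root
#' counts for taxon tables. Pairwise tests are run when the design's
#' primary term is significant at `alpha`.
#'
#' @param table Data frame of responses/counts plus factor columns.
#' @param design One of `"oneway"`, `"nested"`, `"twoway"`.
#' @param response Column name(s) of the response(s) (or taxon columns).
#' @param factors Character vector naming the factor column(s): one for
#'   oneway, (cycle, time) for nested, (A, B) for twoway.
#' @param distance `"euclidean"` or `"bray_curtis"`.
#' @param normalize_columns,fourth_root Distance options.
#' @param n_perm,seed Permutation settings.
#' @param alpha Gate for running pairwise tests (default 0.05).
#' @param out_dir Optional directory for result CSVs.
#' @return List with `permanova`, `pairwise` (or NULL), `simper` (taxon
#'   tables under oneway Bray-Curtis only, or NULL).
#' @export
run_stats <- function(table, design, response, factors,
                      distance = c("euclidean", "bray_curtis"),
                      normalize_columns = FALSE, fourth_root = TRUE,
                      n_perm = 9999, seed = 1, alpha = 0.05,
                      out_dir = NULL) {
  design <- match.arg(design, c("oneway", "nested", "twoway"))
  distance <- match.arg(distance)
  abort_if(!all(response %in% names(table)),
           "response column(s) missing from table")
  abort_if(!all(factors %in% names(table)),
           "factor column(s) missing from table")
  resp <- as.matrix(table[, response, drop = FALSE])
  D <- if (distance == "euclidean") {
    euclidean_matrix(resp, normalize_columns = normalize_columns)
  } else {
    bray_curtis_matrix(resp, fourth_root = fourth_root)
  }
  res <- switch(design,
    oneway = {
      abort_if(length(factors) != 1, "oneway design needs one factor")
      permanova_oneway(D, table[[factors[1]]], n_perm = n_perm, seed = seed)
    },
    nested = {
      abort_if(length(factors) != 2, "nested design needs (cycle, time) factors")
      permanova_nested(D, table[[factors[1]]], table[[factors[2]]],
                       n_perm = n_perm, seed = seed)
    },
    twoway = {
      abort_if(length(factors) != 2, "twoway design needs two factors")
      permanova_twoway(D, table[[factors[1]]], table[[factors[2]]],
                       n_perm = n_perm, seed = seed, term_labels = factors)
    })
  # pairwise follow-up on the first (primary) term, gated at alpha
  pw <- NULL
  p_primary <- res$table$p_perm[1]
  if (!res$degenerate && !is.na(p_primary) && p_primary < alpha) {
    pw_factor <- table[[factors[1]]]
    pw <- pairwise_tests(D, pw_factor, n_perm = n_perm, seed = seed)
  }
  sim <- NULL
  if (design == "oneway" && distance == "bray_curtis") {
    sim <- simper(resp, table[[factors[1]]], fourth_root = fourth_root)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(res$table,
                     file.path(out_dir, sprintf("permanova_%s.csv", design)),
                     row.names = FALSE)
    if (!is.null(pw)) {
      utils::write.csv(pw, file.path(out_dir,
                                     sprintf("pairwise_%s.csv", factors[1])),
                       row.names = FALSE)
    }
    if (!is.null(sim)) {
      simtab <- do.call(rbind, lapply(names(sim), function(nm) {
        cbind(pair = nm, average_dissimilarity_pct =
                sim[[nm]]$average_dissimilarity_pct, sim[[nm]]$contributions)
      }))
      utils::write.csv(simtab, file.path(out_dir, "simper.csv"),
                       row.names = FALSE)
    }
    write_manifest(out_dir, "stats",
                   list(design = design, distance = distance,
                        response = response, factors = factors,
                        normalize_columns = normalize_columns,
                        fourth_root = fourth_root,
                        n_perm = n_perm, seed = seed, alpha = alpha))
  }
  list(permanova = res, pairwise = pw, simper = sim, distance = D)
}
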