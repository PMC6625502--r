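# Segmentation of frames into pixel classes, connected-component labelling
# of open-polyp patches, and overlap-based tracking of patches through time.

#' Segment a frame into open-polyp / coenenchyme / background classes
#'
#' Nearest-class-centroid classification in RGB: every pixel is assigned to
#' the class whose reference colour is closest in squared RGB distance. With
#' the default palette (the renderer's own colours) this recovers the
#' ground-truth mask exactly on noise-free synthetic frames; the white
#' polyp / red coenenchyme / black background contrast of the recordings is
#' what makes the rule work.
#'
#' @param image Height x width x 3 numeric array, channels in \[0, 1\].
#' @param palette 3 x 3 matrix of class reference colours (rows background,
#'   coenenchyme, open_polyp), as from [class_palette()].
#' @param denoise If TRUE, one binary morphological opening (3 x 3 element)
#'   is applied to the open-polyp class to suppress speckle; removed pixels
#'   are reassigned to their nearest remaining class.
#'
#' @return Integer matrix of class codes (0 background, 1 coenenchyme,
#'   2 open polyp), same height/width as the frame.
#' @export
segment_frame <- function(image, palette = class_palette(), denoise = FALSE) {
  abort_if(length(dim(image)) != 3 || dim(image)[3] != 3,
           "image must be a height x width x 3 array")
  h <- dim(image)[1]; w <- dim(image)[2]
  abort_if(h == 0 || w == 0, "frame is empty")
  px <- matrix(image, h * w, 3)
  d <- sapply(1:3, function(k) {
    rowSums((px - matrix(palette[k, ], h * w, 3, byrow = TRUE))^2)
  })
  lab <- max.col(-d, ties.method = "first") - 1L
  mask <- matrix(as.integer(lab), h, w)
  if (denoise) {
    open_bin <- mask == CLASS_OPEN_POLYP
    opened <- binary_opening_3x3(open_bin)
    dropped <- open_bin & !opened
    if (any(dropped)) {
      # reassign to the nearer of the two remaining classes
      d_bg <- d[, CLASS_BACKGROUND + 1L]
      d_co <- d[, CLASS_COENENCHYME + 1L]
      mask[dropped] <- ifelse(d_co[dropped] < d_bg[dropped],
                              CLASS_COENENCHYME, CLASS_BACKGROUND)
    }
  }
  mask
}

# One binary opening (erosion then dilation) with a 3x3 structuring
# element, implemented with vectorised shifts.
binary_opening_3x3 <- function(b) {
  shift <- function(m, dr, dc) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  er <- b
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    er <- er & shift(b, dr, dc)
  }
  di <- er
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    di <- di | shift(er, dr, dc)
  }
  di
}

#' Label connected open-polyp regions
#'
#' Connected components (8-connectivity) of the OPEN_POLYP class, dropping
#' components smaller than `min_area_px`. Region ids are assigned in
#' column-major scan order of each component's first pixel. Coordinates are
#' 0-based with origin at the top-left pixel centre; bounding boxes are
#' half-open (`x1`, `y1` exclusive).
#'
#' @param mask Integer class matrix from [segment_frame()].
#' @param min_area_px Minimum region area in pixels (default 5, to suppress
#'   compression speckle).
#'
#' @return Object of class `labeled_regions`: list with `labels` (integer
#'   matrix, 0 where no region), `regions` (data frame: `region_id`,
#'   `area_px`, `centroid_x`, `centroid_y`, `x0`, `y0`, `x1`, `y1`) and
#'   `pixels` (list of linear pixel indices per region).
#' @export
label_regions <- function(mask, min_area_px = 5) {
  abort_if(!is.matrix(mask), "mask must be a matrix")
  abort_if(min_area_px < 1, "min_area_px must be >= 1")
  fg <- mask == CLASS_OPEN_POLYP
  lab <- label_components8(fg)
  n_comp <- max(lab)
  keep_pixels <- list(); ids <- integer(0)
  if (n_comp > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
    keep <- which(sizes >= min_area_px)
    idx_by_comp <- split(which(lab > 0L), lab[lab > 0L])
    keep_pixels <- idx_by_comp[as.character(keep)]
    ids <- seq_along(keep)
  }
  h <- nrow(mask)
  labels <- matrix(0L, h, ncol(mask))
  reg <- data.frame(region_id = integer(0), area_px = integer(0),
                    centroid_x = numeric(0), centroid_y = numeric(0),
                    x0 = integer(0), y0 = integer(0),
                    x1 = integer(0), y1 = integer(0))
  for (i in ids) {
    px <- keep_pixels[[i]]
    labels[px] <- i
    rows <- ((px - 1L) %% h)          # 0-based y
    cols <- ((px - 1L) %/% h)         # 0-based x
    reg <- rbind(reg, data.frame(
      region_id = i, area_px = length(px),
      centroid_x = mean(cols), centroid_y = mean(rows),
      x0 = min(cols), y0 = min(rows),
      x1 = max(cols) + 1L, y1 = max(rows) + 1L))
  }
  names(keep_pixels) <- NULL
  structure(list(labels = labels, regions = reg, pixels = keep_pixels),
            class = "labeled_regions")
}

# Iterative flood fill with an explicit queue; 8-neighbour connectivity.
# Components numbered in column-major order of their first pixel.
label_components8 <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  n_fg <- sum(fg)
  if (n_fg == 0L) return(lab)
  queue <- integer(n_fg)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  for (start in which(fg)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      for (k in 1:8) {
        rr <- r + dr[k]; c2 <- cc + dc[k]
        if (rr >= 1L && rr <= h && c2 >= 1L && c2 <= w) {
          q <- (c2 - 1L) * h + rr
          if (fg[q] && lab[q] == 0L) {
            lab[q] <- cur
            tail <- tail + 1L
            queue[tail] <- q
          }
        }
      }
    }
  }
  lab
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d region(s), total area %d px\n",
              nrow(x$regions), sum(x$regions$area_px)))
  invisible(x)
}

#' Track labelled regions across a frame sequence
#'
#' Links regions frame-to-frame by maximal pixel overlap with the last seen
#' extent of each open track. Candidate (track, region) pairs are resolved
#' greedily by overlap (descending), then region area (descending), then
#' region id (ascending). Regions with no overlapping track open new tracks;
#' a track unseen for more than `gap_frames` frames is retired, so a polyp
#' that contracts briefly and re-opens at the same spot keeps its identity.
#'
#' @param regions_seq List of [label_regions()] results, one per frame in
#'   temporal order.
#' @param gap_frames Number of consecutive absent frames a track survives
#'   (default 3).
#'
#' @return Object of class `region_tracks`: list with `observations` (data
#'   frame: `track_id`, `frame`, `region_id`, `area_px`) and `tracks` (data
#'   frame: `track_id`, `first_frame`, `last_frame`, `n_frames_present`).
#' @export
track_regions <- function(regions_seq, gap_frames = 3) {
  abort_if(length(regions_seq) < 1, "need at least one frame")
  abort_if(!all(vapply(regions_seq, inherits, TRUE, "labeled_regions")),
           "regions_seq must be label_regions() outputs")
  track_pixels <- list()       # last seen pixel set per track
  track_last_seen <- integer(0)
  obs <- list()
  next_track <- 1L
  for (t in seq_along(regions_seq)) {
    lr <- regions_seq[[t]]
    n_reg <- nrow(lr$regions)
    active <- which(track_last_seen >= t - 1L - gap_frames)
    assigned_reg <- rep(NA_integer_, n_reg)
    if (n_reg > 0 && length(active) > 0) {
      cand <- NULL
      for (ri in seq_len(n_reg)) {
        px <- lr$pixels[[ri]]
        for (tk in active) {
          ov <- length(intersect(px, track_pixels[[tk]]))
          if (ov > 0) {
            cand <- rbind(cand, c(ri, tk, ov, length(px)))
          }
        }
      }
      if (!is.null(cand)) {
        ord <- order(-cand[, 3], -cand[, 4], cand[, 1], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        used_track <- logical(next_track)
        for (k in seq_len(nrow(cand))) {
          ri <- cand[k, 1]; tk <- cand[k, 2]
          if (is.na(assigned_reg[ri]) && !used_track[tk]) {
            assigned_reg[ri] <- tk
            used_track[tk] <- TRUE
          }
        }
      }
    }
    for (ri in seq_len(n_reg)) {
      tk <- assigned_reg[ri]
      if (is.na(tk)) {
        tk <- next_track
        next_track <- next_track + 1L
        track_pixels[[tk]] <- lr$pixels[[ri]]
        track_last_seen[tk] <- t
      } else {
        track_pixels[[tk]] <- lr$pixels[[ri]]
        track_last_seen[tk] <- t
      }
      obs[[length(obs) + 1L]] <- data.frame(
        track_id = tk, frame = t, region_id = ri,
        area_px = lr$regions$area_px[ri])
    }
  }
  observations <- if (length(obs)) {
    do.call(rbind, obs)
  } else {
    data.frame(track_id = integer(0), frame = integer(0),
               region_id = integer(0), area_px = integer(0))
  }
  tracks <- if (nrow(observations)) {
    agg <- split(observations, observations$track_id)
    do.call(rbind, lapply(agg, function(d) data.frame(
      track_id = d$track_id[1], first_frame = min(d$frame),
      last_frame = max(d$frame), n_frames_present = nrow(d))))
  } else {
    data.frame(track_id = integer(0), first_frame = integer(0),
               last_frame = integer(0), n_frames_present = integer(0))
  }
  rownames(tracks) <- NULL
  structure(list(observations = observations, tracks = tracks,
                 gap_frames = gap_frames),
            class = "region_tracks")
}

#' @export
print.region_tracks <- function(x, ...) {
  cat(sprintf("<region_tracks> %d track(s) over %d observation(s)\n",
              nrow(x$tracks), nrow(x$observations)))
  invisible(x)
}

#' Read a directory of PNG frames
#'
#' Frames are read in lexicographic filename order (zero-padded indices).
#'
#' @param dir Directory containing `.png` frames.
#' @return List of height x width x 3 arrays.
#' @export
read_frame_dir <- function(dir) {
  abort_if(!dir.exists(dir), "frame directory '%s' does not exist", dir)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  abort_if(length(files) == 0, "no PNG frames found in '%s'", dir)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE] |> array(dim = c(dim(img)[1], dim(img)[2], 3))
  })
}
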