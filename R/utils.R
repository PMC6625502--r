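# Internal helpers shared across modules.

# Pixel class codes used in segmentation masks and ground-truth masks.
CLASS_BACKGROUND <- 0L
CLASS_COENENCHYME <- 1L
CLASS_OPEN_POLYP <- 2L

#' Default colour palette for the three pixel classes
#'
#' RGB centroids (in \[0, 1\]) for the near-black background, the saturated
#' red coenenchyme and the near-white open polyps. The same palette is used
#' by the renderer and, by default, by the nearest-centroid segmenter, which
#' is what makes noise-free segmentation exact.
#'
#' @return A 3 x 3 numeric matrix, rows named `background`, `coenenchyme`,
#'   `open_polyp`, columns `r`, `g`, `b`.
#' @export
class_palette <- function() {
  pal <- rbind(
    background  = c(0.04, 0.04, 0.05),
    coenenchyme = c(0.72, 0.08, 0.10),
    open_polyp  = c(0.96, 0.95, 0.90)
  )
  colnames(pal) <- c("r", "g", "b")
  pal
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps every generator a pure function of
# (config, seed) with no global side effects.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Stop with a formatted message.
abort_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
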