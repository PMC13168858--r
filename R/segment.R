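# Geometric (threshold-based) segmenter: the desk-scale stand-in for a
# learned instance-segmentation model on rendered synthetic frames.

# 4-connected component labelling via row runs + union-find.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (!any(mask)) return(lab)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  nxt <- 0L
  prev_runs <- NULL  # data.frame(from, to, lab) of previous row
  for (r in seq_len(h)) {
    row <- mask[r, ]
    rl <- rle(row)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    keep <- rl$values
    runs <- data.frame(from = starts[keep], to = ends[keep],
                       lab = rep(0L, sum(keep)))
    if (nrow(runs)) for (k in seq_len(nrow(runs))) {
      hit <- 0L
      if (!is.null(prev_runs) && nrow(prev_runs)) {
        ov <- prev_runs$from <= runs$to[k] & prev_runs$to >= runs$from[k]
        for (pl in prev_runs$lab[ov]) {
          if (hit == 0L) hit <- find(pl)
          else {
            rp <- find(pl)
            if (rp != hit) parent[max(rp, hit)] <- min(rp, hit)
            hit <- min(rp, hit)
          }
        }
      }
      if (hit == 0L) { nxt <- nxt + 1L; parent[nxt] <- nxt; hit <- nxt }
      runs$lab[k] <- hit
      lab[r, runs$from[k]:runs$to[k]] <- hit
    }
    prev_runs <- runs
  }
  # resolve unions and relabel compactly
  roots <- vapply(seq_len(nxt), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- compact[lab[lab > 0L]]
  lab
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (!any(lab > 0L)) return(mask & FALSE)
  tb <- tabulate(lab[lab > 0L])
  lab == which.max(tb)
}

#' Segment an eye frame geometrically
#'
#' Lightweight stand-in for a learned segmenter on synthetic frames:
#' intensity is min-max normalised (suppressing over-exposure by clipping to
#' `[0, 1]`), then two-threshold labelling is applied. The darkest connected
#' blob becomes the pupil, the surrounding mid-intensity region (plus the
#' pupil) the iris, and the aperture (pupil, iris and bright sclera) the
#' palpebral fissure. When no pupil or iris evidence exists (closed eye,
#' blank frame) all three masks are empty.
#'
#' @param frame single-channel image matrix.
#' @param thresholds normalized cut-points: below `pupil` is pupil, between
#'   `pupil` and `iris` is iris, above `sclera` is sclera.
#' @return list of class `frame_masks` with logical `palpebral_fissure`,
#'   `iris`, `pupil` and a `confidence` attribute (fixed at 1 per structure).
#' @export
geometric_segment_frame <- function(frame,
                                    thresholds = c(pupil = 0.25, iris = 0.60,
                                                   sclera = 0.85)) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("frame must be a 2D numeric matrix")
  # normalise by the brightest pixel (sclera anchor) and clip overexposure;
  # min-max scaling would promote skin to "darkest" on closed-eye frames
  img <- frame
  mx <- max(img, na.rm = TRUE)
  if (mx > 0) img <- img / mx
  img <- pmin(pmax(img, 0), 1)
  empty <- matrix(FALSE, nrow(frame), ncol(frame))
  pupil_cand <- img < thresholds[["pupil"]]
  iris_cand <- img >= thresholds[["pupil"]] & img < thresholds[["iris"]]
  sclera <- img > thresholds[["sclera"]]
  if (!any(pupil_cand) && !any(iris_cand)) {
    out <- list(palpebral_fissure = empty, iris = empty, pupil = empty)
  } else {
    pupil <- if (any(pupil_cand)) largest_component(pupil_cand) else empty
    iris <- largest_component(iris_cand | pupil)
    fissure <- iris | sclera
    out <- list(palpebral_fissure = fissure, iris = iris, pupil = pupil)
  }
  structure(out, confidence = c(palpebral_fissure = 1, iris = 1, pupil = 1),
            class = "frame_masks")
}
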