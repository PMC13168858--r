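#' Eye rendering geometry
#'
#' Geometry for rendering synthetic single-eye grayscale frames. Intensities
#' follow the appearance of IR eye imagery after normalisation: bright
#' sclera, mid-gray iris, dark pupil, and eyelid skin outside the palpebral
#' aperture.
#'
#' @param width,height image size in pixels.
#' @param centre eye centre (x, y) in pixel coordinates.
#' @param iris_radius iris radius, pixels.
#' @param fissure_width horizontal extent of the palpebral aperture, pixels.
#' @param levels named intensities in `[0, 1]` for skin, sclera, iris, pupil.
#' @return list of class `eye_geometry`.
#' @export
eye_geometry <- function(width = 160, height = 120, centre = c(80, 60),
                         iris_radius = 22, fissure_width = 90,
                         levels = c(skin = 0.70, sclera = 0.95,
                                    iris = 0.45, pupil = 0.05)) {
  g <- list(width = as.integer(width), height = as.integer(height),
            centre = centre, iris_radius = iris_radius,
            fissure_width = fissure_width, levels = levels)
  if (width < 8 || height < 8) stop("image too small")
  if (centre[1] <= 0 || centre[1] > width || centre[2] <= 0 || centre[2] > height)
    stop("eye centre outside the image")
  if (iris_radius >= min(centre[1], width - centre[1],
                         centre[2], height - centre[2]))
    stop("iris_radius inconsistent with image size")
  if (fissure_width > width) stop("fissure_width exceeds image width")
  structure(g, class = "eye_geometry")
}

# logical H x W mask of an axis-aligned ellipse (pixel centres at integers)
ellipse_mask <- function(width, height, cx, cy, a, b) {
  if (a <= 0 || b <= 0) return(matrix(FALSE, height, width))
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  y <- matrix(seq_len(height), height, width)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

disk_mask <- function(width, height, cx, cy, r)
  ellipse_mask(width, height, cx, cy, r, r)

#' Render frames and ground-truth masks from a trace
#'
#' Produces grayscale frames (matrices in `[0, 1]`, rows = image y) and
#' pixel-exact ground-truth masks for the palpebral fissure, iris and pupil.
#' The aperture is an ellipse whose vertical extent equals the trace's
#' fissure length; the iris and pupil are concentric disks centred on the
#' pupil centroid and clipped to the aperture. Frames where the pupil is
#' invalid render only the (possibly tiny) aperture; a fully closed frame
#' yields empty pupil and iris masks.
#'
#' @param trace an [ocular_trace()].
#' @param geometry an [eye_geometry()]; its iris radius must exceed the
#'   trace's pupil radii.
#' @param frames which frames (0-based indices) to render; defaults to all.
#' @return list with `frames` (list of matrices) and `masks` (list of
#'   per-frame lists with logical `palpebral_fissure`, `iris`, `pupil`).
#' @export
render_frames_and_masks <- function(trace, geometry = eye_geometry(),
                                    frames = trace$frame) {
  stopifnot(inherits(trace, "ocular_trace"), inherits(geometry, "eye_geometry"))
  if (any(trace$pupil_diameter / 2 >= geometry$iris_radius, na.rm = TRUE))
    stop("pupil radius exceeds iris radius: geometry inconsistent with trace")
  w <- geometry$width; h <- geometry$height; lv <- geometry$levels
  idx <- match(frames, trace$frame)
  if (anyNA(idx)) stop("requested frames not present in trace")
  out_frames <- vector("list", length(idx))
  out_masks <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    ap_b <- trace$fissure_length[i] / 2
    aperture <- ellipse_mask(w, h, geometry$centre[1], geometry$centre[2],
                             geometry$fissure_width / 2, ap_b)
    img <- matrix(lv[["skin"]], h, w)
    img[aperture] <- lv[["sclera"]]
    if (trace$valid[i] && !is.na(trace$pupil_diameter[i])) {
      cx <- trace$pupil_x[i]; cy <- trace$pupil_y[i]
      iris <- disk_mask(w, h, cx, cy, geometry$iris_radius) & aperture
      pupil <- disk_mask(w, h, cx, cy, trace$pupil_diameter[i] / 2) & aperture
      img[iris] <- lv[["iris"]]
      img[pupil] <- lv[["pupil"]]
    } else {
      iris <- matrix(FALSE, h, w)
      pupil <- matrix(FALSE, h, w)
    }
    out_frames[[k]] <- img
    out_masks[[k]] <- list(palpebral_fissure = aperture, iris = iris,
                           pupil = pupil)
  }
  list(frames = out_frames, masks = out_masks)
}

#' Export frames as images
#'
#' Writes a numbered image sequence. Plain-text ASCII PGM (P2) is always
#' available; PNG requires the optional \pkg{png} package.
#'
#' @param frames list of grayscale matrices in `[0, 1]`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param format `"pgm"` (ASCII, text-only) or `"png"`.
#' @return character vector of paths, invisibly.
#' @export
write_frame_sequence <- function(frames, dir, prefix = "frame",
                                 format = c("pgm", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    img <- frames[[i]]
    paths[i] <- file.path(dir, sprintf("%s_%05d.%s", prefix, i - 1L, format))
    if (format == "pgm") {
      v <- round(pmin(pmax(img, 0), 1) * 255)
      con <- file(paths[i], "w")
      writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
      utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
      close(con)
    } else {
      if (!requireNamespace("png", quietly = TRUE))
        stop("the 'png' package is required for PNG export")
      png::writePNG(pmin(pmax(img, 0), 1), paths[i])
    }
  }
  invisible(paths)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path file written by [write_frame_sequence()] or any P2 PGM.
#' @return grayscale matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (txt[1] != "P2") stop("only ASCII PGM (P2) supported")
  w <- as.integer(txt[2]); h <- as.integer(txt[3]); mx <- as.numeric(txt[4])
  vals <- as.numeric(txt[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / mx
}
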