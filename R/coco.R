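# COCO-style polygon JSON for the three ocular structures.

coco_categories <- function() {
  data.frame(id = 1:3,
             name = c("palpebral_fissure", "iris", "pupil"),
             supercategory = "eye")
}

# Trace the outline(s) of a binary mask as polygons in pixel coordinates
# (x = column, y = row). Uses the 0.5 level-set of the zero-padded mask, so
# the polygon passes midway between boundary and background pixel centres
# and re-rasterises to (nearly) the same pixel set.
mask_to_polygons <- function(mask) {
  if (!any(mask)) return(list())
  h <- nrow(mask); w <- ncol(mask)
  z <- matrix(0, h + 2, w + 2)
  z[2:(h + 1), 2:(w + 1)] <- mask * 1
  # contourLines: x along rows of z, y along columns
  cl <- grDevices::contourLines(x = 0:(h + 1), y = 0:(w + 1), z = z,
                                levels = 0.5)
  lapply(cl, function(p) list(x = p$y, y = p$x))  # swap: cols are x
}

# Rasterise polygons back to a logical mask (even-odd via point.in.polygon;
# boundary pixels count as inside).
polygons_to_mask <- function(polys, height, width) {
  m <- matrix(FALSE, height, width)
  if (!length(polys)) return(m)
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  inside <- rep(0L, height * width)
  for (p in polys)
    inside <- inside + as.integer(
      sp::point.in.polygon(as.vector(xs), as.vector(ys), p$x, p$y) > 0)
  m[] <- (inside %% 2L) == 1L  # even-odd: holes subtract
  m
}

#' Write masks as COCO-style polygon JSON
#'
#' Serialises per-frame structure masks as a COCO detection/segmentation
#' file: `images`, `categories` (palpebral_fissure = 1, iris = 2, pupil = 3)
#' and `annotations` with polygon segmentations, bounding boxes and areas.
#'
#' @param mask_stack list of per-frame mask lists as produced by
#'   [render_frames_and_masks()]`$masks` or [geometric_segment_frame()]
#'   (named logical matrices per structure).
#' @param path output JSON file.
#' @param scores optional per-frame named numeric confidences to store with
#'   each annotation (defaults to 1).
#' @return `path`, invisibly.
#' @export
write_coco_json <- function(mask_stack, path, scores = NULL) {
  stopifnot(length(mask_stack) >= 1)
  cats <- coco_categories()
  h <- nrow(mask_stack[[1]][[1]]); w <- ncol(mask_stack[[1]][[1]])
  images <- lapply(seq_along(mask_stack), function(i)
    list(id = i, width = w, height = h,
         file_name = sprintf("frame_%05d.png", i - 1L)))
  anns <- list(); aid <- 0L
  for (i in seq_along(mask_stack)) {
    for (s in names(mask_stack[[i]])) {
      mk <- mask_stack[[i]][[s]]
      if (!is.matrix(mk) || !any(mk)) next
      polys <- mask_to_polygons(mk)
      seg <- lapply(polys, function(p) as.vector(rbind(p$x, p$y)))
      ij <- which(mk, arr.ind = TRUE)
      bb <- c(min(ij[, 2]), min(ij[, 1]),
              diff(range(ij[, 2])) + 1, diff(range(ij[, 1])) + 1)
      aid <- aid + 1L
      sc <- if (!is.null(scores)) scores[[i]][[s]] else 1
      anns[[aid]] <- list(id = aid, image_id = i,
                          category_id = cats$id[match(s, cats$name)],
                          segmentation = seg, area = sum(mk),
                          bbox = bb, iscrowd = 0, score = sc)
    }
  }
  obj <- list(images = images,
              categories = lapply(seq_len(nrow(cats)), function(k)
                as.list(cats[k, ])),
              annotations = anns)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-style polygon JSON into masks
#'
#' @param path JSON file written by [write_coco_json()] or a compatible
#'   COCO segmentation export.
#' @return list of per-frame lists of logical masks named by structure,
#'   with per-structure `confidence` attributes.
#' @export
read_coco_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cats <- vapply(obj$categories, function(c) c$name, character(1))
  names(cats) <- vapply(obj$categories, function(c) as.character(c$id),
                        character(1))
  dims <- lapply(obj$images, function(im) c(h = im$height, w = im$width))
  names(dims) <- vapply(obj$images, function(im) as.character(im$id),
                        character(1))
  out <- lapply(obj$images, function(im)
    structure(list(), image_id = im$id))
  names(out) <- names(dims)
  for (a in obj$annotations) {
    d <- dims[[as.character(a$image_id)]]
    polys <- lapply(a$segmentation, function(flat) {
      v <- unlist(flat)
      list(x = v[seq(1, length(v), 2)], y = v[seq(2, length(v), 2)])
    })
    mk <- polygons_to_mask(polys, d[["h"]], d[["w"]])
    nm <- cats[[as.character(a$category_id)]]
    key <- as.character(a$image_id)
    out[[key]][[nm]] <- mk
    conf <- attr(out[[key]], "confidence")
    conf[nm] <- if (!is.null(a$score)) a$score else 1
    attr(out[[key]], "confidence") <- conf
  }
  out
}
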