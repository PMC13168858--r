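#' Dice and IoU overlap between two masks
#'
#' `dice = 2|A∩B| / (|A|+|B|)`, `iou = |A∩B| / |A∪B|`. By convention two
#' empty masks agree perfectly and score 1; an empty vs a non-empty mask
#' scores 0.
#'
#' @param mask_a,mask_b equal-shaped logical (or 0/1) matrices.
#' @return named numeric `c(dice, iou)` as fractions in `[0, 1]`.
#' @examples
#' a <- matrix(FALSE, 10, 10); a[1:10, 1:10] <- TRUE
#' b <- matrix(FALSE, 10, 10); b[1:5, 1:10] <- TRUE
#' overlap_scores(a, b)  # dice 2/3, iou 1/2
#' @export
overlap_scores <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("mask shapes differ: ", paste(dim(mask_a), collapse = "x"), " vs ",
         paste(dim(mask_b), collapse = "x"))
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  if (na + nb == 0) return(c(dice = 1, iou = 1))
  c(dice = 2 * ni / (na + nb), iou = ni / (na + nb - ni))
}

iou_of <- function(a, b) unname(overlap_scores(a, b)[["iou"]])

# IoU matrix between two lists of masks (rows = first list)
iou_matrix <- function(preds, truths) {
  m <- matrix(0, length(preds), length(truths))
  for (i in seq_along(preds)) for (j in seq_along(truths))
    m[i, j] <- iou_of(preds[[i]], truths[[j]])
  m
}

extract_mask <- function(x) if (is.list(x)) x$mask else x
extract_conf <- function(x) {
  if (is.list(x) && !is.null(x$confidence)) x$confidence else 1
}

#' One-to-one instance matching (Hungarian assignment)
#'
#' Finds the assignment of predicted to ground-truth instances maximising
#' total IoU, then drops pairs below `iou_threshold`. Unmatched predictions
#' are false positives, unmatched truths false negatives.
#'
#' @param predicted list of masks, or of `list(mask =, confidence =)`.
#' @param truth list of ground-truth masks.
#' @param iou_threshold minimum IoU for a pair to stand, in `(0, 1]`.
#' @return list with `pairs` (data frame `pred`, `truth`, `iou`),
#'   `false_positives` and `false_negatives` (integer indices).
#' @export
match_instances <- function(predicted, truth, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must be in (0, 1]")
  np <- length(predicted); nt <- length(truth)
  empty <- list(pairs = data.frame(pred = integer(0), truth = integer(0),
                                   iou = numeric(0)),
                false_positives = seq_len(np), false_negatives = seq_len(nt))
  if (np == 0 || nt == 0) return(empty)
  pm <- lapply(predicted, extract_mask)
  m <- iou_matrix(pm, truth)
  if (np <= nt) {
    sol <- clue::solve_LSAP(m, maximum = TRUE)
    pred_idx <- seq_len(np); truth_idx <- as.integer(sol)
  } else {
    sol <- clue::solve_LSAP(t(m), maximum = TRUE)
    truth_idx <- seq_len(nt); pred_idx <- as.integer(sol)
  }
  iou <- m[cbind(pred_idx, truth_idx)]
  keep <- iou >= iou_threshold
  pairs <- data.frame(pred = pred_idx[keep], truth = truth_idx[keep],
                      iou = iou[keep])
  list(pairs = pairs,
       false_positives = setdiff(seq_len(np), pairs$pred),
       false_negatives = setdiff(seq_len(nt), pairs$truth))
}

# ---- COCO-style detection metrics ------------------------------------------

# normalise inputs to per-image lists
as_image_list <- function(x) {
  if (length(x) == 0) return(list())
  first <- x[[1]]
  if (is.matrix(first) || (is.list(first) && !is.null(first$mask))) list(x)
  else x
}

#' COCO-style AP and AR for one category
#'
#' Average precision from the confidence-ranked precision-recall curve with
#' COCO 101-point interpolation, evaluated at IoU thresholds 0.50 to 0.95 in
#' steps of 0.05 (greedy highest-IoU matching per threshold, predictions
#' ranked by confidence, ties broken by larger area). AR is the final recall
#' averaged over the same thresholds. Values are percentages.
#'
#' @param predictions per-image list of predicted masks (each a matrix or
#'   `list(mask =, confidence =)`); a flat list is treated as one image.
#' @param truths per-image list of ground-truth masks.
#' @return named numeric `c(ap50, ap50_95, ar50_95)` in percent, or `NA`s
#'   when there are no ground-truth instances.
#' @export
coco_detection_metrics <- function(predictions, truths) {
  preds <- as_image_list(predictions)
  gts <- as_image_list(truths)
  n_img <- max(length(preds), length(gts))
  length(preds) <- n_img; length(gts) <- n_img
  n_gt <- sum(vapply(gts, length, integer(1)))
  if (n_gt == 0)
    return(c(ap50 = NA_real_, ap50_95 = NA_real_, ar50_95 = NA_real_))

  # flatten predictions with image ids, confidences, areas
  tab <- do.call(rbind, lapply(seq_len(n_img), function(i) {
    p <- preds[[i]]
    if (!length(p)) return(NULL)
    data.frame(img = i, idx = seq_along(p),
               conf = vapply(p, extract_conf, numeric(1)),
               area = vapply(p, function(q) sum(extract_mask(q)), numeric(1)))
  }))
  thresholds <- seq(0.5, 0.95, by = 0.05)
  if (is.null(tab) || nrow(tab) == 0) {
    aps <- rep(0, length(thresholds)); recs <- rep(0, length(thresholds))
  } else {
    ord <- order(-tab$conf, -tab$area)
    tab <- tab[ord, , drop = FALSE]
    ious <- lapply(seq_len(n_img), function(i) {
      p <- preds[[i]]
      if (!length(p) || !length(gts[[i]]))
        return(matrix(0, length(p), length(gts[[i]])))
      iou_matrix(lapply(p, extract_mask), gts[[i]])
    })
    aps <- recs <- numeric(length(thresholds))
    for (ti in seq_along(thresholds)) {
      t <- thresholds[ti]
      used <- lapply(gts, function(g) rep(FALSE, length(g)))
      tp <- logical(nrow(tab))
      for (r in seq_len(nrow(tab))) {
        i <- tab$img[r]
        m <- ious[[i]]
        if (!ncol(m)) next
        cand <- m[tab$idx[r], ]
        cand[used[[i]]] <- -1
        j <- which.max(cand)
        if (cand[j] >= t) { tp[r] <- TRUE; used[[i]][j] <- TRUE }
      }
      ctp <- cumsum(tp)
      prec <- ctp / seq_along(tp)
      rec <- ctp / n_gt
      # precision envelope + 101-point interpolation
      env <- rev(cummax(rev(prec)))
      rpts <- seq(0, 1, by = 0.01)
      ip <- vapply(rpts, function(r0) {
        k <- which(rec >= r0)
        if (length(k)) env[k[1]] else 0
      }, numeric(1))
      aps[ti] <- mean(ip)
      recs[ti] <- max(c(0, rec))
    }
  }
  c(ap50 = 100 * aps[1], ap50_95 = 100 * mean(aps),
    ar50_95 = 100 * mean(recs))
}

#' Score one frame's predicted masks against ground truth
#'
#' @param pred,truth named lists of structure masks for one frame.
#' @param image image identifier.
#' @param eye eye label attached to the rows.
#' @return data frame with one row per structure: pixel counts and
#'   dice / iou fractions.
#' @export
score_frame_masks <- function(pred, truth, image = 1L, eye = "left") {
  structures <- union(names(truth), names(pred))
  do.call(rbind, lapply(structures, function(s) {
    p <- pred[[s]]; g <- truth[[s]]
    if (is.null(p)) p <- g & FALSE
    if (is.null(g)) g <- p & FALSE
    ov <- overlap_scores(p, g)
    data.frame(image = image, eye = eye, structure = s,
               n_pred = sum(p), n_truth = sum(g), n_intersect = sum(p & g),
               dice = ov[["dice"]], iou = ov[["iou"]])
  }))
}

#' Aggregate per-image structure scores
#'
#' Macro aggregation is the unweighted mean across structures (per-structure
#' values first averaged across images and across eyes); micro aggregation
#' recomputes Dice and IoU from intersection/union pixel counts pooled over
#' all structures and images. Reported as percentages.
#'
#' @param scores data frame as produced by rbind-ing [score_frame_masks()].
#' @return list with `per_structure` (percent Dice/IoU per structure),
#'   `macro` and `micro` (named numerics).
#' @export
aggregate_structure_scores <- function(scores) {
  if (is.null(scores) || !nrow(scores)) stop("no scores to aggregate")
  per_eye <- stats::aggregate(cbind(dice, iou) ~ structure + eye,
                              data = scores, FUN = mean)
  per_structure <- stats::aggregate(cbind(dice, iou) ~ structure,
                                    data = per_eye, FUN = mean)
  per_structure$dice <- 100 * per_structure$dice
  per_structure$iou <- 100 * per_structure$iou
  macro <- c(dice = mean(per_structure$dice), iou = mean(per_structure$iou))
  ni <- sum(scores$n_intersect)
  np <- sum(scores$n_pred); ng <- sum(scores$n_truth)
  micro <- if (np + ng == 0) c(dice = 100, iou = 100) else
    c(dice = 100 * 2 * ni / (np + ng), iou = 100 * ni / (np + ng - ni))
  list(per_structure = per_structure, macro = macro, micro = micro)
}

#' Write a segmentation score table CSV
#'
#' @param agg result of [aggregate_structure_scores()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(agg, path) {
  df <- rbind(agg$per_structure,
              data.frame(structure = "overall_macro",
                         dice = agg$macro[["dice"]], iou = agg$macro[["iou"]]),
              data.frame(structure = "overall_micro",
                         dice = agg$micro[["dice"]], iou = agg$micro[["iou"]]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
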