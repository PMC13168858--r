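# shared fixtures, all generated in code

# constant-signal trace with optional injected closures / centroid path
mk_trace <- function(n, fissure = 40, pupil = 30, x = 80, y = 60,
                     valid = TRUE, frame_rate = 30, start = 0L) {
  ocular_trace(seq_len(n) - 1L + start,
               rep_len(fissure, n), rep_len(pupil, n),
               rep_len(x, n), rep_len(y, n), rep_len(valid, n),
               frame_rate = frame_rate)
}

# inject a closure run [from, to] (0-based) into a trace
close_frames <- function(trace, from, to, level = 2) {
  idx <- trace$frame >= from & trace$frame <= to
  trace$fissure_length[idx] <- level
  trace$pupil_diameter[idx] <- NA_real_
  trace$valid[idx] <- FALSE
  trace
}

rand_mask <- function(h = 12, w = 12, p = 0.3) matrix(runif(h * w) < p, h, w)

# axis-aligned rectangle mask
rect_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w); m[rows, cols] <- TRUE; m
}

# brute-force optimal assignment total IoU (<= 6 x 6)
brute_best_iou <- function(iou) {
  n <- nrow(iou); m <- ncol(iou)
  if (n == 0 || m == 0) return(0)
  k <- min(n, m)
  big <- if (n <= m) iou else t(iou)
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- 0
  for (cols in utils::combn(ncol(big), k, simplify = FALSE))
    for (p in perms(cols))
      best <- max(best, sum(big[cbind(seq_len(k), p)]))
  best
}

# separable two-class feature table for classifier sanity checks
separable_features <- function(n_per_class = 25, seed = 1) {
  set.seed(seed)
  data.frame(
    sig = c(rnorm(n_per_class, 3, 0.3), rnorm(n_per_class, -3, 0.3)),
    noise1 = rnorm(2 * n_per_class), noise2 = rnorm(2 * n_per_class),
    label = rep(c("deteriorated", "nondeteriorated"), each = n_per_class))
}

result_row_for_test <- function(name, p) {
  structure(list(feature_name = name, test = "mann_whitney_u", statistic = 0,
                 p_value = p, group_summaries = NULL),
            class = "group_comparison_result")
}

fast_rf <- function() model_spec("random_forest",
                                 grid = data.frame(n_trees = 50,
                                                   max_depth = Inf))
fast_tree <- function() model_spec("decision_tree",
                                   grid = data.frame(max_depth = 3,
                                                     min_leaf = 2))
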