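#' Analysis frame windows
#'
#' The one-minute recording is analysed between frames 200 and 1800 (the
#' first 200 frames are discarded to avoid initial eye-opening movements).
#' Windowed variability uses three task-difficulty segments plus the full
#' analysed range. Windows are half-open `[start, end)` on 0-based frames.
#'
#' @param name one of `"early"`, `"mid"`, `"late"`, `"all"`.
#' @return named integer vector `c(start, end)`.
#' @export
window_spec <- function(name = c("early", "mid", "late", "all")) {
  name <- match.arg(name)
  switch(name,
         early = c(start = 200L, end = 600L),
         mid   = c(start = 600L, end = 1200L),
         late  = c(start = 1200L, end = 1800L),
         all   = c(start = 200L, end = 1800L))
}

#' Derive a trace from a mask stack
#'
#' Converts per-frame structure masks into an [ocular_trace()]: the fissure
#' length is the vertical extent (max row - min row + 1) of the palpebral
#' fissure mask, the pupil diameter is the diameter of the circle with the
#' pupil mask's area (`2 * sqrt(area / pi)`), and the centroid is the pupil
#' mask centroid. Frames with an empty pupil mask are marked invalid.
#'
#' @param mask_stack list of per-frame mask lists (`palpebral_fissure`,
#'   `iris`, `pupil`).
#' @param frame_rate frames per second.
#' @param eye eye label.
#' @param fissure_extent `"vertical"` (eyelid aperture; default) or
#'   `"horizontal"` (mask width) - the anatomical reading of "fissure
#'   length" is configurable.
#' @return an [ocular_trace()].
#' @export
trace_from_masks <- function(mask_stack, frame_rate = 30, eye = "left",
                             fissure_extent = c("vertical", "horizontal")) {
  fissure_extent <- match.arg(fissure_extent)
  if (!length(mask_stack)) stop("empty mask stack")
  dims <- lapply(mask_stack, function(m) dim(m[[1]]))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("inconsistent image shapes in mask stack")
  n <- length(mask_stack)
  fl <- pd <- px <- py <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  dimsel <- if (fissure_extent == "vertical") 1L else 2L
  for (i in seq_len(n)) {
    fm <- mask_stack[[i]]$palpebral_fissure
    pm <- mask_stack[[i]]$pupil
    fl[i] <- if (!is.null(fm) && any(fm)) {
      ij <- which(fm, arr.ind = TRUE)
      diff(range(ij[, dimsel])) + 1
    } else 0
    if (!is.null(pm) && any(pm)) {
      ij <- which(pm, arr.ind = TRUE)
      pd[i] <- 2 * sqrt(sum(pm) / pi)
      px[i] <- mean(ij[, 2]); py[i] <- mean(ij[, 1])
      valid[i] <- TRUE
    }
  }
  ocular_trace(seq_len(n) - 1L, fl, pd, px, py, valid,
               eye = eye, frame_rate = frame_rate)
}

# Open-eye baseline aperture: 95th percentile of fissure length.
aperture_baseline <- function(trace) {
  stats::quantile(trace$fissure_length, 0.95, na.rm = TRUE, names = FALSE)
}

#' Detect blinks from the eyelid aperture signal
#'
#' A blink is a maximal run of at least `min_frames` consecutive frames in
#' which the fissure length is at most `(1 - closure_fraction)` times the
#' open-eye baseline (the 95th percentile of the fissure signal), matching
#' the "at least 80% closed" PERCLOS criterion at the default.
#'
#' @param trace an [ocular_trace()].
#' @param closure_fraction minimum closure (default 0.8 = 80% closed).
#' @param min_frames minimum run length (rejects single-frame noise).
#' @return data frame of class `blink_events` with 0-based inclusive
#'   `start_frame`, `end_frame` and `duration` in ms
#'   (`(end - start + 1) * 1000 / frame_rate`).
#' @export
detect_blinks <- function(trace, closure_fraction = 0.8, min_frames = 2L) {
  stopifnot(nrow(trace) >= 1)
  fr <- frame_rate_of(trace)
  base <- aperture_baseline(trace)
  closed <- trace$fissure_length <= (1 - closure_fraction) * base
  out <- data.frame(start_frame = integer(0), end_frame = integer(0),
                    duration = numeric(0))
  if (base <= 0 || all(closed)) {
    warning("aperture signal never open; no blinks detectable")
  } else {
    runs <- true_runs(closed)
    runs <- runs[runs$end - runs$start + 1L >= min_frames, , drop = FALSE]
    if (nrow(runs)) {
      out <- data.frame(
        start_frame = trace$frame[runs$start],
        end_frame = trace$frame[runs$end],
        duration = (runs$end - runs$start + 1L) * 1000 / fr)
    }
  }
  class(out) <- c("blink_events", "data.frame")
  out
}

#' Summary blink metrics
#'
#' @param events a `blink_events` data frame from [detect_blinks()].
#' @param analyzed_duration analysed time span in seconds (> 0).
#' @param frame_rate frames per second (needed for intervals).
#' @return named numeric: `blink_times_per_min`, `avg_blink_duration` (ms),
#'   `avg_blink_interval` (ms, offset-to-onset; `NA` with fewer than two
#'   events).
#' @export
blink_metrics <- function(events, analyzed_duration, frame_rate = 30) {
  stopifnot(analyzed_duration > 0)
  n <- nrow(events)
  rate <- n / (analyzed_duration / 60)
  dur <- if (n >= 1) mean(events$duration) else NA_real_
  gap <- if (n >= 2) {
    mean((events$start_frame[-1] - events$end_frame[-n]) * 1000 / frame_rate)
  } else NA_real_
  c(blink_times_per_min = rate, avg_blink_duration = dur,
    avg_blink_interval = gap)
}

#' PERCLOS: percentage of eyelid closure
#'
#' Proportion of analysed frames in which the eye is at least
#' `closure_fraction` closed relative to the same open-eye baseline used by
#' [detect_blinks()].
#'
#' @inheritParams detect_blinks
#' @return percentage in `[0, 100]`.
#' @export
perclos <- function(trace, closure_fraction = 0.8) {
  stopifnot(nrow(trace) >= 1)
  base <- aperture_baseline(trace)
  closed <- trace$fissure_length <= (1 - closure_fraction) * base
  100 * sum(closed) / nrow(trace)
}

#' Detect fixations (dispersion threshold, I-DT)
#'
#' Groups valid pupil-centroid frames into maximal windows whose bounding
#' box satisfies `max(range(x), range(y)) <= dispersion_px` and whose
#' duration is at least `min_duration_ms`. Invalid (blink) frames terminate
#' a window.
#'
#' @param trace an [ocular_trace()].
#' @param dispersion_px spatial dispersion threshold, pixels.
#' @param min_duration_ms minimum fixation duration, ms.
#' @return data frame of class `fixation_events`: `start_frame`,
#'   `end_frame` (0-based inclusive), `x`, `y` (centroid), `duration` (ms).
#' @export
detect_fixations <- function(trace, dispersion_px = 15, min_duration_ms = 100) {
  stopifnot(nrow(trace) >= 1)
  fr <- frame_rate_of(trace)
  min_frames <- max(2L, ceiling(min_duration_ms / 1000 * fr))
  res <- data.frame(start_frame = integer(0), end_frame = integer(0),
                    x = numeric(0), y = numeric(0), duration = numeric(0))
  segs <- true_runs(trace$valid)
  for (s in seq_len(nrow(segs))) {
    i0 <- segs$start[s]; i1 <- segs$end[s]
    i <- i0
    while (i1 - i + 1L >= min_frames) {
      j <- i + min_frames - 1L
      disp <- function(a, b) {
        xs <- trace$pupil_x[a:b]; ys <- trace$pupil_y[a:b]
        max(diff(range(xs)), diff(range(ys)))
      }
      if (disp(i, j) > dispersion_px) { i <- i + 1L; next }
      while (j + 1L <= i1 && disp(i, j + 1L) <= dispersion_px) j <- j + 1L
      res <- rbind(res, data.frame(
        start_frame = trace$frame[i], end_frame = trace$frame[j],
        x = mean(trace$pupil_x[i:j]), y = mean(trace$pupil_y[i:j]),
        duration = (j - i + 1L) * 1000 / fr))
      i <- j + 1L
    }
  }
  class(res) <- c("fixation_events", "data.frame")
  res
}

#' Cumulative eye-movement distance
#'
#' Sum of Euclidean distances between consecutive pupil centroids over frame
#' pairs where both frames are valid; pairs spanning an invalid frame are
#' excluded.
#'
#' @param trace an [ocular_trace()].
#' @return distance in pixels.
#' @export
movement_distance <- function(trace) {
  stopifnot(nrow(trace) >= 1)
  if (sum(trace$valid) < 2) {
    warning("fewer than 2 valid frames; movement distance is 0")
    return(0)
  }
  ok <- trace$valid[-nrow(trace)] & trace$valid[-1]
  dx <- diff(trace$pupil_x); dy <- diff(trace$pupil_y)
  sum(sqrt(dx[ok]^2 + dy[ok]^2))
}

#' Pupil constriction speeds
#'
#' Per valid consecutive frame pair, the signed rate is
#' `(d[t+1] - d[t]) * frame_rate` (pixels/second); constriction steps are
#' those with a negative rate. Returns the maximum and mean constriction
#' speed (as positive numbers), both 0 when the pupil never constricts.
#'
#' @param trace an [ocular_trace()].
#' @return named numeric `c(max_speed, avg_speed)` in pixels/second.
#' @export
constriction_speeds <- function(trace) {
  fr <- frame_rate_of(trace)
  ok <- trace$valid[-nrow(trace)] & trace$valid[-1]
  v <- diff(trace$pupil_diameter)[ok] * fr
  v <- v[!is.na(v) & v < 0]
  if (!length(v)) return(c(max_speed = 0, avg_speed = 0))
  c(max_speed = max(-v), avg_speed = mean(-v))
}

#' Windowed variability of an ocular signal
#'
#' Sample SD (n-1 denominator), variance and coefficient of variation
#' (`100 * sd / mean`, percent) of the pupil size or fissure length within a
#' frame window. Invalid frames are excluded for the pupil signal but
#' included for the fissure signal (the aperture is defined during blinks).
#'
#' @param trace an [ocular_trace()].
#' @param window either a window name understood by [window_spec()] or a
#'   `c(start, end)` half-open 0-based frame range.
#' @param signal `"pupil_size"` or `"fissure_length"`.
#' @return named numeric `c(sd, variance, cv)`; all `NA` with fewer than two
#'   valid samples, `cv` `NA` when the mean is non-positive.
#' @export
windowed_variability <- function(trace, window = "all",
                                 signal = c("pupil_size", "fissure_length")) {
  signal <- match.arg(signal)
  if (is.character(window)) window <- window_spec(window)
  keep <- trace$frame >= window[["start"]] & trace$frame < window[["end"]]
  x <- if (signal == "pupil_size") {
    trace$pupil_diameter[keep & trace$valid]
  } else {
    trace$fissure_length[keep]
  }
  x <- x[!is.na(x)]
  if (length(x) < 2)
    return(c(sd = NA_real_, variance = NA_real_, cv = NA_real_))
  s <- stats::sd(x); m <- mean(x)
  c(sd = s, variance = s^2, cv = if (m > 0) 100 * s / m else NA_real_)
}

# per-frame mean of a signal across the two eyes (NA-aware)
binocular_signal <- function(pair, column) {
  rowMeans(cbind(pair$left[[column]], pair$right[[column]]), na.rm = TRUE)
}

# Merge both eyes into a pseudo-trace carrying the per-frame mean signals;
# a frame is valid when either eye's pupil is visible.
binocular_mean_trace <- function(pair) {
  pd <- binocular_signal(pair, "pupil_diameter")
  pd[is.nan(pd)] <- NA_real_
  fl <- binocular_signal(pair, "fissure_length")
  px <- binocular_signal(pair, "pupil_x"); px[is.nan(px)] <- NA_real_
  py <- binocular_signal(pair, "pupil_y"); py[is.nan(py)] <- NA_real_
  ocular_trace(pair$left$frame, fl, pd, px, py, valid = !is.na(pd),
               eye = attr(pair$left, "eye"),
               frame_rate = frame_rate_of(pair$left))
}

# All metrics for one recording (a left/right trace pair), computed over the
# analysed frame range. Blink, PERCLOS and fixation metrics use the primary
# eye; pupil and movement metrics are averaged over both eyes; variability
# uses the per-frame binocular mean signal.
recording_metrics <- function(pair, range = c(200L, 1800L),
                              primary_eye = "left",
                              closure_fraction = 0.8,
                              dispersion_px = 15, min_duration_ms = 100) {
  if (is.null(pair$left)) pair <- list(left = pair[[1]], right = pair[[1]])
  if (is.null(pair$right)) pair$right <- pair$left
  prim <- trim_trace(pair[[primary_eye]], range[1], range[2])
  fr <- frame_rate_of(prim)
  dur_s <- nrow(prim) / fr
  ev <- suppressWarnings(detect_blinks(prim, closure_fraction))
  bm <- blink_metrics(ev, dur_s, fr)
  fx <- detect_fixations(prim, dispersion_px, min_duration_ms)
  per_eye <- lapply(pair[c("left", "right")], function(tr)
    trim_trace(tr, range[1], range[2]))
  move <- mean(vapply(per_eye, function(tr)
    suppressWarnings(movement_distance(tr)), numeric(1)))
  pupil_mean <- mean(vapply(per_eye, function(tr)
    mean(tr$pupil_diameter[tr$valid]), numeric(1)))
  cs <- rowMeans(vapply(per_eye, constriction_speeds, numeric(2)))
  bino <- binocular_mean_trace(pair)
  varfeat <- c()
  for (wname in c("early", "mid", "late", "all")) {
    for (sig in c("pupil_size", "fissure_length")) {
      v <- windowed_variability(bino, wname, sig)
      names(v) <- paste(sig, names(v), wname, sep = "_")
      varfeat <- c(varfeat, v)
    }
  }
  c(bm,
    perclos = perclos(prim, closure_fraction),
    fixation_number_per_min = nrow(fx) / (dur_s / 60),
    avg_fixation_duration = if (nrow(fx)) mean(fx$duration) else NA_real_,
    avg_eye_movement_distance = move,
    avg_pupil_diameter = pupil_mean,
    max_pupil_constriction_speed = cs[["max_speed"]],
    avg_pupil_constriction_speed = cs[["avg_speed"]],
    varfeat)
}

#' Post-minus-pre feature vector for a session
#'
#' Computes every ocular metric separately on the pre- and post-task
#' recordings over the analysed frame range (default frames 200-1800) and
#' returns the named post-minus-pre differences together with the raw
#' pre/post values. Pupil metrics and the movement distance are averaged
#' over the two eyes; blink, PERCLOS and fixation metrics use the primary
#' eye; variability features use the per-frame binocular mean signal. The
#' critical flicker fusion (CFF) difference is appended (`NA` when missing).
#'
#' @param session a `session_record`, or `NULL` if `pre`/`post` are given.
#' @param pre,post lists with `left`/`right` [ocular_trace()]s (ignored when
#'   `session` is supplied).
#' @param cff_pre,cff_post CFF values in Hz (ignored when `session` given).
#' @param range analysed half-open frame range.
#' @param primary_eye eye used for monocular metrics.
#' @return object of class `feature_vector`: list with named numeric `pre`,
#'   `post` and `diff` (`diff == post - pre`).
#' @export
session_feature_vector <- function(session = NULL, pre = NULL, post = NULL,
                                   cff_pre = NA_real_, cff_post = NA_real_,
                                   range = c(200L, 1800L),
                                   primary_eye = "left") {
  if (!is.null(session)) {
    pre <- session$pre; post <- session$post
    cff_pre <- session$cff_pre; cff_post <- session$cff_post
  }
  m_pre <- c(recording_metrics(pre, range, primary_eye), cff = cff_pre)
  m_post <- c(recording_metrics(post, range, primary_eye), cff = cff_post)
  structure(list(pre = m_pre, post = m_post, diff = m_post - m_pre),
            class = "feature_vector")
}

#' Cohort feature table
#'
#' One row per analysis unit with post-minus-pre difference features,
#' questionnaire scores and the derived deterioration label. With
#' `unit = "eye"` each session contributes two rows (left and right eye used
#' as the monocular signal source in turn), reproducing a per-eye sample
#' layout; with `unit = "participant"` one row per session.
#'
#' @param cohort list of `session_record`s.
#' @param unit `"eye"` or `"participant"`.
#' @param range analysed frame range.
#' @return data frame with id columns (`participant_id`, `eye`,
#'   `truth_group`, `cvsq_pre`, `cvsq_post`, `label`) and one column per
#'   difference feature.
#' @export
cohort_feature_table <- function(cohort, unit = c("eye", "participant"),
                                 range = c(200L, 1800L)) {
  unit <- match.arg(unit)
  eyes <- if (unit == "eye") c("left", "right") else "left"
  rows <- list()
  for (s in cohort) {
    for (e in eyes) {
      fv <- session_feature_vector(s, range = range, primary_eye = e)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant_id = s$participant_id, eye = e,
                   truth_group = s$truth_group,
                   cvsq_pre = s$cvsq_pre, cvsq_post = s$cvsq_post,
                   label = label_deterioration(s$cvsq_pre, s$cvsq_post)),
        as.data.frame(as.list(fv$diff)))
    }
  }
  do.call(rbind, rows)
}

#' Write a per-session feature CSV
#'
#' @param features data frame from [cohort_feature_table()].
#' @param path output file; missing values are written as empty cells.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}
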