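#' Classify the session risk level
#'
#' Applies a fitted classifier to a session's post-minus-pre difference
#' features and thresholds the deteriorated-class probability at
#' `threshold` (a probability exactly at the threshold is assigned high
#' risk).
#'
#' @param features a `feature_vector` from [session_feature_vector()] or a
#'   named numeric vector of difference features.
#' @param model an `ocufatigue_model` (typically from [train_risk_model()],
#'   which stores the z-score statistics used at deployment).
#' @param threshold risk threshold on the probability, default 0.5.
#' @return list with `risk_level` (`"low"`/`"high"`) and `probability`.
#' @export
classify_session_risk <- function(features, model, threshold = 0.5) {
  v <- if (inherits(features, "feature_vector")) features$diff else features
  missing <- setdiff(model$feature_names, names(v))
  if (length(missing))
    stop("feature schema mismatch; missing: ", paste(missing, collapse = ", "))
  x <- as.data.frame(as.list(v[model$feature_names]))
  if (!is.null(model$center))
    x[] <- as.list((unlist(x) - model$center) / model$scale)
  p <- predict_prob(model, x)
  list(risk_level = if (p >= threshold) "high" else "low",
       probability = unname(p))
}

#' Build a per-session risk report
#'
#' Summarises a session the way the deployed monitoring app would: the
#' predicted risk level (when a model is supplied), a summary block of key
#' metrics from the post-task recording (total time, blink count, mean
#' blink duration, fixation count, mean fixation duration, mean squared
#' deviation of fixation durations, PERCLOS) and per-eye time-series of
#' blink status, fissure length, pupil size and pupil trajectory. All
#' metrics come from the oculometrics functions; none are recomputed ad
#' hoc.
#'
#' @param session a `session_record`.
#' @param model optional fitted classifier; adds `risk_level`.
#' @param threshold risk threshold.
#' @param range analysed frame range for summary metrics.
#' @param seed provenance seed recorded in the report.
#' @return list of class `session_report`.
#' @export
build_session_report <- function(session, model = NULL, threshold = 0.5,
                                 range = c(200L, 1800L), seed = NULL) {
  post <- session$post
  prim <- trim_trace(post$left, range[1], range[2])
  fr <- frame_rate_of(post$left)
  blinks <- suppressWarnings(detect_blinks(prim))
  fix <- detect_fixations(prim)
  warnings <- character(0)
  fd_mse <- if (nrow(fix) >= 1) mean((fix$duration - mean(fix$duration))^2)
            else NA_real_
  summary <- list(
    total_time = nrow(post$left) / fr,
    blink_count = nrow(blinks),
    mean_blink_duration = if (nrow(blinks)) mean(blinks$duration) else NA_real_,
    fixation_count = nrow(fix),
    mean_fixation_duration = if (nrow(fix)) mean(fix$duration) else NA_real_,
    fixation_duration_mse = fd_mse,
    perclos = perclos(prim))
  if (any(vapply(summary, function(v) length(v) == 1 && is.na(v), logical(1))))
    warnings <- c(warnings, "some summary metrics undefined (no events)")
  risk <- NULL; prob <- NULL
  if (!is.null(model)) {
    fv <- session_feature_vector(session, range = range)
    r <- classify_session_risk(fv, model, threshold)
    risk <- r$risk_level; prob <- r$probability
  }
  series <- lapply(post[c("left", "right")], function(tr) {
    closed <- rep(FALSE, nrow(tr))
    if (nrow(blinks))
      for (i in seq_len(nrow(blinks)))
        closed[tr$frame >= blinks$start_frame[i] &
               tr$frame <= blinks$end_frame[i]] <- TRUE
    list(frame = tr$frame, blink_status = !tr$valid,
         fissure_length = tr$fissure_length,
         pupil_size = tr$pupil_diameter,
         pupil_x = tr$pupil_x, pupil_y = tr$pupil_y)
  })
  structure(list(participant_id = session$participant_id,
                 risk_level = risk, risk_probability = prob,
                 summary = summary,
                 blink_events = as.data.frame(blinks),
                 time_series = series,
                 provenance = list(
                   seed = seed,
                   model = if (!is.null(model)) model$family else NULL,
                   frame_rate = fr, analysed_range = as.integer(range),
                   fixation_mse_note = paste(
                     "fixation_duration_mse is the mean squared deviation",
                     "of fixation durations about their mean")),
                 warnings = warnings),
            class = "session_report")
}

#' Write / read a session report as JSON
#'
#' The report round-trips losslessly through the reader (numeric precision
#' preserved; `NA` encoded as `null`).
#'
#' @param report a `session_report`.
#' @param path JSON file path.
#' @return `write_session_report()` returns `path` invisibly;
#'   `read_session_report()` returns the report list.
#' @export
write_session_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_session_report
#' @export
read_session_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  class(obj) <- "session_report"
  obj
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %s\n", x$participant_id))
  if (!is.null(x$risk_level))
    cat(sprintf("  risk: %s (p = %.3f)\n", x$risk_level, x$risk_probability))
  s <- x$summary
  cat(sprintf("  total time %.1f s, %d blinks (mean %.1f ms), %d fixations (mean %.1f ms)\n",
              s$total_time, s$blink_count,
              ifelse(is.na(s$mean_blink_duration), NaN, s$mean_blink_duration),
              s$fixation_count,
              ifelse(is.na(s$mean_fixation_duration), NaN,
                     s$mean_fixation_duration)))
  cat(sprintf("  PERCLOS %.2f%%\n", s$perclos))
  invisible(x)
}
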