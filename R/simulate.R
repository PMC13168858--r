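#' Trace simulation parameters
#'
#' Parameters of the synthetic one-minute eye recording. Defaults emulate the
#' stated recording conventions (30 fps, 1800 frames = 1 minute) and
#' physiologically plausible reading behaviour: spontaneous blinks of about
#' 100-150 ms, reading fixations of ~250 ms separated by saccades, and a slow
#' pupillary oscillation (hippus) plus frame noise.
#'
#' @param frame_rate frames per second (> 0).
#' @param n_frames number of frames (>= 1). If `NULL`, derived from
#'   `duration_s` as `round(duration_s * frame_rate)`.
#' @param duration_s recording length in seconds, used only when `n_frames`
#'   is `NULL` (default 60 s).
#' @param blink_rate expected blink events per minute (>= 0).
#' @param blink_duration_mean,blink_duration_sd blink (full closure) duration
#'   in ms.
#' @param open_fissure_mean,open_fissure_sd eyelid aperture baseline and
#'   per-frame noise, pixels.
#' @param pupil_mean mean pupil diameter, pixels.
#' @param pupil_osc_amplitude,pupil_osc_period sinusoidal pupil oscillation,
#'   pixels and seconds.
#' @param pupil_noise_sd per-frame Gaussian pupil noise, pixels.
#' @param fixation_duration_mean mean fixation plateau duration, ms.
#' @param saccade_amplitude_mean mean saccade jump, pixels. Realised
#'   amplitudes are uniform in 0.9-1.5 times the mean so that every saccade
#'   exceeds the default fixation-dispersion threshold.
#' @param centroid_noise_sd per-frame centroid jitter, pixels.
#' @param rng_seed integer seed; identical seed + params give a bit-identical
#'   trace. `NULL` uses the current RNG stream.
#' @return a list of class `trace_params`.
#' @export
trace_params <- function(frame_rate = 30, n_frames = NULL, duration_s = 60,
                         blink_rate = 15,
                         blink_duration_mean = 120, blink_duration_sd = 30,
                         open_fissure_mean = 40, open_fissure_sd = 1.5,
                         pupil_mean = 30,
                         pupil_osc_amplitude = 0.5, pupil_osc_period = 5,
                         pupil_noise_sd = 0.5,
                         fixation_duration_mean = 250,
                         saccade_amplitude_mean = 20,
                         centroid_noise_sd = 0.3,
                         rng_seed = NULL) {
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive")
  if (is.null(n_frames)) n_frames <- round(duration_s * frame_rate)
  if (!is.numeric(n_frames) || n_frames < 1)
    stop("n_frames must be >= 1")
  nonneg <- c(blink_rate = blink_rate,
              blink_duration_mean = blink_duration_mean,
              blink_duration_sd = blink_duration_sd,
              open_fissure_mean = open_fissure_mean,
              open_fissure_sd = open_fissure_sd,
              pupil_mean = pupil_mean,
              pupil_osc_amplitude = pupil_osc_amplitude,
              pupil_osc_period = pupil_osc_period,
              pupil_noise_sd = pupil_noise_sd,
              fixation_duration_mean = fixation_duration_mean,
              saccade_amplitude_mean = saccade_amplitude_mean,
              centroid_noise_sd = centroid_noise_sd)
  if (any(nonneg < 0))
    stop("negative parameter: ", paste(names(nonneg)[nonneg < 0], collapse = ", "))
  structure(list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 blink_rate = blink_rate,
                 blink_duration_mean = blink_duration_mean,
                 blink_duration_sd = blink_duration_sd,
                 open_fissure_mean = open_fissure_mean,
                 open_fissure_sd = open_fissure_sd,
                 pupil_mean = pupil_mean,
                 pupil_osc_amplitude = pupil_osc_amplitude,
                 pupil_osc_period = pupil_osc_period,
                 pupil_noise_sd = pupil_noise_sd,
                 fixation_duration_mean = fixation_duration_mean,
                 saccade_amplitude_mean = saccade_amplitude_mean,
                 centroid_noise_sd = centroid_noise_sd,
                 rng_seed = rng_seed),
            class = "trace_params")
}

#' Group effect profile
#'
#' Describes how a post-task recording differs from the pre-task one for a
#' deterioration group. The shipped defaults reproduce the qualitative
#' contrast pattern between deteriorated and non-deteriorated asthenopia
#' groups: the deteriorated group shows a non-positive blink-duration change,
#' a *smaller* mid-window (frames 600-1200) variability change, and a larger
#' critical flicker fusion (CFF) drop, while CVS-Q scores rise by >= 3 points
#' on average only in the deteriorated group.
#'
#' @param group `"deteriorated"` or `"nondeteriorated"`.
#' @param delta_blink_rate change in blink events/minute applied post-task.
#' @param delta_blink_duration change in mean blink duration, ms.
#' @param delta_variability_scale_midwindow unitless multiplier applied to
#'   post-task pupil and fissure frame noise within frames 600-1200.
#' @param delta_cff change in CFF, Hz.
#' @param cvsq_change_mean,cvsq_change_sd Gaussian model of the CVS-Q score
#'   change (points); draws are rounded and clipped at zero.
#' @return list of class `effect_profile`.
#' @export
effect_profile <- function(group = c("deteriorated", "nondeteriorated"),
                           delta_blink_rate = NULL,
                           delta_blink_duration = NULL,
                           delta_variability_scale_midwindow = NULL,
                           delta_cff = NULL,
                           cvsq_change_mean = NULL, cvsq_change_sd = NULL) {
  group <- match.arg(group)
  def <- if (group == "deteriorated") {
    list(delta_blink_rate = 0, delta_blink_duration = -5,
         delta_variability_scale_midwindow = 0.85,
         delta_cff = -2.97, cvsq_change_mean = 4.5, cvsq_change_sd = 1.5)
  } else {
    list(delta_blink_rate = 4, delta_blink_duration = 12,
         delta_variability_scale_midwindow = 1.35,
         delta_cff = -2.14, cvsq_change_mean = 1.0, cvsq_change_sd = 1.0)
  }
  take <- function(x, d) if (is.null(x)) d else x
  structure(list(group = group,
                 delta_blink_rate = take(delta_blink_rate, def$delta_blink_rate),
                 delta_blink_duration = take(delta_blink_duration, def$delta_blink_duration),
                 delta_variability_scale_midwindow =
                   take(delta_variability_scale_midwindow,
                        def$delta_variability_scale_midwindow),
                 delta_cff = take(delta_cff, def$delta_cff),
                 cvsq_change_mean = take(cvsq_change_mean, def$cvsq_change_mean),
                 cvsq_change_sd = take(cvsq_change_sd, def$cvsq_change_sd)),
            class = "effect_profile")
}

# ---- event schedule ---------------------------------------------------------

# Draw the shared binocular event schedule (blink closures and fixation
# plateaus). Blinks are a renewal process with exponential gaps (minimum
# 0.5 s); each closure lasts max(2, round(duration_ms/1000*fps)) frames.
# Fixation plateaus tile the recording; saccade jumps are uniform
# 0.9-1.5 x mean amplitude with a random direction, reflected into a
# +/- 60 px box around the eye centre.
sim_events <- function(params) {
  fr <- params$frame_rate
  n <- params$n_frames
  min_closed <- 2L
  blinks <- data.frame(start = integer(0), end = integer(0))
  if (params$blink_rate > 0) {
    t <- 0
    starts <- integer(0); ends <- integer(0)
    mean_gap <- 60 / params$blink_rate
    repeat {
      gap <- max(0.5, stats::rexp(1, rate = 1 / mean_gap))
      onset <- floor((t + gap) * fr)
      dur_ms <- stats::rnorm(1, params$blink_duration_mean,
                             params$blink_duration_sd)
      nc <- max(min_closed, round(dur_ms / 1000 * fr))
      if (onset + nc + 2L >= n - 2L) break
      starts <- c(starts, onset); ends <- c(ends, onset + nc - 1L)
      t <- (onset + nc + 2L) / fr
    }
    blinks <- data.frame(start = starts, end = ends)
  }
  # fixation plateaus (0-based frame bounds, inclusive)
  min_fix_frames <- max(2L, ceiling(0.15 * fr))
  fs <- integer(0); fe <- integer(0); fx <- numeric(0); fy <- numeric(0)
  pos <- c(0, 0)
  cur <- 0L
  while (cur < n) {
    dur_ms <- stats::rgamma(1, shape = 6,
                            scale = params$fixation_duration_mean / 6)
    nf <- max(min_fix_frames, round(dur_ms / 1000 * fr))
    end <- min(n - 1L, cur + nf - 1L)
    if (n - 1L - end < min_fix_frames) end <- n - 1L  # absorb a short tail
    fs <- c(fs, cur); fe <- c(fe, end); fx <- c(fx, pos[1]); fy <- c(fy, pos[2])
    # reading-like saccade: dominant horizontal component equal to the full
    # amplitude (so each jump exceeds the fixation-dispersion threshold in
    # Chebyshev distance), small vertical drift, reflected at the gaze box
    amp <- params$saccade_amplitude_mean * stats::runif(1, 0.9, 1.5)
    dx <- amp * sample(c(-1, 1), 1)
    dy <- amp * stats::runif(1, -0.2, 0.2)
    if (abs(pos[1] + dx) > 60) dx <- -dx
    if (abs(pos[2] + dy) > 60) dy <- -dy
    pos <- pos + c(dx, dy)
    cur <- end + 1L
  }
  list(blinks = blinks,
       fixations = data.frame(start = fs, end = fe, x = fx, y = fy))
}

# Render one eye's trace from a fixed event schedule. `noise_scale` is a
# per-frame multiplier applied to pupil and fissure noise (used for the
# mid-window variability effect).
sim_trace_from_events <- function(params, events, eye = "left",
                                  noise_scale = NULL, centre = c(80, 60)) {
  fr <- params$frame_rate
  n <- params$n_frames
  if (is.null(noise_scale)) noise_scale <- rep(1, n)
  frames <- seq_len(n) - 1L

  fissure <- params$open_fissure_mean +
    stats::rnorm(n, 0, params$open_fissure_sd) * noise_scale
  closed <- rep(FALSE, n)
  if (nrow(events$blinks)) {
    for (i in seq_len(nrow(events$blinks))) {
      s <- events$blinks$start[i]; e <- events$blinks$end[i]
      closed[(s:e) + 1L] <- TRUE
      fissure[(s:e) + 1L] <- 0.05 * params$open_fissure_mean
      # trapezoidal 2-frame closing / reopening ramps (kept above the 20%
      # closure criterion so detected runs equal the injected closure)
      if (s - 2L >= 0L) {
        fissure[s - 1L] <- params$open_fissure_mean * 2 / 3
        fissure[s]      <- params$open_fissure_mean * 1 / 3
      }
      if (e + 2L <= n - 1L) {
        fissure[e + 2L] <- params$open_fissure_mean * 1 / 3
        fissure[e + 3L] <- params$open_fissure_mean * 2 / 3
      }
    }
  }
  fissure <- pmax(fissure, 0)

  tsec <- frames / fr
  osc <- if (params$pupil_osc_period > 0)
    params$pupil_osc_amplitude * sin(2 * pi * tsec / params$pupil_osc_period)
  else rep(0, n)
  pupil <- params$pupil_mean + osc +
    stats::rnorm(n, 0, params$pupil_noise_sd) * noise_scale

  px <- py <- numeric(n)
  for (i in seq_len(nrow(events$fixations))) {
    idx <- (events$fixations$start[i]:events$fixations$end[i]) + 1L
    px[idx] <- centre[1] + events$fixations$x[i]
    py[idx] <- centre[2] + events$fixations$y[i]
  }
  if (params$centroid_noise_sd > 0) {
    px <- px + stats::rnorm(n, 0, params$centroid_noise_sd)
    py <- py + stats::rnorm(n, 0, params$centroid_noise_sd)
  }
  pupil[closed] <- NA_real_
  px[closed] <- NA_real_; py[closed] <- NA_real_

  tr <- ocular_trace(frames, fissure, pupil, px, py, valid = !closed,
                     eye = eye, frame_rate = fr)
  attr(tr, "events") <- events
  tr
}

#' Simulate a single-eye ocular trace
#'
#' Generates a synthetic per-frame trace with blinks (trapezoidal aperture
#' drops to 5% of baseline, 2-frame close/open ramps), fixation plateaus
#' separated by saccadic jumps, and a pupil signal of the form
#' mean + sinusoid + Gaussian noise (undefined during blinks). The injected
#' ground-truth event schedule is attached as `attr(trace, "events")` so
#' that detector recovery can be checked against it.
#'
#' @param params a [trace_params()] object.
#' @param eye which eye label to attach.
#' @return an [ocular_trace()] with an `events` attribute
#'   (`$blinks`, `$fixations`: 0-based inclusive frame bounds).
#' @examples
#' tr <- simulate_trace(trace_params(rng_seed = 1))
#' nrow(tr)  # 1800 frames = 60 s at 30 fps
#' @export
simulate_trace <- function(params = trace_params(), eye = "left") {
  stopifnot(inherits(params, "trace_params"))
  with_seed(params$rng_seed, {
    ev <- sim_events(params)
    sim_trace_from_events(params, ev, eye = eye)
  })
}

# noise-scale vector implementing the mid-window variability effect
midwindow_scale <- function(n, scale, start = 600L, end = 1200L) {
  s <- rep(1, n)
  idx <- seq_len(n) - 1L
  s[idx >= start & idx < end] <- scale
  s
}

#' Simulate a participant session
#'
#' A session is one participant's pre-task and post-task one-minute binocular
#' recording plus questionnaire (CVS-Q) and critical flicker fusion (CFF)
#' values. The post-task recording is generated from `params` shifted by the
#' group [effect_profile()]: blink rate and duration deltas, a variability
#' multiplier on frames 600-1200, and a CFF shift. The CVS-Q change is a
#' rounded Gaussian clipped at zero. Left and right eyes share one event
#' schedule and differ only by independent frame noise.
#'
#' @param params a [trace_params()] (its `rng_seed` drives the whole session).
#' @param effect an [effect_profile()].
#' @param participant_id opaque identifier.
#' @param cvsq_pre,cff_pre optional fixed baselines; when `NULL` they are
#'   drawn from Normal(6.76, 3.76) rounded and clipped at 0 (CVS-Q points)
#'   and Normal(38, 2) Hz (CFF).
#' @return a list of class `session_record` with elements `participant_id`,
#'   `pre` and `post` (each a list with `left`/`right` traces), `cvsq_pre`,
#'   `cvsq_post`, `cff_pre`, `cff_post`, `truth_group`.
#' @export
simulate_session <- function(params = trace_params(),
                             effect = effect_profile("nondeteriorated"),
                             participant_id = "P01",
                             cvsq_pre = NULL, cff_pre = NULL) {
  stopifnot(inherits(params, "trace_params"), inherits(effect, "effect_profile"))
  with_seed(params$rng_seed, {
    if (is.null(cvsq_pre))
      cvsq_pre <- max(0, round(stats::rnorm(1, 6.76, 3.76)))
    if (is.null(cff_pre)) cff_pre <- stats::rnorm(1, 38, 2)

    post_params <- params
    post_params$blink_rate <- max(0, params$blink_rate + effect$delta_blink_rate)
    post_params$blink_duration_mean <-
      max(2000 / params$frame_rate,
          params$blink_duration_mean + effect$delta_blink_duration)
    post_params$rng_seed <- NULL

    pre_ev <- sim_events(params)
    post_ev <- sim_events(post_params)
    scale <- midwindow_scale(params$n_frames,
                             effect$delta_variability_scale_midwindow)
    pre <- list(left = sim_trace_from_events(params, pre_ev, "left"),
                right = sim_trace_from_events(params, pre_ev, "right"))
    post <- list(left = sim_trace_from_events(post_params, post_ev, "left",
                                              noise_scale = scale),
                 right = sim_trace_from_events(post_params, post_ev, "right",
                                               noise_scale = scale))
    change <- max(0, round(stats::rnorm(1, effect$cvsq_change_mean,
                                        effect$cvsq_change_sd)))
    cff_post <- cff_pre + effect$delta_cff + stats::rnorm(1, 0, 0.4)
    structure(list(participant_id = participant_id,
                   pre = pre, post = post,
                   cvsq_pre = cvsq_pre, cvsq_post = cvsq_pre + change,
                   cff_pre = cff_pre, cff_post = cff_post,
                   truth_group = effect$group),
              class = "session_record")
  })
}

#' Simulate a cohort of sessions
#'
#' Generates `round(n * prevalence)` deteriorated-profile sessions and the
#' remainder non-deteriorated, deterministically under `seed`.
#'
#' @param n number of sessions (> 0).
#' @param prevalence fraction of deteriorated-profile sessions in `[0, 1]`.
#' @param params base [trace_params()] shared by all sessions.
#' @param effects named list with `deteriorated` and `nondeteriorated`
#'   [effect_profile()]s.
#' @param seed integer master seed; each session receives a derived child
#'   seed.
#' @return list of `session_record`s.
#' @examples
#' coh <- simulate_cohort(4, 0.5, trace_params(duration_s = 10), seed = 7)
#' table(vapply(coh, `[[`, "", "truth_group"))
#' @export
simulate_cohort <- function(n, prevalence = 0.5, params = trace_params(),
                            effects = list(
                              deteriorated = effect_profile("deteriorated"),
                              nondeteriorated = effect_profile("nondeteriorated")),
                            seed = NULL) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive")
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  n <- as.integer(n)
  n_det <- as.integer(round(n * prevalence))
  groups <- c(rep("deteriorated", n_det), rep("nondeteriorated", n - n_det))
  lapply(seq_len(n), function(i) {
    p <- params
    p$rng_seed <- child_seed(if (is.null(seed)) NULL else seed, i)
    simulate_session(p, effects[[groups[i]]],
                     participant_id = sprintf("P%03d", i))
  })
}

#' Write cohort metadata CSV
#'
#' One row per session: `participant_id, cvsq_pre, cvsq_post, cff_pre,
#' cff_post, truth_group`.
#'
#' @param cohort list of `session_record`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(participant_id = s$participant_id,
               cvsq_pre = s$cvsq_pre, cvsq_post = s$cvsq_post,
               cff_pre = s$cff_pre, cff_post = s$cff_post,
               truth_group = s$truth_group)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
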