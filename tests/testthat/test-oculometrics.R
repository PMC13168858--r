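test_that("blink detection matches injected closures", {
  # constant fully open: no blinks
  expect_equal(nrow(detect_blinks(mk_trace(300))), 0)
  # one 5-frame closure at 30 fps: duration 5 * 1000/30
  tr <- close_frames(mk_trace(300), 100, 104)
  ev <- detect_blinks(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 100)
  expect_equal(ev$end_frame, 104)
  expect_equal(ev$duration, 5 * 1000 / 30)
  # single-frame dips rejected
  tr1 <- close_frames(mk_trace(300), 50, 50)
  expect_equal(nrow(detect_blinks(tr1)), 0)
  # never-open trace warns and returns empty
  expect_warning(ev0 <- detect_blinks(mk_trace(100, fissure = 0)), "open")
  expect_equal(nrow(ev0), 0)
  # simulator event log recovered exactly at zero noise
  p <- trace_params(open_fissure_sd = 0, pupil_noise_sd = 0,
                    centroid_noise_sd = 0, rng_seed = 8)
  tr2 <- simulate_trace(p)
  expect_equal(nrow(detect_blinks(tr2)), nrow(attr(tr2, "events")$blinks))
})

test_that("blink metrics follow their definitions", {
  none <- blink_metrics(detect_blinks(mk_trace(100)), 60)
  expect_equal(none[["blink_times_per_min"]], 0)
  expect_true(is.na(none[["avg_blink_duration"]]))
  expect_true(is.na(none[["avg_blink_interval"]]))
  ev <- data.frame(start_frame = c(100, 260), end_frame = c(200, 300),
                   duration = c(101, 41) * 1000 / 30)
  m <- blink_metrics(ev, analyzed_duration = 60, frame_rate = 30)
  expect_equal(m[["blink_times_per_min"]], 2)
  expect_equal(m[["avg_blink_interval"]], (260 - 200) * 1000 / 30)  # 2000 ms
  ev20 <- data.frame(start_frame = seq(0, by = 60, length.out = 20),
                     end_frame = seq(4, by = 60, length.out = 20),
                     duration = 5000 / 30)
  expect_equal(blink_metrics(ev20, 60)[["blink_times_per_min"]], 20)
})

test_that("PERCLOS counts closed frames against the open baseline", {
  expect_equal(perclos(mk_trace(200)), 0)
  expect_equal(perclos(mk_trace(200, fissure = 0)), 100)
  tr <- mk_trace(1600)
  tr <- close_frames(tr, 100, 399)  # 300 closed of 1600
  expect_equal(perclos(tr), 100 * 300 / 1600)  # 18.75
})

test_that("PERCLOS >= blink-frame fraction, equal for clean >=2-frame runs", {
  tr <- close_frames(close_frames(mk_trace(1000), 100, 104), 500, 520)
  ev <- detect_blinks(tr)
  blink_frames <- sum(ev$end_frame - ev$start_frame + 1)
  expect_equal(perclos(tr), 100 * blink_frames / 1000)
  # adding a single-frame dip raises PERCLOS but not blink frames
  tr2 <- close_frames(tr, 700, 700)
  ev2 <- detect_blinks(tr2)
  expect_gt(perclos(tr2),
            100 * sum(ev2$end_frame - ev2$start_frame + 1) / 1000)
})

test_that("I-DT fixation detection obeys dispersion and duration rules", {
  # constant centroid, 60 s, all valid: one fixation
  fx <- detect_fixations(mk_trace(1800))
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration, 60000)
  # alternating +/-100 px: none
  tr <- mk_trace(300, x = rep(c(0, 200), 150))
  expect_equal(nrow(detect_fixations(tr)), 0)
  # generator plateaus recovered exactly at zero noise
  p <- trace_params(blink_rate = 0, open_fissure_sd = 0, pupil_noise_sd = 0,
                    centroid_noise_sd = 0, rng_seed = 31)
  tr2 <- simulate_trace(p)
  expect_equal(nrow(detect_fixations(tr2)),
               nrow(attr(tr2, "events")$fixations))
  # an invalid frame splits an otherwise single fixation
  tr3 <- close_frames(mk_trace(600), 300, 304)
  expect_equal(nrow(detect_fixations(tr3)), 2)
})

test_that("movement distance sums valid consecutive pairs only", {
  tr <- mk_trace(2, x = c(0, 3), y = c(0, 4))
  expect_equal(movement_distance(tr), 5)  # 3-4-5 triangle
  expect_equal(movement_distance(mk_trace(50)), 0)
  # gap pair excluded: (0,0),(1,0),invalid,(5,0) -> only the first step
  tr2 <- mk_trace(4, x = c(0, 1, 3, 5), y = 0)
  tr2$valid[3] <- FALSE; tr2$pupil_diameter[3] <- NA
  expect_equal(movement_distance(tr2), 1)
  expect_warning(movement_distance(mk_trace(3, valid = FALSE, pupil = NA)),
                 "valid")
})

test_that("constriction speeds use negative diameter steps only", {
  expect_equal(constriction_speeds(mk_trace(100)),
               c(max_speed = 0, avg_speed = 0))
  tr <- mk_trace(3, pupil = c(30, 29, 29))
  expect_equal(constriction_speeds(tr)[["max_speed"]], 30)  # 1 px * 30 fps
  dilating <- mk_trace(50, pupil = seq(20, 30, length.out = 50))
  expect_equal(constriction_speeds(dilating),
               c(max_speed = 0, avg_speed = 0))
  mixed <- mk_trace(4, pupil = c(30, 28, 28, 29))
  expect_equal(constriction_speeds(mixed),
               c(max_speed = 60, avg_speed = 60))
})

test_that("windowed variability matches hand computation and identities", {
  tr <- mk_trace(3, pupil = c(2, 4, 6), start = 200L)
  v <- windowed_variability(tr, c(start = 200, end = 203), "pupil_size")
  expect_equal(v, c(sd = 2, variance = 4, cv = 50))
  expect_equal(windowed_variability(mk_trace(100, start = 200L), "early",
                                    "fissure_length"),
               c(sd = 0, variance = 0, cv = 0))
  # invalid frames excluded for pupil, included for fissure
  tr2 <- mk_trace(10, pupil = c(5, 5, NA, 9, 9, 5, 5, 9, 9, 5),
                  fissure = 1:10, start = 200L,
                  valid = c(TRUE, TRUE, FALSE, rep(TRUE, 7)))
  vp <- windowed_variability(tr2, c(start = 200, end = 210), "pupil_size")
  expect_equal(vp[["sd"]], sd(c(5, 5, 9, 9, 5, 5, 9, 9, 5)))
  vf <- windowed_variability(tr2, c(start = 200, end = 210), "fissure_length")
  expect_equal(vf[["sd"]], sd(1:10))
  # fewer than 2 valid samples -> sentinel
  expect_true(all(is.na(windowed_variability(
    mk_trace(5, pupil = NA, valid = FALSE, start = 200L),
    c(start = 200, end = 205), "pupil_size"))))
})

test_that("variability obeys scaling laws on random windows", {
  set.seed(9)
  for (i in 1:20) {
    x <- abs(rnorm(50, 30, 3))
    s <- runif(1, 0.5, 4)
    tr <- mk_trace(50, pupil = x, start = 200L)
    trs <- mk_trace(50, pupil = s * x, start = 200L)
    w <- c(start = 200, end = 250)
    v1 <- windowed_variability(tr, w, "pupil_size")
    v2 <- windowed_variability(trs, w, "pupil_size")
    expect_equal(v2[["cv"]], v1[["cv"]], tolerance = 1e-10)
    expect_equal(v2[["sd"]], s * v1[["sd"]], tolerance = 1e-10)
    expect_equal(v2[["variance"]], s^2 * v1[["variance"]], tolerance = 1e-10)
    expect_equal(v1[["variance"]], v1[["sd"]]^2, tolerance = 1e-12)
  }
})

test_that("session feature vectors difference post minus pre", {
  s <- simulate_session(trace_params(rng_seed = 14),
                        effect_profile("deteriorated"))
  # post identical to pre: all differences zero
  same <- session_feature_vector(pre = s$pre, post = s$pre,
                                 cff_pre = 40, cff_post = 40)
  expect_true(all(same$diff[!is.na(same$diff)] == 0))
  # printed CFF example
  fv <- session_feature_vector(pre = s$pre, post = s$post,
                               cff_pre = 40, cff_post = 37.03)
  expect_equal(fv$diff[["cff"]], -2.97)
  expect_equal(fv$diff, fv$post - fv$pre)
  # antisymmetry: swapping pre and post negates every difference
  rev <- session_feature_vector(pre = s$post, post = s$pre,
                                cff_pre = 37.03, cff_post = 40)
  expect_equal(rev$diff, -fv$diff)
})

test_that("metrics ignore the discarded initial frames", {
  s <- simulate_session(trace_params(rng_seed = 15),
                        effect_profile("nondeteriorated"))
  fv1 <- session_feature_vector(s)
  mangled <- s
  for (phase in c("pre", "post")) for (e in c("left", "right")) {
    idx <- mangled[[phase]][[e]]$frame < 200
    mangled[[phase]][[e]]$fissure_length[idx] <- 999
    mangled[[phase]][[e]]$pupil_diameter[idx] <- 1
    mangled[[phase]][[e]]$pupil_x[idx] <- -500
  }
  fv2 <- session_feature_vector(mangled)
  expect_equal(fv2$diff, fv1$diff)
  expect_equal(fv2$pre, fv1$pre)
})

test_that("injected blink-rate shifts are recovered in the features", {
  deltas <- vapply(1:20, function(i) {
    p <- trace_params(rng_seed = 800 + i)
    s <- simulate_session(p, effect_profile("nondeteriorated"))
    session_feature_vector(s)$diff[["blink_times_per_min"]]
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 4), 1.5)
})

test_that("feature tables carry labels and units", {
  coh <- simulate_cohort(3, 1 / 3, trace_params(), seed = 6)
  ft <- cohort_feature_table(coh, unit = "eye")
  expect_equal(nrow(ft), 6)
  expect_true(all(c("participant_id", "eye", "label", "cff",
                    "pupil_size_cv_mid", "fissure_length_variance_all")
                  %in% names(ft)))
  ftp <- cohort_feature_table(coh, unit = "participant")
  expect_equal(nrow(ftp), 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ft, f)
  expect_equal(nrow(utils::read.csv(f)), 6)
})
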