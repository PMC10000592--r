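fs <- 4

test_that("baseline estimation is a fixed point on a constant trace", {
  fhr <- rep(140, 30 * 60 * fs)
  bl <- estimate_baseline(fhr, sample_rate = fs)
  expect_true(all(bl$value == 140))
  expect_true(all(bl$iterations == 1))
})

test_that("baseline iteration excludes a superimposed event", {
  fhr <- rep(140, 30 * 60 * fs)
  fhr <- add_bump(fhr, center = 1200, duration_s = 60, depth = 20, fs = fs)
  bl <- estimate_baseline(fhr, sample_rate = fs)
  # oracle: median of the event-free samples is exactly 140
  expect_true(all(abs(bl$value - 140) <= 1))
})

test_that("baseline recovery on a drifting synthetic cohort stays within 5 bpm", {
  co <- shared_cohort(100, seed = 20)
  errs <- vapply(co, function(el) {
    rec <- el$record
    bl <- estimate_baseline(rec$fhr, rec$mask, rec$sample_rate)
    ok <- !is.na(bl$value)
    mean(abs(bl$value[ok] - vapply(which(ok), function(i)
      mean(el$truth$true_baseline[bl$start[i]:bl$end[i]]), numeric(1))))
  }, numeric(1))
  expect_lte(mean(errs, na.rm = TRUE), 5)
})

test_that("baseline classification uses the guideline cut-offs", {
  expect_equal(classify_baseline(140), "Normal")
  expect_equal(classify_baseline(100), "Bradycardia")
  expect_equal(classify_baseline(161), "Tachycardia")
  expect_equal(classify_baseline(c(110, 160)), c("Normal", "Normal"))
  expect_equal(classify_baseline(NA), "Undetermined")
})

test_that("variability is undetermined on a constant trace", {
  fhr <- rep(140, 30 * 60 * fs)
  bl <- estimate_baseline(fhr, sample_rate = fs)
  v <- compute_variability(fhr, bl, sample_rate = fs)
  expect_true(is.na(v$value))
  expect_equal(v$type, "Absent")
})

test_that("a pure sinusoid recovers the closed-form a/sqrt(2) deviation", {
  a <- 8
  t_s <- (seq_len(30 * 60 * fs) - 1) / fs
  fhr <- 140 + a * sin(2 * pi * (3 / 60) * t_s)   # 3 cycles/min
  v <- compute_variability(fhr, rep(140, length(fhr)), sample_rate = fs)
  expect_equal(v$value, a / sqrt(2), tolerance = 0.02)
})

test_that("variability recovery on the default generator is within 1.5 bpm", {
  errs <- vapply(1:15, function(s) {
    g <- generate_record(synth_config(variability_sd_bpm = 6, seed = 100 + s))
    rec <- g$record
    bl <- estimate_baseline(rec$fhr, rec$mask, fs)
    v <- compute_variability(rec$fhr, bl, rec$mask, fs)
    abs(v$value - 6)
  }, numeric(1))
  expect_lte(mean(errs), 1.5)
})

test_that("variability classes use the NICHD-style bands", {
  expect_equal(classify_variability(0), "Absent")
  expect_equal(classify_variability(3), "Minimal")
  expect_equal(classify_variability(10), "Moderate")
  expect_equal(classify_variability(26), "Marked")
  expect_error(classify_variability(-1), "negative")
})

test_that("acceleration detection enforces the 15 s / 15 bpm definition", {
  base <- rep(140, 30 * 60 * fs)
  bl <- rep(140, length(base))
  acc <- detect_accelerations(add_bump(base, 2000, 60, 20, fs), bl,
                              sample_rate = fs)
  expect_equal(nrow(acc), 1)
  expect_equal(acc$kind, "acceleration")

  too_short <- detect_accelerations(add_bump(base, 2000, 10, 20, fs), bl,
                                    sample_rate = fs)
  expect_equal(nrow(too_short), 0)

  too_small <- detect_accelerations(add_bump(base, 2000, 60, 12, fs), bl,
                                    sample_rate = fs)
  expect_equal(nrow(too_small), 0)

  # an excursion beyond 10 min is a baseline change, not an acceleration
  long <- add_bump(base, 3600, 700, 25, fs)
  lacc <- detect_accelerations(long, bl, sample_rate = fs)
  expect_true(all(lacc$baseline_change))
})

test_that("fuzzy memberships follow the trapezoids", {
  expect_equal(decel_membership(60, 20), 1)
  expect_equal(decel_membership(60, 12), 0.4)   # (12 - 10) / 5
  expect_equal(decel_membership(60, 5), 0)
  expect_equal(decel_membership(12, 20), 0.4)   # (12 - 10) / 5
  expect_equal(decel_membership(700, 20), 0)    # baseline change
  # monotone in depth, and in duration below the 10-min cap
  depths <- seq(5, 30, by = 0.5)
  expect_true(all(diff(mu_depth(depths)) >= 0))
  durs <- seq(5, 600, by = 2.5)
  expect_true(all(diff(mu_duration(durs)) >= 0))
  grid <- expand.grid(dur = c(11, 13, 20, 300), depth = c(11, 13, 20))
  m <- decel_membership(grid$dur, grid$depth)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("borderline decelerations are emitted only above the membership threshold", {
  base <- rep(140, 30 * 60 * fs)
  bl <- rep(140, length(base))
  dec <- detect_decelerations_fuzzy(add_bump(base, 2000, 60, -20, fs), bl,
                                    sample_rate = fs)
  expect_equal(nrow(dec), 1)
  expect_equal(dec$membership, 1)

  # depth 12 bpm grades 0.4 < 0.5 and is not emitted ...
  weak <- detect_decelerations_fuzzy(add_bump(base, 2000, 60, -12, fs), bl,
                                     sample_rate = fs)
  expect_equal(nrow(weak), 0)
  # ... but is at a laxer threshold
  weak2 <- detect_decelerations_fuzzy(add_bump(base, 2000, 60, -12, fs), bl,
                                      sample_rate = fs, theta = 0.3)
  expect_equal(nrow(weak2), 1)
  expect_equal(weak2$membership, 0.4, tolerance = 0.05)

  shallow <- detect_decelerations_fuzzy(add_bump(base, 2000, 60, -5, fs), bl,
                                        sample_rate = fs, theta = 0)
  expect_equal(nrow(shallow), 0)   # membership 0 even at theta = 0
})

test_that("fuzzy detector equals a crisp NICHD detector on unambiguous events", {
  # 200 events across several flat-baseline traces: parameters drawn clear
  # of the fuzzy transition band (depth < 10 or >= 15; duration < 10 or >= 15)
  set.seed(99)
  n_traces <- 20
  total_checked <- 0
  for (tr in seq_len(n_traces)) {
    fhr <- rep(140, 30 * 60 * fs)
    centers <- seq(400, length(fhr) - 400, length.out = 10)
    for (c0 in centers) {
      depth <- sample(c(runif(1, 16, 40), runif(1, 3, 9)), 1)
      dur <- sample(c(runif(1, 16, 90), runif(1, 4, 9)), 1)
      fhr <- add_bump(fhr, round(c0), dur, -depth, fs)
    }
    bl <- rep(140, length(fhr))
    fz <- detect_decelerations_fuzzy(fhr, bl, sample_rate = fs)
    cr <- crisp_decel_detector(fhr, bl, fs)
    expect_equal(nrow(fz), nrow(cr))
    if (nrow(fz) && nrow(cr)) {
      expect_equal(fz$start, cr$start)
      expect_equal(fz$end, cr$end)
    }
    total_checked <- total_checked + 10
  }
  expect_gte(total_checked, 200)
})

test_that("contraction detection counts a clean and a jittered train", {
  flat <- detect_contractions(rep(10, 7200), fs)
  expect_equal(nrow(flat), 0)

  g <- generate_record(synth_config(duration_min = 35,
                                    contraction_period_s = 180,
                                    variability_sd_bpm = 0,
                                    n_accelerations = 0, seed = 6))
  tru <- g$truth$events[g$truth$events$kind == "contraction", ]
  det <- detect_contractions(g$record$ucp, fs)
  expect_equal(nrow(det), nrow(tru))

  gj <- generate_record(synth_config(duration_min = 35,
                                     contraction_period_s = 150,
                                     contraction_jitter_s = 10,
                                     variability_sd_bpm = 2,
                                     n_accelerations = 0, seed = 16))
  truj <- gj$truth$events[gj$truth$events$kind == "contraction", ]
  detj <- detect_contractions(gj$record$ucp, fs)
  m <- match_events(detj, truj, fs, tol_s = 30)
  expect_gte(m$recall, 0.9)
})

test_that("deceleration typing follows shape and contraction timing", {
  ctr <- data.frame(kind = "contraction", type = "untyped",
                    start = 800L, extremum = 1000L, end = 1200L,
                    amplitude = 40, duration_s = 100, membership = NA,
                    baseline_change = FALSE)
  mk_dec <- function(start, nadir, end)
    data.frame(kind = "deceleration", type = "untyped", start = start,
               extremum = nadir, end = end, amplitude = -30,
               duration_s = (end - start + 1) / fs, membership = 1,
               baseline_change = FALSE)
  # gradual, nadir lagging the peak by 40 s -> late
  late <- classify_decelerations(mk_dec(1000L, 1160L, 1320L), ctr, fs)
  expect_equal(late$type, "late")
  # gradual, nadir on the peak -> early
  early <- classify_decelerations(mk_dec(840L, 1000L, 1160L), ctr, fs)
  expect_equal(early$type, "early")
  # abrupt onset -> variable regardless of timing
  abrupt <- classify_decelerations(mk_dec(960L, 1000L, 1240L), ctr, fs)
  expect_equal(abrupt$type, "variable")
  # gradual but uncoupled (> 120 s from any peak) -> variable
  far <- classify_decelerations(mk_dec(1840L, 2000L, 2160L), ctr, fs)
  expect_equal(far$type, "variable")
  # no contractions at all -> variable with a warning
  expect_warning(
    nc <- classify_decelerations(mk_dec(840L, 1000L, 1160L),
                                 ctr[0, ], fs),
    "no contractions")
  expect_equal(nc$type, "variable")
})

test_that("typing and detection clear 0.9 against cohort ground truth", {
  co <- shared_cohort(100, seed = 20)
  dec <- cohort_detection_score(co, "deceleration")
  acc <- cohort_detection_score(co, "acceleration")
  expect_gte(acc$f1, 0.9)
  expect_gte(dec$f1, 0.9)
  expect_gte(dec$typing_accuracy, 0.9)
})

test_that("sinusoidal screening needs 20 valid minutes and the 2-5 cpm band", {
  t_s <- (seq_len(30 * 60 * fs) - 1) / fs
  sine <- 140 + 10 * sin(2 * pi * (4 / 60) * t_s)
  bl <- rep(140, length(sine))
  expect_equal(detect_shr(sine, bl, sample_rate = fs), "Present")
  expect_equal(detect_shr(rep(140, length(sine)), bl, sample_rate = fs),
               "Absent")
  short <- 140 + 10 * sin(2 * pi * (4 / 60) * t_s[seq_len(10 * 60 * fs)])
  expect_equal(detect_shr(short, bl[seq_len(10 * 60 * fs)],
                          sample_rate = fs), "Undetermined")
})

test_that("the feature vector assembles the 11 fields deterministically", {
  rec <- make_flat_record(bpm = 140, minutes = 30)
  f <- extract_features(rec)
  expect_equal(names(f),
               c("baseline", "baseline_type", "variability",
                 "variability_type", "acceleration_present",
                 "n_accelerations", "n_early", "n_late", "n_variable",
                 "shr", "stage"))
  expect_equal(f$baseline, 140)
  expect_equal(f$baseline_type, "Normal")
  expect_equal(f$variability, 0)
  expect_equal(f$variability_type, "Absent")
  expect_false(f$acceleration_present)
  expect_equal(f$n_accelerations + f$n_early + f$n_late + f$n_variable, 0)
  expect_equal(f$shr, "Absent")
  expect_equal(f$stage, "stage1")

  g <- generate_record(synth_config(
    variability_sd_bpm = 1, n_accelerations = 0,
    decel_spec = list(list(type = "late", depth_bpm = 40, duration_s = 90),
                      list(type = "late", depth_bpm = 40, duration_s = 90),
                      list(type = "variable", depth_bpm = 35,
                           duration_s = 45)),
    seed = 18))
  f2 <- extract_features(g$record)
  expect_equal(f2$n_late, 2)
  expect_equal(f2$n_variable, 1)
})

test_that("emitted decelerations all carry a type (counting conservation)", {
  ft <- shared_features(100, seed = 20)
  expect_equal(nrow(ft), 100)
  expect_false(anyNA(ft[, setdiff(names(ft), "label")]))
  for (el in shared_cohort(100, seed = 20)[1:10]) {
    f <- extract_features(el$record)
    dec <- attr(f, "events")$decelerations
    expect_equal(f$n_early + f$n_late + f$n_variable, nrow(dec))
    expect_true(all(dec$type %in% c("early", "late", "variable")))
  }
})

test_that("baseline estimate is stable once detected events are excised", {
  g <- generate_record(synth_config(variability_sd_bpm = 2, seed = 24,
                                    n_accelerations = 3,
                                    decel_spec = list(
                                      list(type = "late", depth_bpm = 40,
                                           duration_s = 90))))
  rec <- g$record
  bl1 <- estimate_baseline(rec$fhr, rec$mask, fs)
  f <- extract_features(rec)
  ev <- attr(f, "events")
  excise <- rec$mask
  for (e in list(ev$accelerations, ev$decelerations))
    for (i in seq_len(nrow(e))) excise[e$start[i]:e$end[i]] <- FALSE
  bl2 <- estimate_baseline(rec$fhr, excise, fs)
  ok <- !is.na(bl1$value) & !is.na(bl2$value)
  expect_true(all(abs(bl1$value[ok] - bl2$value[ok]) < 1))
})
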