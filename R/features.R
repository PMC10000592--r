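#' Iterative FHR baseline estimation
#'
#' Estimates the fetal heart rate baseline in sliding 10-minute windows with
#' 3 minutes of overlap (7-minute step). Each window starts from an initial
#' virtual baseline (the mode of the valid samples binned to 1 bpm) and
#' iterates: samples deviating from the current estimate by more than
#' `envelope_bpm` -- i.e. samples inside accelerations/decelerations -- are
#' excluded and the estimate is recomputed as the median of the remainder,
#' until the change falls below `tol_bpm` or `max_iter` is reached. The
#' window's value is accepted only if the samples within `envelope_bpm` of
#' the final estimate total more than `min_identifiable_s` seconds (not
#' necessarily contiguous); otherwise the window is marked unidentifiable
#' (`NA`), as is any window with too little valid signal. An all-masked
#' window is unidentifiable, not an error.
#'
#' @param fhr Numeric FHR series, bpm.
#' @param mask Logical validity mask (`TRUE` = valid); default all valid.
#' @param sample_rate Hz.
#' @param window_min,overlap_min Window length and overlap, minutes.
#' @param envelope_bpm Event-exclusion envelope around the current estimate
#'   (bpm).
#' @param tol_bpm Convergence tolerance (bpm).
#' @param max_iter Iteration cap.
#' @param min_identifiable_s Seconds of near-baseline signal required to
#'   accept a window's value.
#' @return A data frame of class `ctg_baseline` with one row per window:
#'   `start`, `end` (1-based sample bounds, end inclusive), `value` (bpm or
#'   `NA`), `iterations`, `identifiable_s`. The `sample_rate` and series
#'   length are attached as attributes.
#' @export
estimate_baseline <- function(fhr, mask = NULL, sample_rate = 4,
                              window_min = 10, overlap_min = 3,
                              envelope_bpm = 10, tol_bpm = 0.5,
                              max_iter = 20, min_identifiable_s = 120) {
  n <- length(fhr)
  if (is.null(mask)) mask <- rep(TRUE, n)
  win <- as.integer(window_min * 60 * sample_rate)
  step <- as.integer((window_min - overlap_min) * 60 * sample_rate)
  if (n < win) stop("record shorter than one ", window_min,
                    "-minute baseline window", call. = FALSE)
  starts <- seq(1L, max(1L, n - win + 1L), by = step)
  # cover the tail: ensure the last window reaches the end of the series
  if (starts[length(starts)] + win - 1L < n) starts <- c(starts, n - win + 1L)

  rows <- lapply(starts, function(s) {
    e <- min(n, s + win - 1L)
    x <- fhr[s:e][mask[s:e]]
    if (length(x) < min_identifiable_s * sample_rate)
      return(data.frame(start = s, end = e, value = NA_real_,
                        iterations = 0L, identifiable_s = 0))
    est <- binned_mode(x)
    it <- 0L
    repeat {
      it <- it + 1L
      keep <- x[abs(x - est) <= envelope_bpm]
      new <- if (length(keep)) stats::median(keep) else est
      done <- abs(new - est) < tol_bpm || it >= max_iter
      est <- new
      if (done) break
    }
    id_s <- sum(abs(x - est) <= envelope_bpm) / sample_rate
    data.frame(start = s, end = e,
               value = if (id_s > min_identifiable_s) est else NA_real_,
               iterations = it, identifiable_s = id_s)
  })
  out <- do.call(rbind, rows)
  attr(out, "sample_rate") <- sample_rate
  attr(out, "n_samples") <- n
  class(out) <- c("ctg_baseline", "data.frame")
  out
}

# mode of a histogram with 1-bpm bins
binned_mode <- function(x) {
  tb <- table(round(x))
  as.numeric(names(tb)[which.max(tb)])
}

#' Per-sample baseline series from window estimates
#'
#' Expands the windowed baseline values to a per-sample series: each sample
#' takes the mean of the identifiable windows covering it; samples covered
#' by no identifiable window are filled by interpolation/extension from the
#' nearest identifiable ones. All-unidentifiable input yields an all-`NA`
#' series.
#'
#' @param baseline A `ctg_baseline` from [estimate_baseline()].
#' @return Numeric vector, length of the original series.
#' @export
baseline_series <- function(baseline) {
  n <- attr(baseline, "n_samples")
  acc <- numeric(n)
  cnt <- numeric(n)
  for (i in seq_len(nrow(baseline))) {
    if (is.na(baseline$value[i])) next
    idx <- baseline$start[i]:baseline$end[i]
    acc[idx] <- acc[idx] + baseline$value[i]
    cnt[idx] <- cnt[idx] + 1
  }
  out <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
  if (all(is.na(out))) return(out)
  zoo::na.fill(zoo::na.approx(out, na.rm = FALSE), "extend")
}

#' Classify a baseline value
#'
#' Bradycardia below 110 bpm, Normal in 110--160 bpm, Tachycardia above
#' 160 bpm (standard guideline cut-offs); an unidentifiable (`NA`) value
#' passes through as `"Undetermined"`.
#'
#' @param value Baseline bpm (vectorized).
#' @return Character vector in
#'   `{"Bradycardia","Normal","Tachycardia","Undetermined"}`.
#' @export
classify_baseline <- function(value) {
  out <- ifelse(is.na(value), "Undetermined",
                ifelse(value < 110, "Bradycardia",
                       ifelse(value <= 160, "Normal", "Tachycardia")))
  as.character(out)
}

#' Segment-based FHR variability
#'
#' Splits the record into discrete (non-overlapping) 10-minute slices and
#' each slice into 1-minute segments. Within a segment the deviation of the
#' FHR from the baseline is examined: the segment has an identifiable
#' variability only if the deviation completes more than one cycle (more
#' than two zero crossings). A qualifying segment contributes the standard
#' deviation of the deviation. Per slice the qualifying segments are
#' combined by `mode` (`"mean"`, the default, or `"sum"`), and the record
#' variability is the mean over slices with at least one qualifying
#' segment. With no qualifying segment anywhere the variability is
#' undetermined (`NA`).
#'
#' @param fhr Numeric FHR series, bpm.
#' @param baseline A `ctg_baseline` from [estimate_baseline()], or a
#'   per-sample numeric baseline series.
#' @param mask Logical validity mask.
#' @param sample_rate Hz.
#' @param mode How qualifying 1-minute segments combine within a 10-minute
#'   slice: `"mean"` (default) or `"sum"`.
#' @return A list of class `ctg_variability`: `value` (bpm, `NA` if
#'   undetermined), `type` (see [classify_variability()]), `n_segments`
#'   (qualifying segments), `per_slice` (numeric vector).
#' @export
compute_variability <- function(fhr, baseline, mask = NULL, sample_rate = 4,
                                mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  n <- length(fhr)
  if (is.null(mask)) mask <- rep(TRUE, n)
  bl <- if (inherits(baseline, "ctg_baseline")) baseline_series(baseline)
        else as.numeric(baseline)
  dev <- fhr - bl
  slice_len <- as.integer(10 * 60 * sample_rate)
  seg_len <- as.integer(60 * sample_rate)
  slice_starts <- seq(1L, n, by = slice_len)
  per_slice <- numeric(0)
  n_seg <- 0L
  for (ss in slice_starts) {
    se <- min(n, ss + slice_len - 1L)
    seg_vals <- numeric(0)
    for (gs in seq(ss, se, by = seg_len)) {
      ge <- min(se, gs + seg_len - 1L)
      d <- dev[gs:ge][mask[gs:ge]]
      d <- d[!is.na(d)]
      if (length(d) < 2) next
      if (count_cycles(d) <= 1) next
      seg_vals <- c(seg_vals, stats::sd(d))
    }
    if (length(seg_vals)) {
      n_seg <- n_seg + length(seg_vals)
      per_slice <- c(per_slice,
                     if (mode == "mean") mean(seg_vals) else sum(seg_vals))
    }
  }
  value <- if (length(per_slice)) mean(per_slice) else NA_real_
  out <- list(value = value, type = classify_variability(value),
              n_segments = n_seg, per_slice = per_slice)
  class(out) <- "ctg_variability"
  out
}

# cycles = sign changes of the deviation / 2 (zeros carry the last sign)
count_cycles <- function(d) {
  s <- sign(d)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(diff(s) != 0) / 2
}

#' Classify a variability value
#'
#' Absent when essentially undetectable (<= 0.5 bpm), Minimal up to 5 bpm,
#' Moderate in (5, 25] bpm, Marked above 25 bpm; `NA` (undetermined
#' variability) maps to `"Absent"`, since no segment showed a measurable
#' oscillation.
#'
#' @param v Variability in bpm (vectorized).
#' @return Character vector in `{"Absent","Minimal","Moderate","Marked"}`.
#' @export
classify_variability <- function(v) {
  if (any(!is.na(v) & v < 0)) stop("variability cannot be negative",
                                   call. = FALSE)
  out <- ifelse(is.na(v) | v <= 0.5, "Absent",
                ifelse(v <= 5, "Minimal",
                       ifelse(v <= 25, "Moderate", "Marked")))
  as.character(out)
}

# maximal runs where cond is TRUE, split at masked runs longer than
# max_gap_s; returns data.frame(start, end) in samples (end inclusive)
excursion_runs <- function(cond, mask, sample_rate, max_gap_s = 15) {
  # treat short masked runs as belonging to the surrounding excursion
  n <- length(cond)
  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  long_gap <- logical(n)
  for (i in seq_along(r$lengths))
    if (r$values[i] && r$lengths[i] > max_gap_s * sample_rate)
      long_gap[(ends[i] - r$lengths[i] + 1L):ends[i]] <- TRUE
  x <- cond & !long_gap
  x[!mask & !long_gap] <- NA          # bridge short gaps
  x <- zoo::na.locf(zoo::na.locf(x, na.rm = FALSE), fromLast = TRUE,
                    na.rm = FALSE)
  x[is.na(x)] <- FALSE
  rr <- rle(as.logical(x))
  ee <- cumsum(rr$lengths)
  ss <- ee - rr$lengths + 1L
  keep <- rr$values
  data.frame(start = ss[keep], end = ee[keep])
}

#' Detect accelerations
#'
#' Finds positive baseline-crossing excursions of the FHR and keeps those
#' lasting between 15 s and 10 min whose peak exceeds the baseline by more
#' than 15 bpm. Excursions longer than 10 min are not events but baseline
#' changes and are returned flagged as such. Excursions may not span a
#' masked run longer than 15 s; such runs split the excursion.
#'
#' @param fhr Numeric FHR series, bpm.
#' @param baseline A `ctg_baseline` or per-sample baseline series.
#' @param mask Logical validity mask.
#' @param sample_rate Hz.
#' @param min_amp_bpm Peak-above-baseline threshold (bpm, exclusive).
#' @return An event log: data frame of class `ctg_events` with columns
#'   `kind`, `type`, `start`, `extremum`, `end` (1-based samples),
#'   `amplitude` (bpm), `duration_s`, `membership` (`NA` for
#'   accelerations), `baseline_change` (logical).
#' @export
detect_accelerations <- function(fhr, baseline, mask = NULL, sample_rate = 4,
                                 min_amp_bpm = 15) {
  n <- length(fhr)
  if (is.null(mask)) mask <- rep(TRUE, n)
  bl <- if (inherits(baseline, "ctg_baseline")) baseline_series(baseline)
        else as.numeric(baseline)
  dev <- fhr - bl
  runs <- excursion_runs(!is.na(dev) & dev > 0, mask, sample_rate)
  out <- empty_events()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    idx <- s:e
    dd <- dev[idx]
    dd[!mask[idx]] <- NA
    if (all(is.na(dd))) next
    pk <- idx[which.max(dd)]
    amp <- dev[pk]
    dur <- (e - s + 1) / sample_rate
    if (is.na(amp) || amp <= min_amp_bpm) next
    if (dur < 15) next
    bc <- dur > 600
    out <- rbind(out, data.frame(kind = "acceleration", type = "untyped",
                                 start = s, extremum = pk, end = e,
                                 amplitude = amp, duration_s = dur,
                                 membership = NA_real_,
                                 baseline_change = bc,
                                 stringsAsFactors = FALSE))
  }
  class(out) <- c("ctg_events", "data.frame")
  out
}

empty_events <- function() {
  data.frame(kind = character(), type = character(), start = integer(),
             extremum = integer(), end = integer(), amplitude = numeric(),
             duration_s = numeric(), membership = numeric(),
             baseline_change = logical(), stringsAsFactors = FALSE)
}

#' Trapezoidal membership grades for a candidate deceleration
#'
#' Duration grade: 0 below 10 s, rising linearly on 10--15 s, 1 on 15 s to
#' 10 min, 0 beyond 10 min (a baseline change, not a deceleration). Depth
#' grade: 0 below 10 bpm, rising linearly on 10--15 bpm, 1 at 15 bpm and
#' above. The event membership is the minimum of the two, so any event
#' meeting the crisp NICHD definition (>= 15 s and >= 15 bpm) grades 1.
#'
#' @param duration_s Event duration, seconds.
#' @param depth_bpm Baseline-to-nadir depth, bpm.
#' @return `decel_membership()` returns the combined grade in `[0, 1]`;
#'   `mu_duration()`/`mu_depth()` the individual grades. All vectorized.
#' @export
decel_membership <- function(duration_s, depth_bpm) {
  pmin(mu_duration(duration_s), mu_depth(depth_bpm))
}

#' @rdname decel_membership
#' @export
mu_duration <- function(duration_s) {
  ifelse(duration_s > 600, 0,
         pmin(1, pmax(0, (duration_s - 10) / 5)))
}

#' @rdname decel_membership
#' @export
mu_depth <- function(depth_bpm) pmin(1, pmax(0, (depth_bpm - 10) / 5))

#' Fuzzy deceleration detection
#'
#' Finds negative baseline-crossing excursions of the FHR and grades each
#' with [decel_membership()]; excursions with membership at least `theta`
#' are emitted as decelerations. Events meeting the crisp NICHD definition
#' (duration >= 15 s, depth >= 15 bpm) always carry membership 1, so the
#' fuzzy detector can only add borderline events relative to a crisp one.
#' Negative excursions longer than 10 minutes are baseline changes and
#' grade 0.
#'
#' @inheritParams detect_accelerations
#' @param theta Emission threshold on the membership (default 0.5).
#' @return A `ctg_events` data frame (see [detect_accelerations()]), with
#'   `membership` filled and `type = "untyped"`.
#' @export
detect_decelerations_fuzzy <- function(fhr, baseline, mask = NULL,
                                       sample_rate = 4, theta = 0.5) {
  n <- length(fhr)
  if (is.null(mask)) mask <- rep(TRUE, n)
  bl <- if (inherits(baseline, "ctg_baseline")) baseline_series(baseline)
        else as.numeric(baseline)
  dev <- fhr - bl
  runs <- excursion_runs(!is.na(dev) & dev < 0, mask, sample_rate)
  out <- empty_events()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    idx <- s:e
    dd <- dev[idx]
    dd[!mask[idx]] <- NA
    if (all(is.na(dd))) next
    nadir <- idx[which.min(dd)]
    depth <- -dev[nadir]
    dur <- (e - s + 1) / sample_rate
    memb <- decel_membership(dur, depth)
    if (is.na(memb) || memb == 0 || memb < theta) next
    out <- rbind(out, data.frame(kind = "deceleration", type = "untyped",
                                 start = s, extremum = nadir, end = e,
                                 amplitude = -depth, duration_s = dur,
                                 membership = memb,
                                 baseline_change = dur > 600,
                                 stringsAsFactors = FALSE))
  }
  class(out) <- c("ctg_events", "data.frame")
  out
}

#' Detect uterine contractions
#'
#' Prominence-based peak detection on the uterine-contraction-pressure
#' channel: peaks rising at least `min_prominence` above their surroundings
#' and separated by at least `min_separation_s` are contraction peaks; the
#' onset/offset are where the pressure last/next drops to within
#' `onset_frac` of the prominence above the local base. A flat channel
#' yields an empty log.
#'
#' @param ucp Numeric UCP series (arbitrary pressure units).
#' @param sample_rate Hz.
#' @param min_prominence Minimum peak prominence (pressure units).
#' @param min_separation_s Minimum peak separation, seconds.
#' @param onset_frac Fraction of prominence defining onset/offset (default
#'   0.1).
#' @return A `ctg_events` data frame with `kind = "contraction"`.
#' @export
detect_contractions <- function(ucp, sample_rate = 4, min_prominence = 10,
                                min_separation_s = 30, onset_frac = 0.1) {
  out <- empty_events()
  if (max(ucp) - min(ucp) < min_prominence) {
    class(out) <- c("ctg_events", "data.frame")
    return(out)
  }
  pk <- pracma::findpeaks(ucp,
                          minpeakdistance =
                            as.integer(min_separation_s * sample_rate),
                          minpeakheight = min(ucp) + min_prominence,
                          zero = "+")
  if (is.null(pk)) {
    class(out) <- c("ctg_events", "data.frame")
    return(out)
  }
  base <- stats::quantile(ucp, 0.1)   # resting tonus estimate
  for (i in seq_len(nrow(pk))) {
    p <- pk[i, 2]
    h <- pk[i, 1]
    prom <- h - base
    if (prom < min_prominence) next
    thr <- base + onset_frac * prom
    s <- p
    while (s > 1 && ucp[s - 1] > thr) s <- s - 1
    e <- p
    while (e < length(ucp) && ucp[e + 1] > thr) e <- e + 1
    out <- rbind(out, data.frame(kind = "contraction", type = "untyped",
                                 start = s, extremum = p, end = e,
                                 amplitude = prom,
                                 duration_s = (e - s + 1) / sample_rate,
                                 membership = NA_real_,
                                 baseline_change = FALSE,
                                 stringsAsFactors = FALSE))
  }
  class(out) <- c("ctg_events", "data.frame")
  out
}

#' Type a deceleration against the contraction train
#'
#' Rule-based early/late/variable typing from shape and timing: an abrupt
#' onset (onset-to-nadir under `abrupt_s`, default 30 s) makes the
#' deceleration variable; a gradual deceleration whose nadir falls within
#' `align_tol_s` (15 s) of the nearest contraction peak is early; a gradual
#' nadir lagging the peak by more than `align_tol_s` is late; with no
#' contraction peak within `max_couple_s` (120 s) the deceleration is
#' uncoupled and typed variable. An empty contraction log types everything
#' variable, with a warning.
#'
#' @param decels A `ctg_events` data frame of decelerations.
#' @param contractions A `ctg_events` data frame of contractions.
#' @param sample_rate Hz.
#' @param abrupt_s Onset-to-nadir threshold separating abrupt from gradual.
#' @param align_tol_s Nadir/peak alignment tolerance, seconds.
#' @param max_couple_s Maximum nadir-to-peak distance for coupling, seconds.
#' @return `decels` with its `type` column filled with
#'   `"early"`/`"late"`/`"variable"`.
#' @export
classify_decelerations <- function(decels, contractions, sample_rate = 4,
                                   abrupt_s = 30, align_tol_s = 15,
                                   max_couple_s = 120) {
  if (!nrow(decels)) return(decels)
  if (!nrow(contractions)) {
    warning("no contractions detected; all decelerations typed variable",
            call. = FALSE)
    decels$type <- "variable"
    return(decels)
  }
  peaks <- contractions$extremum
  for (i in seq_len(nrow(decels))) {
    onset_to_nadir <- (decels$extremum[i] - decels$start[i]) / sample_rate
    if (onset_to_nadir < abrupt_s) {
      decels$type[i] <- "variable"
      next
    }
    lag_s <- (decels$extremum[i] - peaks) / sample_rate
    j <- which.min(abs(lag_s))
    if (abs(lag_s[j]) > max_couple_s) {
      decels$type[i] <- "variable"
    } else if (abs(lag_s[j]) <= align_tol_s) {
      decels$type[i] <- "early"
    } else if (lag_s[j] > align_tol_s) {
      decels$type[i] <- "late"
    } else {
      decels$type[i] <- "variable"   # gradual but leading the peak
    }
  }
  decels
}

#' Screen for a sinusoidal heart-rate pattern
#'
#' A sinusoidal pattern is reported `"Present"` when, over at least 20
#' minutes of valid signal, the deviation from baseline concentrates its
#' spectral power (more than `power_frac`) in the 2--5 cycles/min band with
#' an equivalent sine amplitude of 5--15 bpm, and no accelerations were
#' detected. Records with under 20 minutes of valid signal are
#' `"Undetermined"`.
#'
#' @inheritParams detect_accelerations
#' @param accelerations A `ctg_events` log of detected accelerations (the
#'   pattern requires their absence).
#' @param power_frac Minimum fraction of total power inside the band.
#' @return `"Present"`, `"Absent"` or `"Undetermined"`.
#' @export
detect_shr <- function(fhr, baseline, mask = NULL, sample_rate = 4,
                       accelerations = NULL, power_frac = 0.5) {
  n <- length(fhr)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (sum(mask) < 20 * 60 * sample_rate) return("Undetermined")
  bl <- if (inherits(baseline, "ctg_baseline")) baseline_series(baseline)
        else as.numeric(baseline)
  dev <- fhr - bl
  dev[!mask] <- NA
  dev <- zoo::na.fill(zoo::na.approx(dev, na.rm = FALSE), "extend")
  if (all(is.na(dev)) || stats::sd(dev) < 1e-9) return("Absent")
  sp <- stats::spec.pgram(stats::ts(dev, frequency = sample_rate),
                          taper = 0.1, plot = FALSE, detrend = TRUE)
  band <- sp$freq >= 2 / 60 & sp$freq <= 5 / 60
  frac <- sum(sp$spec[band]) / sum(sp$spec)
  # equivalent sine amplitude from band power: a = sqrt(2 * var_band)
  df <- sp$freq[2] - sp$freq[1]
  amp <- sqrt(2 * 2 * sum(sp$spec[band]) * df)
  has_acc <- !is.null(accelerations) && nrow(accelerations) > 0
  if (frac > power_frac && amp >= 5 && amp <= 15 && !has_acc) "Present"
  else "Absent"
}

#' Extract the 11-feature summary of a CTG record
#'
#' Runs the full detector stack (baseline, variability, accelerations,
#' fuzzy decelerations, contractions, deceleration typing, sinusoidal
#' screening) over the record's stage-1 analysis span (truncated to its
#' final 60 minutes) and assembles the standard 11-feature row: baseline
#' (bpm) and its class, variability (bpm) and its class, acceleration
#' presence and count, early/late/variable deceleration counts, sinusoidal
#' pattern, and labor stage. An undetermined baseline or variability
#' propagates as its explicit category, never as a silent imputation.
#'
#' @param record A [ctg_record()].
#' @param stage Stage label for the row: `"normal"`, `"stage1"` or
#'   `"stage2"`. Defaults to `"stage1"`.
#' @param variability_mode Passed to [compute_variability()].
#' @param theta Fuzzy emission threshold, see [detect_decelerations_fuzzy()].
#' @return A one-row data frame of class `ctg_features` with columns
#'   `baseline`, `baseline_type`, `variability`, `variability_type`,
#'   `acceleration_present`, `n_accelerations`, `n_early`, `n_late`,
#'   `n_variable`, `shr`, `stage`. The detected event logs are attached as
#'   attribute `"events"`.
#' @export
extract_features <- function(record, stage = c("stage1", "stage2", "normal"),
                             variability_mode = "mean", theta = 0.5) {
  stopifnot(inherits(record, "ctg_record"))
  stage <- match.arg(stage)
  record <- truncate_stage1(record)
  idx <- span_idx(record$stage1_span)
  fhr <- record$fhr[idx]
  ucp <- record$ucp[idx]
  mask <- record$mask[idx]
  fs <- record$sample_rate

  bl <- estimate_baseline(fhr, mask, fs)
  blv <- bl$value[!is.na(bl$value)]
  baseline_val <- if (length(blv)) mean(blv) else NA_real_

  varb <- compute_variability(fhr, bl, mask, fs, mode = variability_mode)
  acc <- detect_accelerations(fhr, bl, mask, fs)
  acc <- acc[!acc$baseline_change, , drop = FALSE]
  dec <- detect_decelerations_fuzzy(fhr, bl, mask, fs, theta = theta)
  dec <- dec[!dec$baseline_change, , drop = FALSE]
  ctr <- detect_contractions(ucp, fs)
  dec <- suppressWarnings(classify_decelerations(dec, ctr, fs))
  shr <- detect_shr(fhr, bl, mask, fs, accelerations = acc)

  out <- data.frame(
    baseline = baseline_val,
    baseline_type = classify_baseline(baseline_val),
    variability = if (is.na(varb$value)) 0 else varb$value,
    variability_type = varb$type,
    acceleration_present = nrow(acc) > 0,
    n_accelerations = nrow(acc),
    n_early = sum(dec$type == "early"),
    n_late = sum(dec$type == "late"),
    n_variable = sum(dec$type == "variable"),
    shr = shr,
    stage = stage,
    stringsAsFactors = FALSE)
  attr(out, "events") <- list(accelerations = acc, decelerations = dec,
                              contractions = ctr)
  class(out) <- c("ctg_features", "data.frame")
  out
}

#' Feature table for a cohort
#'
#' Applies [extract_features()] to every record of a cohort (as produced by
#' [generate_cohort()], or any list of `list(record, truth)` /
#' `ctg_record` elements) and binds the rows. When ground truth is present
#' the majority-vote label of the simulated raters (or the true label if no
#' raters) is attached as a `label` column.
#'
#' @param cohort List of cohort elements.
#' @param ... Passed to [extract_features()].
#' @return A data frame with 11 feature columns plus `id` and (when
#'   available) `label`.
#' @export
extract_cohort_features <- function(cohort, ...) {
  rows <- lapply(cohort, function(el) {
    rec <- if (inherits(el, "ctg_record")) el else el$record
    truth <- if (inherits(el, "ctg_record")) NULL else el$truth
    stage <- if (!is.null(truth) && identical(truth$stage, 2)) "stage2"
             else "stage1"
    f <- extract_features(rec, stage = stage, ...)
    attr(f, "events") <- NULL
    f$id <- rec$id
    if (!is.null(truth)) {
      f$label <- if (!anyNA(truth$rater_labels))
        aggregate_annotations(truth$rater_labels) else truth$label
    }
    f
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match detected events to ground-truth events
#'
#' Greedy one-to-one interval matching: a detected event matches a truth
#' event of the same kind when their intervals overlap or their extrema lie
#' within `tol_s` seconds. Used to score detection recall/precision/F1
#' against the synthetic generator's event log.
#'
#' @param detected,truth Event data frames with `start`, `extremum`, `end`
#'   columns (samples).
#' @param sample_rate Hz.
#' @param tol_s Extremum tolerance, seconds.
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`, and
#'   `pairs` (matrix of matched row indices: detected, truth).
#' @export
match_events <- function(detected, truth, sample_rate = 4, tol_s = 30) {
  nt <- nrow(truth)
  nd <- nrow(detected)
  used <- logical(nt)
  pairs <- NULL
  for (i in seq_len(nd)) {
    best <- 0L
    bestd <- Inf
    for (j in seq_len(nt)) {
      if (used[j]) next
      overlap <- detected$start[i] <= truth$end[j] &&
        truth$start[j] <= detected$end[i]
      d <- abs(detected$extremum[i] - truth$extremum[j]) / sample_rate
      if ((overlap || d <= tol_s) && d < bestd) {
        best <- j
        bestd <- d
      }
    }
    if (best > 0L) {
      used[best] <- TRUE
      pairs <- rbind(pairs, c(i, best))
    }
  }
  tp <- sum(used)
  fp <- nd - tp
  fn <- nt - tp
  prec <- if (nd) tp / nd else NA_real_
  rec <- if (nt) tp / nt else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1,
       pairs = pairs)
}
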