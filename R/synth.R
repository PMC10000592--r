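#' Configuration for a synthetic CTG record
#'
#' Collects every knob of the synthetic generator: signal duration and rate,
#' baseline level and slow drift, beat-to-beat variability, episodic
#' accelerations, a uterine-contraction train, a list of decelerations tied
#' to that train, an optional sinusoidal pattern, and a missing-signal
#' fraction. The same configuration (including `seed`) always yields a
#' bit-identical record.
#'
#' @param duration_min Record length in minutes (> 0).
#' @param sample_rate Sampling rate in Hz (default 4).
#' @param baseline_bpm Baseline FHR level, bpm.
#' @param baseline_drift_bpm Amplitude (bpm) of a slow sinusoidal drift
#'   (one cycle over the record).
#' @param variability_sd_bpm Standard deviation (bpm) of the band-limited
#'   beat-to-beat variability noise.
#' @param n_accelerations Number of accelerations to place.
#' @param contraction_period_s Seconds between successive contraction peaks.
#' @param decel_spec List of deceleration specs, each a list/vector with
#'   elements `type` (`"early"`, `"late"` or `"variable"`), `depth_bpm` and
#'   `duration_s`. Each spec is attached to the next free contraction.
#' @param late_lag_s Seconds by which a late deceleration's nadir lags the
#'   contraction peak (default 40).
#' @param gap_fraction Fraction of samples flagged missing, in `[0, 0.5]`.
#' @param shr `"absent"` or `"present"`: add a sinusoidal heart-rate pattern
#'   (4 cycles/min, 10 bpm amplitude). A sinusoidal record carries no
#'   accelerations.
#' @param stage Labor stage of the record, 1 or 2.
#' @param contraction_jitter_s SD (seconds) of random jitter applied to each
#'   contraction peak time (default 0: strictly periodic).
#' @param seed Integer seed fixing all randomness of the record.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_min = 30, sample_rate = 4,
                         baseline_bpm = 140, baseline_drift_bpm = 3,
                         variability_sd_bpm = 6, n_accelerations = 3,
                         contraction_period_s = 180, decel_spec = list(),
                         late_lag_s = 40, gap_fraction = 0,
                         shr = c("absent", "present"), stage = 1,
                         contraction_jitter_s = 0, seed = 1L) {
  shr <- match.arg(shr)
  if (!is.numeric(duration_min) || duration_min <= 0)
    stop("duration_min must be > 0", call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0", call. = FALSE)
  if (gap_fraction < 0 || gap_fraction > 0.5)
    stop("gap_fraction must lie in [0, 0.5]", call. = FALSE)
  if (!stage %in% c(1, 2)) stop("stage must be 1 or 2", call. = FALSE)
  decel_spec <- lapply(decel_spec, function(d) {
    d <- as.list(d)
    if (is.null(d$type) || !d$type %in% c("early", "late", "variable"))
      stop("decel_spec entries need type in {early, late, variable}",
           call. = FALSE)
    d$depth_bpm <- as.numeric(d$depth_bpm)
    d$duration_s <- as.numeric(d$duration_s)
    if (is.na(d$depth_bpm) || is.na(d$duration_s) || d$depth_bpm <= 0 ||
        d$duration_s <= 0)
      stop("decel_spec entries need positive depth_bpm and duration_s",
           call. = FALSE)
    d
  })
  out <- list(duration_min = duration_min, sample_rate = sample_rate,
              baseline_bpm = baseline_bpm,
              baseline_drift_bpm = baseline_drift_bpm,
              variability_sd_bpm = variability_sd_bpm,
              n_accelerations = as.integer(n_accelerations),
              contraction_period_s = contraction_period_s,
              decel_spec = decel_spec, late_lag_s = late_lag_s,
              gap_fraction = gap_fraction, shr = shr, stage = stage,
              contraction_jitter_s = contraction_jitter_s,
              seed = as.integer(seed))
  class(out) <- "synth_config"
  out
}

# raised-cosine bump of unit peak over [start, end] (sample indices)
raised_cosine <- function(n, start, end) {
  v <- numeric(n)
  i <- max(1L, start):min(n, end)
  v[i] <- 0.5 * (1 - cos(2 * pi * (i - start) / (end - start)))
  v
}

# abrupt piecewise-linear V with nadir at frac of the duration
vee_shape <- function(n, start, end, nadir) {
  v <- numeric(n)
  i1 <- max(1L, start):nadir
  i2 <- nadir:min(n, end)
  v[i1] <- (i1 - start) / (nadir - start)
  v[i2] <- (end - i2) / (end - nadir)
  v
}

# band-limited Gaussian noise, rescaled to unit sd
bandlimited_noise <- function(n, sample_rate, cutoff_hz = 0.5) {
  w <- stats::rnorm(n + 200)
  bf <- signal::butter(2, min(0.99, cutoff_hz / (sample_rate / 2)), "low")
  x <- signal::filtfilt(bf, w)[101:(n + 100)]
  x / stats::sd(x)
}

#' Generate one synthetic CTG record with ground truth
#'
#' Builds an FHR trace as baseline + slow drift + band-limited variability
#' noise + summed event deflections (clipped to 50--220 bpm) and a UCP trace
#' as resting tonus + raised-cosine contraction bumps at the configured
#' period. Accelerations and early decelerations are raised-cosine bumps,
#' late decelerations are raised-cosine bumps whose nadir lags the nearest
#' contraction peak by `late_lag_s`, and variable decelerations are abrupt
#' piecewise-linear V shapes. Every placed event is logged in the ground
#' truth with its exact start/extremum/end sample.
#'
#' @param config A [synth_config()].
#' @param label Optional true 3-class label (1 Normal, 2 Suspicious,
#'   3 Pathological) stored in the ground truth.
#' @param rater_concordance If not `NULL`, probability with which each of 6
#'   simulated raters reproduces `label` (see [simulate_raters()]).
#' @return A list with elements `record` (a [ctg_record()]) and `truth`, a
#'   list of class `ctg_truth` holding `events` (data frame: kind, type,
#'   start, extremum, end in 1-based samples, depth_bpm), `true_baseline`
#'   (per-sample bpm), `true_variability_bpm`, `label` and `rater_labels`.
#' @export
generate_record <- function(config, label = NA_integer_,
                            rater_concordance = NULL) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  fs <- config$sample_rate
  n <- as.integer(round(config$duration_min * 60 * fs))
  t_s <- (seq_len(n) - 1) / fs

  base <- config$baseline_bpm +
    config$baseline_drift_bpm * sin(2 * pi * t_s / (config$duration_min * 60))

  noise <- if (config$variability_sd_bpm > 0)
    config$variability_sd_bpm * bandlimited_noise(n, fs) else numeric(n)

  # contraction train: tonus + raised-cosine bumps
  tonus <- 10
  contr_dur <- 60 * fs
  period <- config$contraction_period_s * fs
  peaks <- seq(period, n - contr_dur / 2, by = period)
  if (config$contraction_jitter_s > 0 && length(peaks))
    peaks <- peaks + round(stats::rnorm(length(peaks),
                                        sd = config$contraction_jitter_s * fs))
  peaks <- as.integer(round(peaks))
  peaks <- peaks[peaks > contr_dur / 2 & peaks < n - contr_dur / 2]
  ucp <- rep(tonus, n)
  contr_events <- NULL
  if (length(peaks)) {
    amp <- stats::runif(length(peaks), 30, 50)
    for (j in seq_along(peaks)) {
      s <- as.integer(peaks[j] - contr_dur / 2)
      e <- as.integer(peaks[j] + contr_dur / 2)
      ucp <- ucp + amp[j] * raised_cosine(n, s, e)
    }
    contr_events <- data.frame(kind = "contraction", type = "untyped",
                               start = as.integer(peaks - contr_dur / 2),
                               extremum = peaks,
                               end = as.integer(peaks + contr_dur / 2),
                               depth_bpm = amp, stringsAsFactors = FALSE)
  }

  deflect <- numeric(n)
  events <- list(contr_events)
  occupied <- logical(n)   # samples claimed by an event (incl. margin)
  claim <- function(s, e) {
    i <- max(1L, s - as.integer(15 * fs)):min(n, e + as.integer(15 * fs))
    occupied[i] <<- TRUE
  }

  # decelerations ride on successive contractions
  if (length(config$decel_spec)) {
    if (!length(peaks))
      stop("cannot place decelerations: record too short for any contraction",
           call. = FALSE)
    next_peak <- 1L
    for (k in seq_along(config$decel_spec)) {
      d <- config$decel_spec[[k]]
      placed <- FALSE
      while (next_peak <= length(peaks) && !placed) {
        pk <- peaks[next_peak]
        half <- as.integer(round(d$duration_s * fs / 2))
        nadir <- switch(d$type,
                        early = pk,
                        late = pk + as.integer(round(config$late_lag_s * fs)),
                        variable = pk)
        s <- nadir - half
        e <- nadir + half
        if (d$type == "variable") {
          # abrupt onset: nadir reached well inside 30 s
          s <- nadir - as.integer(round(min(10, d$duration_s / 3) * fs))
          e <- s + as.integer(round(d$duration_s * fs))
        }
        next_peak <- next_peak + 1L
        if (s < 1L || e > n) next
        if (any(occupied[s:e])) next
        shape <- if (d$type == "variable") vee_shape(n, s, e, nadir)
                 else raised_cosine(n, s, e)
        deflect <- deflect - d$depth_bpm * shape
        claim(s, e)
        events[[length(events) + 1L]] <-
          data.frame(kind = "deceleration", type = d$type,
                     start = as.integer(s), extremum = as.integer(nadir),
                     end = as.integer(e), depth_bpm = d$depth_bpm,
                     stringsAsFactors = FALSE)
        placed <- TRUE
      }
      if (!placed)
        stop("cannot place decel_spec entry ", k, " (type=", d$type,
             ", duration=", d$duration_s,
             "s): no free contraction slot in the record", call. = FALSE)
    }
  }

  # accelerations go into free gaps between claimed event windows
  n_acc <- if (config$shr == "present") 0L else config$n_accelerations
  if (n_acc > 0) {
    for (k in seq_len(n_acc)) {
      depth <- stats::runif(1, 18, 25)
      dur <- as.integer(round(stats::runif(1, 30, 90) * fs))
      placed <- FALSE
      for (try in 1:200) {
        s <- as.integer(sample.int(n - dur - 2L * fs, 1) + fs)
        e <- s + dur
        if (any(occupied[s:e])) next
        pk <- as.integer(round((s + e) / 2))
        deflect <- deflect + depth * raised_cosine(n, s, e)
        claim(s, e)
        events[[length(events) + 1L]] <-
          data.frame(kind = "acceleration", type = "untyped", start = s,
                     extremum = pk, end = e, depth_bpm = depth,
                     stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) warning("could not place acceleration ", k,
                           "; record is crowded", call. = FALSE)
    }
  }

  shr_wave <- if (config$shr == "present")
    10 * sin(2 * pi * (4 / 60) * t_s) else numeric(n)

  fhr <- pmin(220, pmax(50, base + noise + deflect + shr_wave))

  mask <- rep(TRUE, n)
  if (config$gap_fraction > 0) mask <- gap_mask(n, config$gap_fraction, fs)

  ev <- do.call(rbind, Filter(Negate(is.null), events))
  if (is.null(ev))
    ev <- data.frame(kind = character(), type = character(),
                     start = integer(), extremum = integer(),
                     end = integer(), depth_bpm = numeric(),
                     stringsAsFactors = FALSE)
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL

  raters <- if (!is.null(rater_concordance) && !is.na(label))
    simulate_raters(label, rater_concordance) else rep(NA_integer_, 6)

  stage2 <- NULL
  s1 <- c(0L, n)
  if (config$stage == 2) s1 <- c(0L, n)  # whole record is the analysed stage
  rec <- ctg_record(fhr, ucp, mask, fs, stage1_span = s1,
                    stage2_span = stage2,
                    meta = ctg_meta(ph = 7.2, gestation_weeks = 39,
                                    maternal_age = 28,
                                    end_to_birth_min = 10),
                    id = sprintf("synth-%d", config$seed))
  truth <- list(events = ev, true_baseline = base,
                true_variability_bpm = config$variability_sd_bpm,
                label = as.integer(label), rater_labels = raters,
                stage = config$stage, config = config)
  class(truth) <- "ctg_truth"
  list(record = rec, truth = truth)
}

# mask gap_fraction of n samples in non-overlapping runs of ~gap_len samples
gap_mask <- function(n, fraction, sample_rate, gap_len_s = 30) {
  target <- as.integer(round(fraction * n))
  run <- max(1L, as.integer(gap_len_s * sample_rate))
  bad <- logical(n)
  guard <- 0L
  while (sum(bad) < target && guard < 10000L) {
    guard <- guard + 1L
    len <- min(run, target - sum(bad))
    s <- sample.int(n - len + 1L, 1)
    if (any(bad[s:(s + len - 1L)])) next
    bad[s:(s + len - 1L)] <- TRUE
  }
  !bad
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate six independent annotators
#'
#' Each rater reports the true class with probability `concordance`;
#' otherwise an adjacent class (Normal 1 <-> Suspicious 2 <-> Pathological
#' 3; class 2 errs toward 1 or 3 with equal probability), reflecting the
#' clinical gray zone where confusions are between neighbouring severities.
#'
#' @param truth_label True class in `{1, 2, 3}`.
#' @param concordance Per-rater probability of reporting the truth.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so cohort generation stays reproducible from one seed).
#' @return Integer vector of 6 class labels.
#' @seealso [aggregate_annotations()] for the majority vote.
#' @export
simulate_raters <- function(truth_label, concordance, seed = NULL) {
  stopifnot(truth_label %in% 1:3, concordance >= 0, concordance <= 1)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  ok <- stats::runif(6) < concordance
  adj <- switch(truth_label,
                `1` = rep(2L, 6),
                `2` = sample(c(1L, 3L), 6, replace = TRUE),
                `3` = rep(2L, 6))
  ifelse(ok, as.integer(truth_label), adj)
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n` records whose class-conditional generation recipes make the
#' three fetal-state classes statistically separable in the extracted
#' features: Normal records have moderate variability, several
#' accelerations and at most mild early decelerations; Suspicious records
#' have reduced variability, mild tachy-/bradycardia and variable
#' decelerations; Pathological records have absent/minimal variability and
#' recurrent late decelerations or a sinusoidal pattern. Stage-2 records
#' use a shorter contraction period with deeper, recurrent decelerations.
#'
#' @param n Number of records.
#' @param class_mix Length-3 proportions (Normal, Suspicious, Pathological)
#'   summing to 1. Class counts are `n * class_mix` rounded so that they
#'   total `n` (largest-remainder rule).
#' @param stage Labor stage for the whole cohort, 1 or 2.
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @param concordance Per-rater concordance passed to [simulate_raters()].
#' @param gap_fraction Missing-signal fraction per record.
#' @return A list of `n` elements, each a `list(record, truth)` as returned
#'   by [generate_record()].
#' @export
generate_cohort <- function(n, class_mix = c(0.34, 0.39, 0.27), stage = 1,
                            seed = 1L, concordance = 0.9,
                            gap_fraction = 0.05) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix proportions must sum to 1", call. = FALSE)
  if (n < sum(class_mix > 0))
    stop("infeasible mix: n = ", n, " is smaller than the number of nonzero ",
         "class proportions", call. = FALSE)
  counts <- floor(n * class_mix)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * class_mix - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  labels <- rep(1:3, counts)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- class_recipe(labels[i], stage, rec_seeds[i], gap_fraction)
    # a crowded record can refuse a deceleration slot; shed events until
    # placement succeeds rather than aborting the cohort
    repeat {
      r <- tryCatch(generate_record(cfg, label = labels[i],
                                    rater_concordance = concordance),
                    error = function(e) e)
      if (!inherits(r, "error")) break
      if (length(cfg$decel_spec) == 0L) stop(r)
      cfg$decel_spec <- cfg$decel_spec[-length(cfg$decel_spec)]
    }
    out[[i]] <- r
    out[[i]]$record$id <- sprintf("synth-%03d", i)
  }
  out
}

# class-conditional generation recipe; uses the cohort RNG stream
class_recipe <- function(label, stage, seed, gap_fraction) {
  dur <- if (stage == 2) 20 else 30
  period <- if (stage == 2) stats::runif(1, 70, 110) else
    stats::runif(1, 150, 210)
  # a late nadir must still sit closer to its own contraction peak than to
  # the next one, so the lag shrinks with the stage-2 contraction period
  lag <- min(40, 0.35 * period)
  depth_boost <- if (stage == 2) 10 else 0
  if (label == 1) {                       # Normal
    n_dec <- sample(0:2, 1)
    # gradual shapes: half-duration >= 35 s keeps onset-to-nadir gradual
    spec <- replicate(n_dec, list(type = "early",
                                  depth_bpm = stats::runif(1, 28, 38),
                                  duration_s = stats::runif(1, 90, 120)),
                      simplify = FALSE)
    synth_config(duration_min = dur, baseline_bpm = stats::runif(1, 125, 150),
                 baseline_drift_bpm = stats::runif(1, 2, 5),
                 variability_sd_bpm = stats::runif(1, 5, 7.5),
                 n_accelerations = sample(2:5, 1),
                 contraction_period_s = period, decel_spec = spec,
                 late_lag_s = lag,
                 gap_fraction = gap_fraction, stage = stage, seed = seed)
  } else if (label == 2) {                # Suspicious
    bl <- if (stats::runif(1) < 0.5) stats::runif(1, 161, 172)
          else stats::runif(1, 96, 108)
    n_dec <- sample(2:4, 1)
    spec <- replicate(n_dec, list(type = "variable",
                                  depth_bpm = stats::runif(1, 25, 45) +
                                    depth_boost,
                                  duration_s = stats::runif(1, 35, 60)),
                      simplify = FALSE)
    synth_config(duration_min = dur, baseline_bpm = bl,
                 baseline_drift_bpm = stats::runif(1, 1, 4),
                 variability_sd_bpm = stats::runif(1, 2.5, 5),
                 n_accelerations = sample(0:1, 1),
                 contraction_period_s = period, decel_spec = spec,
                 late_lag_s = lag,
                 gap_fraction = gap_fraction, stage = stage, seed = seed)
  } else {                                # Pathological
    sinusoidal <- stats::runif(1) < 0.2
    n_dec <- if (sinusoidal) 0 else
      if (stage == 2) sample(5:8, 1) else sample(4:6, 1)
    dur_rng <- if (stage == 2) c(70, 90) else c(85, 110)
    spec <- replicate(n_dec, list(type = "late",
                                  depth_bpm = stats::runif(1, 35, 60) +
                                    depth_boost,
                                  duration_s = stats::runif(1, dur_rng[1],
                                                            dur_rng[2])),
                      simplify = FALSE)
    synth_config(duration_min = dur, baseline_bpm = stats::runif(1, 120, 160),
                 baseline_drift_bpm = stats::runif(1, 1, 3),
                 variability_sd_bpm = if (sinusoidal) 0.5 else
                   stats::runif(1, 0.3, 1.8),
                 n_accelerations = 0,
                 contraction_period_s = period, decel_spec = spec,
                 shr = if (sinusoidal) "present" else "absent",
                 late_lag_s = lag,
                 gap_fraction = gap_fraction, stage = stage, seed = seed)
  }
}
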