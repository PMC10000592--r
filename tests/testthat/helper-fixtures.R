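# shared fixtures and independent oracles for the test suite

# memoised cohorts so several test files can share one generation pass
.cohort_cache <- new.env(parent = emptyenv())
shared_cohort <- function(n = 100, seed = 20, stage = 1, gap_fraction = 0,
                          concordance = 0.9) {
  key <- paste(n, seed, stage, gap_fraction, concordance, sep = "_")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(n, stage = stage, seed = seed,
                                            concordance = concordance,
                                            gap_fraction = gap_fraction)
  .cohort_cache[[key]]
}

shared_features <- function(n = 100, seed = 20, stage = 1,
                            gap_fraction = 0, concordance = 0.9) {
  key <- paste("ft", n, seed, stage, gap_fraction, concordance, sep = "_")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- extract_cohort_features(
      shared_cohort(n, seed, stage, gap_fraction, concordance))
  .cohort_cache[[key]]
}

# flat-trace record: constant FHR, flat UCP unless supplied
make_flat_record <- function(bpm = 140, minutes = 30, fs = 4, ucp = NULL,
                             mask = NULL, meta = NULL, ...) {
  n <- minutes * 60 * fs
  if (is.null(ucp)) ucp <- rep(10, n)
  if (is.null(meta))
    meta <- ctg_meta(ph = 7.2, gestation_weeks = 39, maternal_age = 28,
                     end_to_birth_min = 10)
  ctg_record(rep(bpm, n), ucp, mask = mask, sample_rate = fs,
             meta = meta, ...)
}

# add a raised-cosine bump (positive or negative) to a series
add_bump <- function(x, center, duration_s, depth, fs = 4) {
  half <- round(duration_s * fs / 2)
  i <- (center - half):(center + half)
  x[i] <- x[i] + depth * 0.5 * (1 - cos(2 * pi * seq_along(i) / length(i)))
  x
}

# brute-force Pearson chi-squared: explicit double loop over cells
chi2_brute <- function(m) {
  n <- sum(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  tot <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- rs[i] * cs[j] / n
    tot <- tot + (m[i, j] - e)^2 / e
  }
  tot
}

# independent kappa: from the expanded pair sequence, agreement frequencies
kappa_oracle <- function(m) {
  pr <- realize_pairs(m)
  n <- length(pr$actual)
  po <- mean(pr$actual == pr$predicted)
  pe <- 0
  for (k in 1:3) pe <- pe + mean(pr$actual == k) * mean(pr$predicted == k)
  (po - pe) / (1 - pe)
}

# independent multiclass MCC: Pearson correlation route over indicator
# matrices, cov(X, Y) / sqrt(cov(X, X) cov(Y, Y))
mcc_oracle <- function(m) {
  pr <- realize_pairs(m)
  X <- stats::model.matrix(~ factor(pr$actual, levels = 1:3) - 1)
  Y <- stats::model.matrix(~ factor(pr$predicted, levels = 1:3) - 1)
  cv <- function(A, B) sum(diag(crossprod(scale(A, scale = FALSE),
                                          scale(B, scale = FALSE))))
  cv(X, Y) / sqrt(cv(X, X) * cv(Y, Y))
}

# crisp NICHD deceleration detector: threshold rules only, no fuzzy logic
crisp_decel_detector <- function(fhr, baseline, fs = 4) {
  dev <- fhr - baseline
  r <- rle(dev < 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- NULL
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    dur <- (e - s + 1) / fs
    depth <- -min(dev[s:e])
    if (dur >= 15 && dur <= 600 && depth >= 15)
      out <- rbind(out, data.frame(start = s, end = e, depth = depth))
  }
  if (is.null(out)) data.frame(start = integer(), end = integer(),
                               depth = numeric()) else out
}

# exact enumeration over all 3^6 rater patterns for given truth/concordance
rater_patterns <- as.matrix(expand.grid(rep(list(1:3), 6)))
majority_recovery_exact <- function(truth, concordance) {
  p_label <- function(lab, truth) {
    if (lab == truth) return(concordance)
    adj <- switch(truth, `1` = 2L, `2` = c(1L, 3L), `3` = 2L)
    if (lab %in% adj) (1 - concordance) / length(adj) else 0
  }
  tot <- 0
  for (r in seq_len(nrow(rater_patterns))) {
    pat <- rater_patterns[r, ]
    pr <- prod(vapply(pat, p_label, numeric(1), truth = truth))
    if (pr == 0) next
    if (aggregate_annotations(pat) == truth) tot <- tot + pr
  }
  tot
}

# pooled event-detection score against ground truth over a cohort
cohort_detection_score <- function(cohort, kind) {
  tp <- fp <- fn <- 0
  correct <- 0
  matched <- 0
  for (el in cohort) {
    f <- extract_features(el$record)
    ev <- attr(f, "events")
    det <- if (kind == "acceleration") ev$accelerations else ev$decelerations
    tru <- el$truth$events[el$truth$events$kind == kind, , drop = FALSE]
    m <- match_events(det, tru, el$record$sample_rate)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    if (kind == "deceleration" && !is.null(m$pairs)) {
      correct <- correct + sum(det$type[m$pairs[, 1]] ==
                                 tru$type[m$pairs[, 2]])
      matched <- matched + nrow(m$pairs)
    }
  }
  list(f1 = 2 * tp / (2 * tp + fp + fn),
       typing_accuracy = if (matched) correct / matched else NA_real_)
}
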