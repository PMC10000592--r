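#' Clinical metadata for a CTG record
#'
#' Bundles the birth-outcome and demographic fields that accompany an
#' intrapartum cardiotocograph recording and that drive record selection:
#' umbilical artery pH, base excess (BE, mmol/L), base deficit in
#' extracellular fluid (BDecf, mmol/L), Apgar score, gestational age,
#' maternal age, delivery mode and the interval from the end of the recorded
#' signal to birth.
#'
#' @param ph Umbilical artery pH (unitless). May be `NA` if unknown, but
#'   record selection then fails explicitly rather than silently including
#'   the record.
#' @param be Base excess, mmol/L.
#' @param bdecf Base deficit in extracellular fluid, mmol/L.
#' @param apgar Apgar score (0--10).
#' @param gestation_weeks Gestational age in completed weeks.
#' @param maternal_age Maternal age in years.
#' @param delivery `"vaginal"` or `"caesarean"`.
#' @param end_to_birth_min Minutes from end of the recorded first-stage
#'   signal to birth.
#' @return An object of class `ctg_meta` (a named list).
#' @export
ctg_meta <- function(ph = NA_real_, be = NA_real_, bdecf = NA_real_,
                     apgar = NA_integer_, gestation_weeks = NA_real_,
                     maternal_age = NA_real_,
                     delivery = c("vaginal", "caesarean"),
                     end_to_birth_min = NA_real_) {
  delivery <- match.arg(delivery)
  out <- list(ph = as.numeric(ph), be = as.numeric(be),
              bdecf = as.numeric(bdecf), apgar = as.integer(apgar),
              gestation_weeks = as.numeric(gestation_weeks),
              maternal_age = as.numeric(maternal_age),
              delivery = delivery,
              end_to_birth_min = as.numeric(end_to_birth_min))
  class(out) <- "ctg_meta"
  out
}

#' Construct a CTG record
#'
#' A `ctg_record` holds the paired fetal heart rate (FHR, bpm) and uterine
#' contraction pressure (UCP, arbitrary units) channels sampled at a common
#' fixed rate, a per-sample validity mask, the labor-stage spans and the
#' clinical metadata. Missing/noisy signal is represented by the mask
#' (`TRUE` = valid), never by sentinel values, so downstream arithmetic
#' stays honest.
#'
#' Stage spans are half-open `[start, end)` intervals in 0-based sample
#' offsets; they must be disjoint and ordered (stage 1 before stage 2), and
#' the stage-2 span may not exceed 30 minutes.
#'
#' @param fhr Numeric vector, FHR in bpm.
#' @param ucp Numeric vector, uterine contraction pressure; same length as
#'   `fhr`.
#' @param mask Logical vector, `TRUE` where the sample is valid. Defaults to
#'   all valid.
#' @param sample_rate Sampling rate in Hz (default 4, the common CTG
#'   convention).
#' @param stage1_span,stage2_span Integer length-2 vectors `c(start, end)`,
#'   0-based half-open sample offsets. `stage1_span` defaults to the whole
#'   record; `stage2_span` may be `NULL`.
#' @param meta A [ctg_meta()] object.
#' @param id Optional record identifier (character).
#' @return An object of class `ctg_record`.
#' @export
ctg_record <- function(fhr, ucp, mask = NULL, sample_rate = 4,
                       stage1_span = NULL, stage2_span = NULL,
                       meta = ctg_meta(), id = "record") {
  fhr <- as.numeric(fhr)
  ucp <- as.numeric(ucp)
  n <- length(fhr)
  if (length(ucp) != n)
    stop("channel length mismatch: fhr has ", n, " samples, ucp has ",
         length(ucp), call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, n)
  mask <- as.logical(mask)
  if (length(mask) != n)
    stop("channel length mismatch: mask has ", length(mask),
         " samples, fhr has ", n, call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a positive number (Hz)", call. = FALSE)
  if (is.null(stage1_span)) stage1_span <- c(0L, n)
  stage1_span <- check_span(stage1_span, n, "stage1_span")
  if (!is.null(stage2_span)) {
    stage2_span <- check_span(stage2_span, n, "stage2_span")
    if (stage2_span[1] < stage1_span[2])
      stop("stage spans must be disjoint and ordered: stage2 starts at ",
           stage2_span[1], " before stage1 ends at ", stage1_span[2],
           call. = FALSE)
    if ((stage2_span[2] - stage2_span[1]) / sample_rate > 30 * 60)
      stop("stage2_span exceeds the 30-minute second-stage limit",
           call. = FALSE)
  }
  if (!inherits(meta, "ctg_meta")) stop("meta must be a ctg_meta object",
                                        call. = FALSE)
  out <- list(fhr = fhr, ucp = ucp, mask = mask,
              sample_rate = as.numeric(sample_rate),
              stage1_span = stage1_span, stage2_span = stage2_span,
              meta = meta, id = as.character(id))
  class(out) <- "ctg_record"
  out
}

check_span <- function(span, n, what) {
  span <- as.integer(span)
  if (length(span) != 2 || anyNA(span) || span[1] < 0 || span[2] > n ||
      span[1] >= span[2])
    stop(what, " must be a valid half-open [start, end) span within 0..", n,
         call. = FALSE)
  span
}

# 1-based R indices covered by a 0-based half-open span
span_idx <- function(span) (span[1] + 1L):span[2]

#' @export
print.ctg_record <- function(x, ...) {
  n <- length(x$fhr)
  cat("<ctg_record>", x$id, "\n")
  cat(sprintf("  %d samples @ %g Hz (%.1f min), %.1f%% masked\n",
              n, x$sample_rate, n / x$sample_rate / 60,
              100 * mean(!x$mask)))
  cat(sprintf("  stage 1: [%d, %d)", x$stage1_span[1], x$stage1_span[2]))
  if (!is.null(x$stage2_span))
    cat(sprintf("  stage 2: [%d, %d)", x$stage2_span[1], x$stage2_span[2]))
  cat("\n")
  invisible(x)
}

#' Write / read a CTG record as CSV channels plus a JSON sidecar
#'
#' `write_record()` writes `<path>_fhr.csv` and `<path>_ucp.csv`, each a
#' two-column `time_s,value` table, and `<path>.json` holding the sample
#' rate, validity mask (as 0-based indices of invalid samples), stage spans
#' and metadata. `read_record()` reverses this; a write/read round trip
#' reproduces the record exactly.
#'
#' @param record A [ctg_record()].
#' @param path File-path prefix (no extension).
#' @return `write_record()` returns `path` invisibly; `read_record()`
#'   returns a [ctg_record()].
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ctg_record"))
  n <- length(record$fhr)
  t_s <- (seq_len(n) - 1L) / record$sample_rate
  # %.17g keeps doubles bit-exact through the text round trip
  chan <- function(v, file) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines("time_s,value", con)
    writeLines(sprintf("%.17g,%.17g", t_s, v), con)
  }
  chan(record$fhr, paste0(path, "_fhr.csv"))
  chan(record$ucp, paste0(path, "_ucp.csv"))
  side <- list(id = record$id,
               sample_rate = record$sample_rate,
               n_samples = n,
               invalid_idx = which(!record$mask) - 1L,
               stage1_span = record$stage1_span,
               stage2_span = record$stage2_span,
               meta = unclass(record$meta))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  side_file <- paste0(path, ".json")
  if (!file.exists(side_file))
    stop("sidecar not found: ", side_file, call. = FALSE)
  side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
  for (f in c("sample_rate", "n_samples", "stage1_span", "meta"))
    if (is.null(side[[f]]))
      stop("malformed sidecar: missing field '", f, "'", call. = FALSE)
  rd <- function(file) {
    x <- utils::read.csv(file, colClasses = "numeric")
    if (!identical(names(x), c("time_s", "value")))
      stop("malformed channel file '", file,
           "': expected columns time_s,value", call. = FALSE)
    x$value
  }
  fhr <- rd(paste0(path, "_fhr.csv"))
  ucp <- rd(paste0(path, "_ucp.csv"))
  if (length(fhr) != side$n_samples || length(ucp) != side$n_samples)
    stop("channel length mismatch: sidecar declares ", side$n_samples,
         " samples but fhr has ", length(fhr), " and ucp has ", length(ucp),
         call. = FALSE)
  mask <- rep(TRUE, side$n_samples)
  if (length(side$invalid_idx)) mask[side$invalid_idx + 1L] <- FALSE
  m <- side$meta
  meta <- ctg_meta(ph = null_na(m$ph), be = null_na(m$be),
                   bdecf = null_na(m$bdecf), apgar = null_na(m$apgar),
                   gestation_weeks = null_na(m$gestation_weeks),
                   maternal_age = null_na(m$maternal_age),
                   delivery = if (is.null(m$delivery)) "vaginal" else m$delivery,
                   end_to_birth_min = null_na(m$end_to_birth_min))
  s2 <- side$stage2_span
  if (!is.null(s2) && !length(s2)) s2 <- NULL
  ctg_record(fhr, ucp, mask, side$sample_rate,
             stage1_span = side$stage1_span, stage2_span = s2,
             meta = meta, id = side$id)
}

null_na <- function(x) if (is.null(x) || !length(x)) NA_real_ else x

#' Per-stage signal-quality report
#'
#' Computes the percentage of missing (masked-invalid) samples inside the
#' stage-1 window, the stage-2 window (when present) and over the whole
#' record. "Noisy" and "missing" signal are both carried by the validity
#' mask and are therefore reported together.
#'
#' @param record A [ctg_record()].
#' @return A list of class `ctg_quality` with elements `window1_missing_pct`,
#'   `window2_missing_pct` (NA when no stage-2 span) and
#'   `overall_missing_pct`, each in \eqn{[0, 100]}.
#' @export
quality_windows <- function(record) {
  stopifnot(inherits(record, "ctg_record"))
  pct <- function(span) {
    if (span[2] - span[1] <= 0) stop("undefined quality window: empty span",
                                     call. = FALSE)
    100 * mean(!record$mask[span_idx(span)])
  }
  out <- list(window1_missing_pct = pct(record$stage1_span),
              window2_missing_pct = if (is.null(record$stage2_span))
                NA_real_ else pct(record$stage2_span),
              overall_missing_pct = 100 * mean(!record$mask))
  class(out) <- "ctg_quality"
  out
}

#' Apply record-selection rules
#'
#' Decides whether a record enters the analysis cohort. A record is included
#' iff all of the following hold: the stage-1 duration Td meets the
#' pH-dependent minimum (pH <= 7.15 requires Td >= 30 min; pH > 7.15
#' requires Td >= 40 min, both inclusive); the interval from signal end to
#' birth is under 30 min; stage-1 missing signal is at most 50%; gestational
#' age exceeds 36 weeks; and maternal age is at least 18. Stage-1 analysis
#' is additionally truncated to its final 60 minutes (see
#' [truncate_stage1()]); the duration test uses the recorded (wall-clock)
#' stage-1 length.
#'
#' @param record A [ctg_record()].
#' @return A list with `included` (logical) and `reasons` (character vector
#'   naming every violated rule; empty when included).
#' @export
select_record <- function(record) {
  stopifnot(inherits(record, "ctg_record"))
  meta <- record$meta
  if (is.na(meta$ph))
    stop("record ", record$id,
         " cannot be evaluated for selection: umbilical pH is missing",
         call. = FALSE)
  td_min <- (record$stage1_span[2] - record$stage1_span[1]) /
    record$sample_rate / 60
  reasons <- character()
  if (meta$ph <= 7.15) {
    if (td_min < 30) reasons <- c(reasons, "Td<30 for pH<=7.15")
  } else {
    if (td_min < 40) reasons <- c(reasons, "Td<40 for pH>7.15")
  }
  if (is.na(meta$end_to_birth_min) || meta$end_to_birth_min >= 30)
    reasons <- c(reasons, "end-to-birth>=30min")
  q <- quality_windows(record)
  if (q$window1_missing_pct > 50) reasons <- c(reasons, "missing>50%")
  if (is.na(meta$gestation_weeks) || meta$gestation_weeks <= 36)
    reasons <- c(reasons, "gestation<=36wk")
  if (is.na(meta$maternal_age) || meta$maternal_age < 18)
    reasons <- c(reasons, "maternal_age<18")
  list(included = length(reasons) == 0L, reasons = reasons)
}

#' Truncate the stage-1 span to its final 60 minutes
#'
#' First-stage analysis is restricted to at most 60 minutes; when the
#' recorded stage-1 span is longer, the span is replaced by its last 60
#' minutes (the portion closest to the second stage).
#'
#' @param record A [ctg_record()].
#' @return The record, with `stage1_span` possibly shortened.
#' @export
truncate_stage1 <- function(record) {
  stopifnot(inherits(record, "ctg_record"))
  max_samp <- as.integer(60 * 60 * record$sample_rate)
  len <- record$stage1_span[2] - record$stage1_span[1]
  if (len > max_samp)
    record$stage1_span <- c(record$stage1_span[2] - max_samp,
                            record$stage1_span[2])
  record
}
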