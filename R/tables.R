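#' Serialize feature tables and event logs
#'
#' `write_feature_table()`/`read_feature_table()` round-trip the 11-feature
#' table as CSV. `write_event_log()`/`read_event_log()` store an event log
#' as a BED-like TSV (`id`, `start_s`, `end_s`, `kind`, `type`,
#' `amplitude`, `membership`), with times in seconds.
#'
#' @param features Feature data frame.
#' @param events A `ctg_events` data frame.
#' @param sample_rate Hz, to convert sample indices to seconds.
#' @param id Record identifier written with each event row.
#' @param path Output file.
#' @name ctg_serialize
#' @return Readers return data frames; writers return `path` invisibly.
NULL

#' @rdname ctg_serialize
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ctg_serialize
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname ctg_serialize
#' @export
write_event_log <- function(events, path, sample_rate = 4, id = "record") {
  df <- data.frame(id = id,
                   start_s = (events$start - 1) / sample_rate,
                   end_s = events$end / sample_rate,
                   kind = events$kind, type = events$type,
                   amplitude = events$amplitude,
                   membership = events$membership)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname ctg_serialize
#' @export
read_event_log <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Reference stage-1 contingency tables
#'
#' The published 3x3 actual-vs-predicted contingency tables of the four
#' classifiers on a 399-record stage-1 CTG study (the worked reference for
#' the evaluation battery). Shipped as plain CSV in `inst/extdata`.
#'
#' @return A named list of four `ctg_confusion` matrices (`mlp`, `rf`,
#'   `svm`, `bagging`).
#' @export
stage1_contingency_tables <- function() {
  path <- system.file("extdata", "stage1_contingency.csv",
                      package = "ctgkit", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$classifier), function(d) {
    m <- matrix(0L, 3, 3)
    m[cbind(d$actual, d$predicted)] <- d$count
    as_confusion(m)
  })
  out[c("mlp", "rf", "svm", "bagging")]
}
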