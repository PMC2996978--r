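#' Read a clinical annotation table
#'
#' Reads a tab-delimited table with named columns for the sample identifier,
#' survival time (years), event indicator (1 = event, 0 = censored) and
#' estrogen-receptor status. Column names are matched case-insensitively:
#' `sample`/`sample_id`/`id`, `time`/`survival_time`/`years`,
#' `event`/`status`, `er`/`er_status`. ER values `ER+`/`positive`/`pos`/`1`
#' map to `"positive"`, `ER-`/`negative`/`neg`/`0` to `"negative"`, anything
#' else (including an empty cell) to `"unknown"`. An ER column is optional;
#' without one every sample is `"unknown"`.
#'
#' When `expression` is supplied the rows are aligned to the matrix sample
#' order by identifier, not file order: table rows naming samples absent from
#' the matrix are dropped with a warning, and matrix samples absent from the
#' table get `NA` time/event and `er_status = "unknown"` (they are excluded
#' from survival analysis downstream).
#'
#' @param path path to the TSV file.
#' @param expression optional [expr_matrix()] to align against.
#' @return A data frame of class `clinical_table` with columns `sample_id`,
#'   `time`, `event`, `er_status`.
#' @export
read_clinical <- function(path, expression = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(trimws(names(raw)))
  pick <- function(patterns, required = TRUE, what = "") {
    hit <- which(nm %in% patterns)
    if (!length(hit)) {
      if (required) stop("no column for ", what, " found (looked for: ",
                         paste(patterns, collapse = ", "), ")")
      return(NA_integer_)
    }
    hit[1L]
  }
  ci <- pick(c("sample", "sample_id", "sampleid", "id"), what = "sample ID")
  ti <- pick(c("time", "survival_time", "time_years", "years"), what = "survival time")
  ei <- pick(c("event", "status"), what = "event indicator")
  ri <- pick(c("er", "er_status", "erstatus"), required = FALSE)

  sample_id <- as.character(raw[[ci]])
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup)) stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
  time <- suppressWarnings(as.numeric(raw[[ti]]))
  bad <- which(!is.na(time) & time < 0)
  if (length(bad)) stop("negative survival time at row ", bad[1L])
  event <- suppressWarnings(as.numeric(raw[[ei]]))
  bad <- which(!is.na(event) & !(event %in% c(0, 1)))
  if (length(bad)) stop("non-binary event indicator at row ", bad[1L])

  er <- if (is.na(ri)) rep("", nrow(raw)) else as.character(raw[[ri]])
  er_status <- .map_er(er)

  out <- data.frame(sample_id = sample_id, time = time,
                    event = as.integer(event), er_status = er_status,
                    stringsAsFactors = FALSE)
  if (!is.null(expression)) out <- align_clinical(out, expression)
  class(out) <- c("clinical_table", "data.frame")
  out
}

.map_er <- function(er) {
  key <- toupper(trimws(er))
  key[is.na(er)] <- ""
  out <- rep("unknown", length(key))
  out[key %in% c("ER+", "POSITIVE", "POS", "1", "+")] <- "positive"
  out[key %in% c("ER-", "NEGATIVE", "NEG", "0", "-")] <- "negative"
  out
}

#' Align a clinical table to the samples of an expression matrix
#'
#' @param clinical a `clinical_table` (or compatible data frame).
#' @param expression an [expr_matrix()].
#' @return A `clinical_table` with one row per matrix sample, in matrix
#'   column order.
#' @export
align_clinical <- function(clinical, expression) {
  ids <- sample_ids(expression)
  extra <- setdiff(clinical$sample_id, ids)
  if (length(extra))
    warning("dropping clinical row(s) for sample(s) not in the matrix: ",
            paste(extra, collapse = ", "))
  idx <- match(ids, clinical$sample_id)
  out <- data.frame(sample_id = ids,
                    time = clinical$time[idx],
                    event = clinical$event[idx],
                    er_status = ifelse(is.na(idx), "unknown", clinical$er_status[idx]),
                    stringsAsFactors = FALSE)
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Write a clinical table as TSV
#' @param clinical a `clinical_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
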