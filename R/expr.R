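#' Expression matrix container
#'
#' A light container for a probes x samples expression matrix: a numeric
#' matrix with probe identifiers as row names and sample identifiers as
#' column names, plus an optional probe -> gene-symbol annotation. Values may
#' contain `NA` before imputation; [impute_knn()] completes the matrix.
#'
#' @param values numeric matrix, probes in rows, samples in columns; both
#'   dimnames set and unique.
#' @param symbols optional named character vector mapping probe IDs to gene
#'   symbols; unnamed probes are treated as unannotated.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `symbols`.
#' @export
expr_matrix <- function(values, symbols = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry probe row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate probe ID(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(symbols)) {
    symbols <- as.character(symbols)
    if (is.null(names(symbols)) && length(symbols) == nrow(values))
      names(symbols) <- rownames(values)
  }
  structure(list(values = values, symbols = symbols), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples; %d missing value(s)%s\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              if (is.null(x$symbols)) "" else "; symbol annotation attached"))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

.missing_tokens <- c("", "na", "nan", "null")

.strip_quotes <- function(x) {
  q <- startsWith(x, "\"") & endsWith(x, "\"") & nchar(x) >= 2L
  x[q] <- substr(x[q], 2L, nchar(x[q]) - 1L)
  x
}

#' Read an expression matrix from text
#'
#' Reads a tab-delimited probes x samples table: first column probe IDs,
#' header row sample IDs. The `series_matrix` dialect additionally skips the
#' "!"-prefixed metadata lines (including the table begin/end markers) that
#' GEO series-matrix exports carry, and strips surrounding double quotes from
#' identifiers. Empty cells and the tokens `NA`, `NaN`, `null`
#' (case-insensitive), as well as any non-numeric cell, become missing
#' values.
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"series_matrix"`.
#' @return An [expr_matrix()] with rows in file order.
#' @export
read_expression <- function(path, dialect = c("tsv", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  if (dialect == "series_matrix") {
    keep <- !startsWith(lines, "!")
    lines <- lines[keep]; lineno <- lineno[keep]
  }
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) < 2L) stop("no table found in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(parts[[1L]])
  bad <- which(lengths(parts) != width)
  if (length(bad))
    stop(sprintf("ragged row: line %d has %d field(s), expected %d",
                 lineno[bad[1L]], lengths(parts)[bad[1L]], width))
  samples <- .strip_quotes(parts[[1L]][-1L])
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
  body <- parts[-1L]
  probes <- .strip_quotes(vapply(body, `[[`, "", 1L))
  dup <- probes[duplicated(probes)]
  if (length(dup)) stop("duplicate probe ID(s): ", paste(unique(dup), collapse = ", "))
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  vals[tolower(trimws(cells)) %in% .missing_tokens] <- NA_real_
  m <- matrix(vals, nrow = length(body), ncol = width - 1L, byrow = TRUE,
              dimnames = list(probes, samples))
  expr_matrix(m)
}

#' Write an expression matrix as TSV
#'
#' Full-precision output (`%.17g`): `read_expression()` on the result
#' recovers the numeric content exactly. Missing entries are written as `NA`.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  fmt <- function(z) {
    out <- sprintf("%.17g", z)
    out[is.na(z)] <- "NA"
    out
  }
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], fmt(v[i, ])), collapse = "\t"), "")
  writeLines(c(paste(c("probe_id", colnames(v)), collapse = "\t"), rows), path)
  invisible(path)
}

#' k-nearest-neighbour imputation of missing expression values
#'
#' Each missing entry (g, j) is replaced by the mean of the column-j values
#' of the k nearest probe rows that observe column j. Distance between two
#' rows is the root mean squared difference over the coordinates observed in
#' both (Euclidean distance normalised by the number of shared coordinates),
#' so rows with different missingness patterns are comparable. Fully observed
#' rows are returned unchanged; a matrix with no missing entries is returned
#' bitwise identical.
#'
#' @param x an `expr_matrix`, possibly with missing entries.
#' @param k number of donor rows (default 10).
#' @return An `expr_matrix` with no missing entries.
#' @export
impute_knn <- function(x, k = 10L) {
  stopifnot(inherits(x, "expr_matrix"))
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  v <- x$values
  miss <- is.na(v)
  if (!any(miss)) return(x)
  if (any(colSums(!miss) == 0L))
    stop("column(s) missing in all rows: ",
         paste(colnames(v)[colSums(!miss) == 0L], collapse = ", "))
  if (any(rowSums(!miss) == 0L))
    stop("probe row(s) with no observed value: ",
         paste(rownames(v)[rowSums(!miss) == 0L], collapse = ", "))
  out <- v
  short <- 0L
  for (g in which(rowSums(miss) > 0L)) {
    d <- .row_distances(v, miss, g)
    for (j in which(miss[g, ])) {
      donors <- which(!miss[, j] & is.finite(d))
      if (!length(donors)) stop("no donor row observes column ", colnames(v)[j])
      donors <- donors[order(d[donors], donors)]
      if (length(donors) < k) short <- short + 1L
      use <- donors[seq_len(min(k, length(donors)))]
      out[g, j] <- mean(v[use, j])
    }
  }
  if (short > 0L)
    warning(sprintf("fewer than k = %d donor rows available for %d missing entr%s; used all donors",
                    k, short, if (short == 1L) "y" else "ies"))
  expr_matrix(out, x$symbols)
}

# RMS distance from row g to every row, over shared observed coordinates.
.row_distances <- function(v, miss, g) {
  obs_g <- !miss[g, ]
  diffs <- sweep(v[, obs_g, drop = FALSE], 2L, v[g, obs_g], "-")
  shared <- rowSums(!is.na(diffs))
  d <- sqrt(rowSums(diffs^2, na.rm = TRUE) / shared)
  d[shared == 0L] <- Inf
  d[g] <- Inf
  d
}
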