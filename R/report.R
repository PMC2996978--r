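#' Write / read enumeration instances as TSV
#'
#' One row per instance: cell label, s, t, direction, comma-separated probe
#' list, comma-separated consensus sample IDs. `read_instances()` parses the
#' file back losslessly (sample IDs are resolved against `sample_ids`).
#'
#' @param enum a `gene_set_enumeration` (or plain instance list).
#' @param path output path.
#' @param sample_ids sample identifiers used to render consensus indices.
#' @return `path`, invisibly.
#' @export
write_instances <- function(enum, path, sample_ids = NULL) {
  inst <- if (inherits(enum, "gene_set_enumeration")) enum$instances else enum
  rows <- vapply(inst, function(z) {
    cons <- if (is.null(sample_ids)) as.character(z$consensus_samples)
            else sample_ids[z$consensus_samples]
    paste(c(z$cell, z$s, z$t, z$direction,
            paste(z$probes, collapse = ","),
            paste(cons, collapse = ",")), collapse = "\t")
  }, "")
  writeLines(c("cell\ts\tt\tdirection\tprobes\tconsensus_samples", rows), path)
  invisible(path)
}

#' @rdname write_instances
#' @param sample_ids for `read_instances`, the sample-ID vector of the
#'   matrix the run used; consensus IDs are mapped back to indices when
#'   supplied.
#' @export
read_instances <- function(path, sample_ids = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    cons <- strsplit(df$consensus_samples[i], ",", fixed = TRUE)[[1L]]
    cons <- if (is.null(sample_ids)) as.integer(cons)
            else match(cons, sample_ids)
    structure(list(s = df$s[i], t = df$t[i],
                   probes = strsplit(df$probes[i], ",", fixed = TRUE)[[1L]],
                   consensus_samples = sort.int(cons),
                   cell = df$cell[i], direction = df$direction[i]),
              class = "gene_set_instance")
  })
}

#' Write consolidated families as TSV
#'
#' @param families a `gene_set_families` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_families <- function(families, path) {
  rows <- vapply(families$families, function(f) {
    syms <- if (is.null(families$symbols)) ""
            else paste(.symbol_set(f$core_probes, families$symbols), collapse = ",")
    paste(c(f$family_id, f$label, length(f$instances),
            paste(vapply(f$instances, `[[`, "", "cell"), collapse = ","),
            paste(f$core_probes, collapse = ","), syms,
            ifelse(is.na(f$artifact_flag), "NA", f$artifact_flag)),
          collapse = "\t")
  }, "")
  writeLines(c("family_id\tlabel\tn_instances\tcells\tcore_probes\tsymbols\tartifact_flag",
               rows), path)
  invisible(path)
}

#' Write survival results as TSV
#'
#' One row per evaluation with a significance flag at p <= 0.05; p-values
#' are written at full precision.
#'
#' @param results a `survival_eval` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(results, path) {
  out <- as.data.frame(results)
  if (is.null(out$significant)) out$significant <- !is.na(out$p) & out$p <= 0.05
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Red-green heatmap of a gene-set family
#'
#' Draws the family's core probes with columns ordered by the set's
#' column-sum score and expression mapped to a green (low) - black - red
#' (high) continuum. When clinical data are supplied, event markers are
#' drawn under the columns of samples with an observed event.
#'
#' @param x a `gene_set_families` object.
#' @param expression the [expr_matrix()] the enumeration was run on.
#' @param family index of the family to draw (default 1).
#' @param clinical optional `clinical_table` for event markers.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the column order used.
#' @export
plot.gene_set_families <- function(x, expression, family = 1L,
                                   clinical = NULL, ...) {
  f <- x$families[[family]]
  if (!length(f$core_probes)) stop("family ", family, " has an empty core")
  score <- column_sum_score(expression, f$core_probes)
  ord <- order(score)
  v <- expression$values[f$core_probes, ord, drop = FALSE]
  pal <- grDevices::colorRampPalette(c("green", "black", "red"))(63)
  lim <- max(abs(v - mean(v)))
  graphics::image(x = seq_len(ncol(v)), y = seq_len(nrow(v)),
                  z = t(v), col = pal,
                  zlim = mean(v) + c(-lim, lim),
                  xlab = "samples (ordered by column sum)", ylab = "",
                  yaxt = "n", main = sprintf("family %d '%s'", f$family_id, f$label),
                  ...)
  graphics::axis(2, at = seq_len(nrow(v)), labels = rownames(v),
                 las = 2, cex.axis = 0.6)
  if (!is.null(clinical)) {
    cl <- align_clinical(clinical, expression)
    ev <- which(!is.na(cl$event[ord]) & cl$event[ord] == 1L)
    if (length(ev))
      graphics::points(ev, rep(0.4, length(ev)), pch = 17, cex = 0.5,
                       xpd = NA)
  }
  invisible(ord)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-identically: package
#' version, seed, configuration echo, input checksums (md5), per-cell
#' instance counts and wall-clock timing.
#'
#' @param path output JSON path.
#' @param config named list of configuration objects.
#' @param inputs named character vector of input file paths to checksum.
#' @param seed integer seed (NA if the run is deterministic).
#' @param cells optional data frame of per-cell instance counts.
#' @param elapsed elapsed seconds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), inputs = character(),
                           seed = NA_integer_, cells = NULL, elapsed = NA_real_) {
  strip <- function(z) if (is.list(z)) lapply(unclass(z), strip) else z
  manifest <- list(
    tool = "ranksets",
    version = as.character(utils::packageVersion("ranksets")),
    seed = seed,
    config = lapply(config, strip),
    input_md5 = as.list(tools::md5sum(inputs)),
    cells = cells,
    elapsed_seconds = elapsed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
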