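#' Consolidation configuration
#'
#' @param jaccard_threshold minimum probe-set Jaccard similarity for two
#'   instances to be linked into one family (default 0.5).
#' @param core_fraction fraction of a family's instances a probe must appear
#'   in to enter the core set (default 0.5: "at least half").
#' @return A list of class `consolidation_config`.
#' @export
consolidation_config <- function(jaccard_threshold = 0.5, core_fraction = 0.5) {
  if (jaccard_threshold <= 0 || jaccard_threshold > 1)
    stop("'jaccard_threshold' must be in (0, 1]")
  if (core_fraction <= 0 || core_fraction > 1)
    stop("'core_fraction' must be in (0, 1]")
  structure(list(jaccard_threshold = jaccard_threshold,
                 core_fraction = core_fraction),
            class = "consolidation_config")
}

#' Link gene-set instances across grid cells into families
#'
#' The grid typically detects many versions of the same underlying gene set,
#' differing marginally in gene composition between neighbouring (s, t)
#' cells; a "gene set" is therefore a set of sets. Instances are linked by
#' single-linkage on probe-set Jaccard similarity at or above the threshold,
#' so each instance lands in exactly one family.
#'
#' @param instances list of `gene_set_instance` objects (one enumeration
#'   run), or a `gene_set_enumeration`.
#' @param cfg a [consolidation_config()].
#' @return List of families, each a list of member instances, ordered by
#'   descending instance count then smallest probe ID.
#' @export
link_instances <- function(instances, cfg = consolidation_config()) {
  if (inherits(instances, "gene_set_enumeration")) instances <- instances$instances
  if (!length(instances)) return(list())
  universe <- sort(unique(unlist(lapply(instances, `[[`, "probes"))))
  ni <- length(instances)
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(ni), vapply(instances, function(z) length(z$probes), 0L)),
    j = match(unlist(lapply(instances, `[[`, "probes")), universe),
    x = 1, dims = c(ni, length(universe)))
  ov <- Matrix::tcrossprod(inc)
  tri <- Matrix::summary(ov)
  tri <- tri[tri$i < tri$j, , drop = FALSE]
  sizes <- Matrix::rowSums(inc)
  jac <- tri$x / (sizes[tri$i] + sizes[tri$j] - tri$x)
  sel <- jac >= cfg$jaccard_threshold
  g <- igraph::make_graph(rbind(tri$i[sel], tri$j[sel]), n = ni, directed = FALSE)
  memb <- igraph::components(g)$membership
  fams <- split(seq_len(ni), memb)
  fams <- lapply(fams, function(ix) instances[ix])
  min_probe <- vapply(fams, function(f)
    min(unlist(lapply(f, `[[`, "probes"))), "")
  fams <- fams[order(-lengths(fams), min_probe)]
  names(fams) <- NULL
  fams
}

#' Core probe set of a family ("squashing")
#'
#' Summarises the family's versions into a single list: the probes that
#' appear in at least `core_fraction` of the member instances (by default at
#' least half), in ascending probe-ID order. The core can be empty for
#' fragmented families; such families are kept but flagged and excluded from
#' survival analysis.
#'
#' @param instances list of member `gene_set_instance`s (or a family object).
#' @param cfg a [consolidation_config()].
#' @return Character vector of core probe IDs (possibly empty).
#' @export
core_set <- function(instances, cfg = consolidation_config()) {
  if (inherits(instances, "gene_set_family")) instances <- instances$instances
  counts <- table(unlist(lapply(instances, `[[`, "probes")))
  need <- ceiling(cfg$core_fraction * length(instances))
  sort(names(counts)[counts >= need])
}

#' Flag families that are artefacts of the chip design
#'
#' A pattern realised exclusively by probes that all spot the same gene adds
#' no co-regulation evidence; such single-gene families are kept but marked.
#'
#' @param family a `gene_set_family`, or a character vector of core probes.
#' @param symbols named character vector mapping probe IDs to gene symbols.
#' @return `TRUE` iff every core probe maps to one common non-empty symbol;
#'   `NA` (with a warning) when no annotation is available. A probe without
#'   a symbol counts as a distinct unknown gene.
#' @export
flag_single_gene_artifact <- function(family, symbols) {
  core <- if (inherits(family, "gene_set_family")) family$core_probes else family
  if (is.null(symbols) || !length(symbols)) {
    warning("no symbol annotation available; artifact flag not set")
    return(NA)
  }
  if (!length(core)) return(FALSE)
  sym <- symbols[core]
  if (anyNA(sym) || any(!nzchar(sym))) return(FALSE)
  length(unique(sym)) == 1L
}

.family_label <- function(core, symbols) {
  if (!length(core)) return("")
  if (!is.null(symbols)) {
    sym <- symbols[core]
    sym <- sym[!is.na(sym) & nzchar(sym)]
    if (length(sym)) {
      tab <- sort(table(sym), decreasing = TRUE)
      return(names(tab)[[1L]])
    }
  }
  core[[1L]]
}

#' Consolidate an enumeration into gene-set families
#'
#' Links instances into families ([link_instances()]), squashes each family
#' into its core probe set ([core_set()]), attaches an auto-label (most
#' frequent core gene symbol), the chip-design artifact flag, and a
#' representative sample set (samples present in at least half of the member
#' instances' consensus sets).
#'
#' @param enum a `gene_set_enumeration` (or plain instance list).
#' @param cfg a [consolidation_config()].
#' @param symbols optional probe -> symbol map; defaults to the annotation
#'   carried by the matrix the enumeration was run on, if supplied there.
#' @return An object of class `gene_set_families`: list with `families`
#'   (each a `gene_set_family` with `family_id`, `instances`, `core_probes`,
#'   `label`, `artifact_flag`, `representative_samples`) and `config`.
#' @export
consolidate <- function(enum, cfg = consolidation_config(), symbols = NULL) {
  fams <- link_instances(enum, cfg)
  families <- lapply(seq_along(fams), function(i) {
    inst <- fams[[i]]
    core <- core_set(inst, cfg)
    flag <- if (is.null(symbols)) NA else {
      if (length(core)) flag_single_gene_artifact(core, symbols) else FALSE
    }
    cons <- table(unlist(lapply(inst, `[[`, "consensus_samples")))
    rep_samples <- sort(as.integer(names(cons)[cons >= length(inst) / 2]))
    structure(list(family_id = i, instances = inst, core_probes = core,
                   label = .family_label(core, symbols),
                   artifact_flag = flag,
                   empty_core = length(core) == 0L,
                   representative_samples = rep_samples),
              class = "gene_set_family")
  })
  structure(list(families = families, config = cfg, symbols = symbols),
            class = "gene_set_families")
}

#' @export
print.gene_set_family <- function(x, ...) {
  cat(sprintf("gene_set_family %d '%s': %d instance(s), core of %d probe(s)%s\n",
              x$family_id, x$label, length(x$instances),
              length(x$core_probes),
              if (isTRUE(x$artifact_flag)) " [single-gene artifact]" else ""))
  invisible(x)
}

#' @export
print.gene_set_families <- function(x, ...) {
  cat(sprintf("gene_set_families: %d family(ies)\n", length(x$families)))
  for (f in utils::head(x$families, 20L)) print(f)
  if (length(x$families) > 20L) cat("...\n")
  invisible(x)
}

#' @export
summary.gene_set_families <- function(object, ...) {
  df <- data.frame(
    family_id = vapply(object$families, `[[`, 0L, "family_id"),
    label = vapply(object$families, `[[`, "", "label"),
    n_instances = vapply(object$families, function(f) length(f$instances), 0L),
    core_size = vapply(object$families, function(f) length(f$core_probes), 0L),
    artifact = vapply(object$families, function(f) isTRUE(f$artifact_flag), NA))
  df
}

.symbol_set <- function(core, symbols) {
  if (is.null(symbols)) return(unique(core))
  sym <- symbols[core]
  miss <- is.na(sym) | !nzchar(sym)
  unique(c(sym[!miss], core[miss]))
}

#' Align gene-set families across two datasets
#'
#' Matches families found in two independent enumerations (possibly on
#' different platforms) at the gene-symbol level: greedy one-to-one matching
#' on the Jaccard similarity of core symbol sets, highest similarity first
#' (ties by larger overlap count), keeping pairs at or above the threshold.
#'
#' @param fams_a,fams_b `gene_set_families` objects.
#' @param symbols_a,symbols_b probe -> symbol maps for the two datasets
#'   (default: the maps stored in the family objects).
#' @param threshold minimum symbol Jaccard (default 0.3).
#' @return A list of class `gene_set_alignment`: `matches` (data frame
#'   `family_a`, `family_b`, `jaccard`, `overlap`), `unmatched_a`,
#'   `unmatched_b` (family ids).
#' @export
compare_across_datasets <- function(fams_a, fams_b,
                                    symbols_a = fams_a$symbols,
                                    symbols_b = fams_b$symbols,
                                    threshold = 0.3) {
  sets_a <- lapply(fams_a$families, function(f) .symbol_set(f$core_probes, symbols_a))
  sets_b <- lapply(fams_b$families, function(f) .symbol_set(f$core_probes, symbols_b))
  cand <- list()
  for (i in seq_along(sets_a)) for (j in seq_along(sets_b)) {
    ov <- length(intersect(sets_a[[i]], sets_b[[j]]))
    if (!ov) next
    jac <- ov / length(union(sets_a[[i]], sets_b[[j]]))
    if (jac >= threshold)
      cand[[length(cand) + 1L]] <- data.frame(family_a = i, family_b = j,
                                              jaccard = jac, overlap = ov)
  }
  matches <- data.frame(family_a = integer(), family_b = integer(),
                        jaccard = numeric(), overlap = integer())
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$jaccard, -cand$overlap, cand$family_a, cand$family_b), ]
    used_a <- used_b <- integer()
    for (r in seq_len(nrow(cand))) {
      if (cand$family_a[r] %in% used_a || cand$family_b[r] %in% used_b) next
      matches <- rbind(matches, cand[r, ])
      used_a <- c(used_a, cand$family_a[r])
      used_b <- c(used_b, cand$family_b[r])
    }
    rownames(matches) <- NULL
  }
  structure(list(matches = matches,
                 unmatched_a = setdiff(seq_along(sets_a), matches$family_a),
                 unmatched_b = setdiff(seq_along(sets_b), matches$family_b)),
            class = "gene_set_alignment")
}

#' @export
print.gene_set_alignment <- function(x, ...) {
  cat(sprintf("gene_set_alignment: %d matched pair(s); %d / %d unmatched\n",
              nrow(x$matches), length(x$unmatched_a), length(x$unmatched_b)))
  if (nrow(x$matches)) print(x$matches)
  invisible(x)
}
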