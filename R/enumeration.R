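#' Grid-search configuration
#'
#' Controls the (s, t) grid: partition size s runs from a small margin
#' (6, alternatively 10) to n minus that margin, and for each s the
#' tolerance t runs from 0 (perfect match) up to a per-s ceiling — either
#' the sentinel stop rule ([sentinel_config()]) or, without a sentinel, a
#' fixed cap defaulting to `floor(s / 2)`.
#'
#' @param s_margin margin defining `s_min = s_margin` and
#'   `s_max = n - s_margin` (default 6; the common alternative is 10).
#' @param s_step step for s (default 1).
#' @param min_set_size smallest component reported as a gene set (default 6).
#' @param t_cap fixed tolerance ceiling used when no sentinel is configured;
#'   `NULL` (default) means `floor(s / 2)`.
#' @param sentinel optional [sentinel_config()].
#' @param direction match high-expression patterns (`"high"`, default), the
#'   low end (`"low"`), or both.
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(s_margin = 6L, s_step = 1L, min_set_size = 6L,
                        t_cap = NULL, sentinel = NULL,
                        direction = c("high", "low", "both")) {
  direction <- match.arg(direction)
  s_margin <- as.integer(s_margin); s_step <- as.integer(s_step)
  min_set_size <- as.integer(min_set_size)
  if (s_margin < 1L) stop("'s_margin' must be >= 1")
  if (s_step < 1L) stop("'s_step' must be >= 1")
  if (min_set_size < 2L) stop("'min_set_size' must be >= 2")
  if (!is.null(sentinel) && !inherits(sentinel, "sentinel_config"))
    stop("'sentinel' must be a sentinel_config()")
  structure(list(s_margin = s_margin, s_step = s_step,
                 min_set_size = min_set_size,
                 t_cap = if (is.null(t_cap)) NULL else as.integer(t_cap),
                 sentinel = sentinel, direction = direction),
            class = "grid_config")
}

#' Sentinel stop rule configuration
#'
#' The per-s tolerance ceiling is defined operationally: increment t from 0
#' until a designated sentinel gene set (e.g. an interferon set) stops being
#' a distinct object because it merges with designated foil probes (e.g.
#' other immune genes). `majority_fraction` tolerates sentinel probes that
#' fail to co-cluster: the sentinel component is the one holding at least
#' that fraction of the sentinel probes.
#'
#' @param sentinel_probes character vector of probe IDs to preserve.
#' @param foil_probes probe IDs the sentinel component must not contain.
#' @param majority_fraction fraction in (0, 1], default 0.5.
#' @return A list of class `sentinel_config`.
#' @export
sentinel_config <- function(sentinel_probes, foil_probes,
                            majority_fraction = 0.5) {
  if (length(intersect(sentinel_probes, foil_probes)))
    stop("sentinel and foil probe lists must be disjoint")
  if (majority_fraction <= 0 || majority_fraction > 1)
    stop("'majority_fraction' must be in (0, 1]")
  structure(list(sentinel_probes = as.character(sentinel_probes),
                 foil_probes = as.character(foil_probes),
                 majority_fraction = majority_fraction),
            class = "sentinel_config")
}

.t_cap <- function(cfg, s) {
  cap <- if (is.null(cfg$t_cap)) s %/% 2L else cfg$t_cap
  as.integer(min(cap, s - 1L))
}

# G x s matrix of top-s sample indices, row g in descending-expression order
# (ties by ascending sample index). direction "low" ranks ascending.
.top_index_matrix <- function(vals, s, direction = "high") {
  v <- if (direction == "low") -vals else vals
  n <- ncol(v)
  t(apply(v, 1L, function(r) order(-r, seq_len(n))[seq_len(s)]))
}

# sparse G x n incidence of top-s membership: the inverted index in matrix
# form; tcrossprod gives all pairwise overlap counts without touching pairs
# that share no sample.
.membership <- function(topidx, n) {
  G <- nrow(topidx); s <- ncol(topidx)
  Matrix::sparseMatrix(i = rep(seq_len(G), times = s),
                       j = as.vector(topidx),
                       x = 1, dims = c(G, n))
}

# off-diagonal overlap counts as a triplet data frame (i < j, count)
.overlap_pairs <- function(M) {
  ov <- Matrix::tcrossprod(M)
  tri <- Matrix::summary(ov)
  tri <- tri[tri$i < tri$j, , drop = FALSE]
  data.frame(i = tri$i, j = tri$j, x = tri$x)
}

# connected-component membership at threshold overlap >= s - t
.component_membership <- function(pairs, G, s, t) {
  sel <- pairs$x >= s - t
  g <- igraph::make_graph(rbind(pairs$i[sel], pairs$j[sel]),
                          n = G, directed = FALSE)
  igraph::components(g)$membership
}

#' Match-graph connected components of a set of top-s partitions
#'
#' Builds the undirected graph with an edge for every probe pair whose top-s
#' sample sets match at tolerance t, and returns its connected components —
#' the gene sets at one (s, t) grid cell, before the minimum-size filter.
#' Candidate pairs are generated through an inverted index (a sparse
#' sample-membership incidence matrix; only pairs sharing at least one
#' sample are scored), which returns exactly the same components as all-pairs
#' matching.
#'
#' @param partitions list of [induce_partition()] results sharing one s.
#' @param t tolerance.
#' @return List of components; each component is the sorted vector of its
#'   members' probe IDs (or 1-based list indices when IDs are absent or
#'   duplicated). Components are ordered by their smallest member.
#' @export
build_match_graph <- function(partitions, t) {
  if (!length(partitions)) return(list())
  s <- unique(vapply(partitions, `[[`, 0L, "s"))
  if (length(s) != 1L) stop("mixed partition sizes: ", paste(s, collapse = ", "))
  n <- max(vapply(partitions, function(p) max(p$samples), 0L))
  topidx <- do.call(rbind, lapply(partitions, `[[`, "samples"))
  pairs <- .overlap_pairs(.membership(topidx, n))
  memb <- .component_membership(pairs, length(partitions), s, t)
  ids <- vapply(partitions, function(p) as.character(p$probe_id), "")
  use_ids <- all(nzchar(ids)) && !anyDuplicated(ids)
  comps <- split(seq_along(partitions), memb)
  comps <- lapply(comps, function(ix) {
    if (use_ids) sort(ids[ix]) else sort(ix)
  })
  comps[order(unlist(lapply(comps, `[[`, 1L)))]
}

#' Consensus sample set of a component
#'
#' A gene set induces a single partition on the samples regardless of how
#' many genes it contains: the s samples most frequently present in the
#' members' top-s sets. Frequency ties are broken by the higher total rank
#' score (members' top-ranked samples score highest), then by ascending
#' sample index.
#'
#' @param component nonempty list of `top_sample_set`s sharing one s.
#' @return Sorted integer vector of s sample indices.
#' @export
consensus_samples <- function(component) {
  if (!length(component)) stop("empty component")
  s <- unique(vapply(component, `[[`, 0L, "s"))
  if (length(s) != 1L) stop("mixed partition sizes")
  rows <- do.call(rbind, lapply(component, `[[`, "rank_order"))
  n <- max(rows)
  .consensus_from_rows(rows, n)
}

.consensus_from_rows <- function(rows, n) {
  s <- ncol(rows)
  v <- as.vector(rows)                      # column k = rank position k
  w <- rep(s:1, each = nrow(rows))          # rank score s..1 by position
  freq <- tabulate(v, n)
  sc <- numeric(n)
  rs <- rowsum(w, v)
  sc[as.integer(rownames(rs))] <- rs
  sort.int(order(-freq, -sc, seq_len(n))[seq_len(s)])
}

.new_instance <- function(s, t, probes, consensus, direction) {
  structure(list(s = s, t = t, probes = probes,
                 consensus_samples = consensus,
                 cell = sprintf("%dt%d", s, t),
                 direction = direction),
            class = "gene_set_instance")
}

#' @export
print.gene_set_instance <- function(x, ...) {
  cat(sprintf("gene_set_instance %s: %d probes, consensus of %d samples\n",
              x$cell, length(x$probes), length(x$consensus_samples)))
  invisible(x)
}

#' Gene-set instances at one (s, t) grid cell
#'
#' Induces the top-s partition of every probe, forms the match-graph
#' components at tolerance t, drops components smaller than
#' `cfg$min_set_size`, and attaches each surviving component's consensus
#' sample set and a cell label of the form `"21t4"`.
#'
#' @param x an imputed [expr_matrix()].
#' @param s partition size.
#' @param t tolerance.
#' @param cfg a [grid_config()].
#' @return List of `gene_set_instance` objects, ordered by smallest probe ID.
#' @export
components_at <- function(x, s, t, cfg = grid_config()) {
  dir <- if (cfg$direction == "both") "high" else cfg$direction
  cell <- .grid_cell_state(x$values, s, dir)
  .instances_at(cell, t, cfg, rownames(x$values), dir)
}

.grid_cell_state <- function(vals, s, direction) {
  topidx <- .top_index_matrix(vals, s, direction)
  list(s = s, topidx = topidx,
       pairs = .overlap_pairs(.membership(topidx, ncol(vals))),
       n = ncol(vals), G = nrow(vals))
}

.instances_at <- function(cell, t, cfg, probes, direction) {
  memb <- .component_membership(cell$pairs, cell$G, cell$s, t)
  keep <- which(tabulate(memb) >= cfg$min_set_size)
  out <- lapply(keep, function(cid) {
    ix <- which(memb == cid)
    cons <- .consensus_from_rows(cell$topidx[ix, , drop = FALSE], cell$n)
    .new_instance(cell$s, t, sort(probes[ix]), cons, direction)
  })
  out[order(vapply(out, function(inst) inst$probes[[1L]], ""))]
}

# sentinel scan over one grid-cell state; returns largest admissible t
.t_max_sentinel <- function(cell, cfg, probes) {
  sen <- cfg$sentinel
  s_ix <- match(sen$sentinel_probes, probes)
  if (anyNA(s_ix))
    stop("sentinel probe(s) absent from matrix: ",
         paste(sen$sentinel_probes[is.na(s_ix)], collapse = ", "))
  f_ix <- match(sen$foil_probes, probes)
  f_ix <- f_ix[!is.na(f_ix)]
  last_good <- -1L
  for (t in 0:(cell$s - 1L)) {
    memb <- .component_membership(cell$pairs, cell$G, cell$s, t)
    counts <- table(memb[s_ix])
    host <- as.integer(names(counts)[which.max(counts)])
    if (max(counts) < sen$majority_fraction * length(s_ix)) break
    if (any(memb[f_ix] == host)) break
    last_good <- t
  }
  last_good
}

#' Largest admissible tolerance at a given partition size
#'
#' Applies the sentinel stop rule: the largest t at which the component
#' holding the majority of the sentinel probes still contains no foil probe.
#' Returns -1 when the sentinel has already merged (or dispersed) at t = 0.
#' Without a configured sentinel, returns the fixed cap
#' (`cfg$t_cap`, default `floor(s / 2)`).
#'
#' @inheritParams components_at
#' @return Integer tolerance ceiling.
#' @export
t_max_for_s <- function(x, s, cfg = grid_config()) {
  if (is.null(cfg$sentinel)) return(.t_cap(cfg, s))
  dir <- if (cfg$direction == "both") "high" else cfg$direction
  cell <- .grid_cell_state(x$values, s, dir)
  .t_max_sentinel(cell, cfg, rownames(x$values))
}

#' Enumerate all gene-set instances over the (s, t) grid
#'
#' The central fit: for every partition size s from `s_margin` to
#' `n - s_margin` (step `s_step`) and every tolerance t from 0 to the per-s
#' ceiling ([t_max_for_s()]), emits the gene-set instances found at that
#' cell. The result is deterministic — ascending s, then t, then smallest
#' probe ID — and two runs on identical input and configuration are
#' identical.
#'
#' @param x an imputed [expr_matrix()].
#' @param cfg a [grid_config()].
#' @param verbose log per-s progress to stderr.
#' @return An object of class `gene_set_enumeration`: list with `instances`
#'   (list of `gene_set_instance`), `cells` (data frame of visited cells and
#'   instance counts), `config`, `n`, and `call`.
#' @export
enumerate_gene_sets <- function(x, cfg = grid_config(), verbose = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (anyNA(x$values)) stop("matrix has missing values; run impute_knn() first")
  n <- ncol(x$values)
  probes <- rownames(x$values)
  s_min <- cfg$s_margin
  s_max <- n - cfg$s_margin
  if (s_max < s_min) stop("too few samples for s_margin = ", cfg$s_margin)
  dirs <- if (cfg$direction == "both") c("high", "low") else cfg$direction
  instances <- list()
  cells <- list()
  for (dir in dirs) {
    for (s in seq.int(s_min, s_max, by = cfg$s_step)) {
      cell <- .grid_cell_state(x$values, s, dir)
      tmax <- if (is.null(cfg$sentinel)) .t_cap(cfg, s)
              else .t_max_sentinel(cell, cfg, probes)
      count_s <- 0L
      if (tmax >= 0L) for (t in 0:tmax) {
        inst <- .instances_at(cell, t, cfg, probes, dir)
        count_s <- count_s + length(inst)
        instances <- c(instances, inst)
        cells[[length(cells) + 1L]] <-
          data.frame(s = s, t = t, direction = dir, n_instances = length(inst))
      }
      if (verbose)
        message(sprintf("s = %d (%s): t <= %d, %d instance(s)",
                        s, dir, tmax, count_s))
    }
  }
  structure(list(instances = instances,
                 cells = if (length(cells)) do.call(rbind, cells)
                         else data.frame(s = integer(), t = integer(),
                                         direction = character(),
                                         n_instances = integer()),
                 config = cfg, n = n, probes = probes,
                 call = match.call()),
            class = "gene_set_enumeration")
}

#' @rdname enumerate_gene_sets
#' @export
enumerate_grid <- enumerate_gene_sets

#' @export
print.gene_set_enumeration <- function(x, ...) {
  cat(sprintf("gene_set_enumeration: %d instance(s) over %d grid cell(s), n = %d samples\n",
              length(x$instances), nrow(x$cells), x$n))
  invisible(x)
}

#' @export
summary.gene_set_enumeration <- function(object, ...) {
  sizes <- vapply(object$instances, function(i) length(i$probes), 0L)
  cat(sprintf("%d instance(s) in %d non-empty cell(s) of %d visited\n",
              length(object$instances), sum(object$cells$n_instances > 0),
              nrow(object$cells)))
  if (length(sizes)) {
    cat("instance sizes:\n"); print(summary(sizes))
  }
  invisible(object)
}

#' Coarse-to-fine reconnaissance of the (s, t) grid
#'
#' Steps s and t in large increments until gene sets are found, then refines
#' around each hit in unit steps. Used for scouting where the productive
#' band of the grid lies; the full enumeration does not depend on it. With
#' both coarse steps equal to 1 the scan is exhaustive.
#'
#' @inheritParams enumerate_gene_sets
#' @param coarse_s_step,coarse_t_step coarse increments (>= 1).
#' @return Data frame of non-empty refined cells (`s`, `t`, `n_instances`),
#'   sorted by s then t.
#' @export
spiral_search <- function(x, cfg = grid_config(), coarse_s_step = 5L,
                          coarse_t_step = 2L) {
  stopifnot(coarse_s_step >= 1L, coarse_t_step >= 1L)
  n <- ncol(x$values)
  probes <- rownames(x$values)
  dir <- if (cfg$direction == "both") "high" else cfg$direction
  s_min <- cfg$s_margin; s_max <- n - cfg$s_margin
  cache_cells <- new.env(parent = emptyenv())
  cache_state <- new.env(parent = emptyenv())
  count_at <- function(s, t) {
    key <- sprintf("%d.%d", s, t)
    if (!is.null(cache_cells[[key]])) return(cache_cells[[key]])
    skey <- as.character(s)
    if (is.null(cache_state[[skey]]))
      cache_state[[skey]] <- .grid_cell_state(x$values, s, dir)
    k <- length(.instances_at(cache_state[[skey]], t, cfg, probes, dir))
    cache_cells[[key]] <- k
    k
  }
  hits <- list()
  for (s in seq.int(s_min, s_max, by = coarse_s_step))
    for (t in seq.int(0L, .t_cap(cfg, s), by = coarse_t_step))
      if (count_at(s, t) > 0L) hits[[length(hits) + 1L]] <- c(s, t)
  refined <- list()
  for (h in hits) {
    for (s in max(s_min, h[1] - coarse_s_step + 1L):min(s_max, h[1] + coarse_s_step - 1L))
      for (t in max(0L, h[2] - coarse_t_step + 1L):min(.t_cap(cfg, s), h[2] + coarse_t_step - 1L)) {
        k <- count_at(s, t)
        if (k > 0L) refined[[sprintf("%d.%d", s, t)]] <- data.frame(s = s, t = t, n_instances = k)
      }
  }
  if (!length(refined))
    return(data.frame(s = integer(), t = integer(), n_instances = integer()))
  out <- do.call(rbind, refined)
  out <- out[order(out$s, out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}
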