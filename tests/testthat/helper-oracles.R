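# Independent oracles: deliberately naive, sharing no code with the package
# internals they check.

# all-pairs matcher + BFS transitive closure; O(G^2)
oracle_components <- function(partitions, t) {
  G <- length(partitions)
  adj <- matrix(FALSE, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i >= j) next
    s <- partitions[[i]]$s
    ov <- length(intersect(partitions[[i]]$samples, partitions[[j]]$samples))
    adj[i, j] <- adj[j, i] <- (s - ov) <= t
  }
  comp <- rep(NA_integer_, G)
  cid <- 0L
  for (start in seq_len(G)) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# canonical form of a component partition for comparison: sorted list of
# sorted member vectors
canon_partition <- function(members) {
  comps <- lapply(unname(split(seq_along(members), members)), sort)
  unname(comps[order(vapply(comps, `[[`, 0L, 1L))])
}

canon_components <- function(comps) {
  comps <- lapply(comps, function(z) unname(sort(z)))
  unname(comps[order(vapply(comps, function(z) as.character(z[[1L]]), ""))])
}

# brute-force kNN imputation value for entry (g, j)
oracle_knn_value <- function(vals, g, j, k) {
  G <- nrow(vals)
  d <- rep(Inf, G)
  for (r in seq_len(G)) {
    if (r == g) next
    shared <- which(!is.na(vals[g, ]) & !is.na(vals[r, ]))
    if (!length(shared)) next
    d[r] <- sqrt(sum((vals[g, shared] - vals[r, shared])^2) / length(shared))
  }
  donors <- which(!is.na(vals[, j]) & is.finite(d))
  donors <- donors[order(d[donors], donors)]
  mean(vals[donors[seq_len(min(k, length(donors)))], j])
}

# explicit O/E/V log-rank tabulation over simultaneous risk sets
oracle_logrank_chi2 <- function(time, event, group) {
  g1 <- unique(group)[[1L]]
  O <- E <- V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at <- time >= tt
    n <- sum(at); n1 <- sum(at & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# random partitions derived from a random expression matrix
rand_partitions <- function(G, n, s) {
  m <- matrix(stats::rnorm(G * n), G, n)
  lapply(seq_len(G), function(g)
    induce_partition(m[g, ], s, probe_id = sprintf("P%03d", g)))
}

# brute-force single-linkage over the pairwise Jaccard matrix
oracle_link <- function(probe_sets, threshold) {
  G <- length(probe_sets)
  adj <- matrix(FALSE, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i >= j) next
    jac <- length(intersect(probe_sets[[i]], probe_sets[[j]])) /
      length(union(probe_sets[[i]], probe_sets[[j]]))
    adj[i, j] <- adj[j, i] <- jac >= threshold
  }
  comp <- rep(NA_integer_, G)
  cid <- 0L
  for (start in seq_len(G)) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# small expression fixture with an exactly planted block: block probes take
# large values on 'block_samples', everything else is standard noise
planted_block_matrix <- function(n_probes, n_samples, block_probes,
                                 block_samples, shift = 100, seed = 42) {
  withr::local_seed(seed)
  m <- matrix(stats::rnorm(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("P%03d", seq_len(n_probes)),
                              sprintf("S%03d", seq_len(n_samples))))
  m[block_probes, block_samples] <- m[block_probes, block_samples] + shift
  expr_matrix(m)
}

tmpfile <- function(ext = ".tsv") tempfile(fileext = ext)
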