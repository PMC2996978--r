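#' Synthetic-data configuration
#'
#' Describes a synthetic cohort emulating the structure of the real inputs
#' the method targets: a probes x samples matrix with multi-probe genes and
#' missing values, planted co-regulated gene blocks active in sample
#' subsets, and survival times whose hazard depends on planted-set activity.
#'
#' The default is the standard benchmark fixture: 200 probes x 60 samples,
#' one 10-probe set active in 15 samples at effect size 3 SD, unit noise.
#'
#' @param n_probes,n_samples matrix dimensions.
#' @param planted_sets list of planted sets, each a list with `n_probes`,
#'   `n_active`, `delta` (additive shift in SD units) and `hazard_ratio`
#'   (hazard multiplier for active samples); an optional `samples` element
#'   fixes the active sample indices explicitly. Without explicit samples,
#'   active sets are drawn disjointly across sets while they fit in n.
#' @param noise_sd background standard deviation.
#' @param missing_rate fraction of entries masked missing, in \[0, 1).
#' @param multiprobe_rate fraction of probes starting a multi-probe gene
#'   (2-5 probes sharing a base row plus independent noise).
#' @param er_positive_rate probability a sample is ER positive (default 0.7,
#'   a typical breast-cohort fraction).
#' @param baseline_hazard events per year for an inactive sample (default
#'   0.11, giving roughly 40% events under the default censoring window).
#' @param censoring_time_max censoring drawn uniformly on (0, this\] years.
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_probes = 200L, n_samples = 60L,
                         planted_sets = list(list(n_probes = 10L,
                                                  n_active = 15L,
                                                  delta = 3,
                                                  hazard_ratio = 1)),
                         noise_sd = 1, missing_rate = 0,
                         multiprobe_rate = 0.1, er_positive_rate = 0.7,
                         baseline_hazard = 0.11, censoring_time_max = 10,
                         seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) stop("'missing_rate' must be in [0, 1)")
  total_planted <- sum(vapply(planted_sets, function(p) p$n_probes, 0))
  if (total_planted > n_probes)
    stop("planted sets need ", total_planted, " probes but n_probes = ", n_probes)
  for (p in planted_sets)
    if (p$n_active > n_samples) stop("planted set active in more samples than exist")
  structure(list(n_probes = as.integer(n_probes),
                 n_samples = as.integer(n_samples),
                 planted_sets = planted_sets, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 multiprobe_rate = multiprobe_rate,
                 er_positive_rate = er_positive_rate,
                 baseline_hazard = baseline_hazard,
                 censoring_time_max = censoring_time_max,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic expression + clinical fixture
#'
#' Background entries are i.i.d. normal(0, noise_sd). Probes are grouped
#' into genes; a gene spanning several probes duplicates one base row with
#' independent per-probe noise (mimicking multiple probe sets spotting the
#' same transcript). Each planted set shifts its probes by +delta on its
#' active samples. Entries are then masked missing at `missing_rate`.
#' Survival times are exponential with per-sample hazard equal to the
#' baseline times the product of the hazard ratios of the planted sets the
#' sample is active in; censoring is uniform on (0, censoring_time_max].
#' The global RNG state is saved and restored, so generation is a pure
#' function of the config.
#'
#' @param cfg a [synth_config()].
#' @return List with `expression` (an [expr_matrix()] with symbol
#'   annotation), `clinical` (a `clinical_table`) and `truth` (list with
#'   per-set `probes`, `samples`, `delta`, `hazard_ratio`).
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(cfg$seed)

  P <- cfg$n_probes; n <- cfg$n_samples
  probe_id <- sprintf("P%04d", seq_len(P))
  sample_id <- sprintf("S%03d", seq_len(n))

  # gene assignment: walk the probes, occasionally opening a multi-probe
  # gene; spans never cross a planted-block boundary (a gene belongs to one
  # co-regulated set, or to the background)
  blocks <- cumsum(c(0L, vapply(cfg$planted_sets, function(p) as.integer(p$n_probes), 0L)))
  boundary <- c(blocks[blocks > 0L], P)
  gene_of <- integer(P); gid <- 0L; i <- 1L
  while (i <= P) {
    gid <- gid + 1L
    limit <- min(boundary[boundary >= i]) - i + 1L
    span <- if (stats::runif(1) < cfg$multiprobe_rate)
      min(sample.int(4L, 1L) + 1L, limit) else 1L
    gene_of[i:(i + span - 1L)] <- gid
    i <- i + span
  }
  symbols <- stats::setNames(sprintf("G%04d", gene_of), probe_id)

  # background expression; multi-probe siblings share half the noise
  # variance (base + probe-level components), so every row's marginal sd is
  # exactly noise_sd and siblings correlate at 0.5
  vals <- matrix(0, P, n, dimnames = list(probe_id, sample_id))
  half <- cfg$noise_sd / sqrt(2)
  for (g in seq_len(gid)) {
    rows <- which(gene_of == g)
    if (length(rows) == 1L) {
      vals[rows, ] <- stats::rnorm(n, 0, cfg$noise_sd)
    } else {
      base <- stats::rnorm(n, 0, half)
      for (r in rows) vals[r, ] <- base + stats::rnorm(n, 0, half)
    }
  }

  # planted blocks: disjoint probe ranges; active samples disjoint across
  # sets while they fit, unless given explicitly
  truth <- list()
  next_probe <- 1L
  pool <- seq_len(n)
  for (k in seq_along(cfg$planted_sets)) {
    p <- cfg$planted_sets[[k]]
    rows <- seq.int(next_probe, next_probe + p$n_probes - 1L)
    next_probe <- next_probe + p$n_probes
    if (!is.null(p$samples)) {
      active <- sort(as.integer(p$samples))
    } else if (p$n_active <= length(pool)) {
      active <- sort(sample(pool, p$n_active))
      pool <- setdiff(pool, active)
    } else {
      active <- sort(sample(seq_len(n), p$n_active))
    }
    vals[rows, active] <- vals[rows, active] + p$delta * cfg$noise_sd
    truth[[k]] <- list(probes = probe_id[rows], samples = active,
                       delta = p$delta, hazard_ratio = p$hazard_ratio)
  }

  if (cfg$missing_rate > 0) {
    mask <- stats::runif(P * n) < cfg$missing_rate
    vals[matrix(mask, P, n)] <- NA_real_
  }

  hazard <- rep(cfg$baseline_hazard, n)
  for (tr in truth) hazard[tr$samples] <- hazard[tr$samples] * tr$hazard_ratio
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::runif(n, 0, cfg$censoring_time_max)
  clinical <- data.frame(
    sample_id = sample_id,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    er_status = ifelse(stats::runif(n) < cfg$er_positive_rate,
                       "positive", "negative"),
    stringsAsFactors = FALSE)
  class(clinical) <- c("clinical_table", "data.frame")

  list(expression = expr_matrix(vals, symbols), clinical = clinical,
       truth = truth)
}

#' Score recovery of planted sets by consolidated families
#'
#' Each planted set is matched to the family whose core overlaps it most
#' (ties broken by higher Jaccard, then earlier family), and scored by
#' precision (overlap / core size), recall (overlap / planted size) and an
#' exact-match flag.
#'
#' @param truth the `truth` element of [generate_synthetic()] output.
#' @param families a `gene_set_families` object.
#' @return Data frame with one row per planted set: `set`, `family_id`,
#'   `overlap`, `precision`, `recall`, `exact`.
#' @export
evaluate_recovery <- function(truth, families) {
  cores <- lapply(families$families, `[[`, "core_probes")
  rows <- lapply(seq_along(truth), function(k) {
    planted <- truth[[k]]$probes
    if (!length(cores)) {
      return(data.frame(set = k, family_id = NA_integer_, overlap = 0L,
                        precision = 0, recall = 0, exact = FALSE))
    }
    ov <- vapply(cores, function(cc) length(intersect(cc, planted)), 0L)
    jac <- mapply(function(cc, o) if (length(union(cc, planted))) o / length(union(cc, planted)) else 0,
                  cores, ov)
    best <- order(-ov, -jac, seq_along(cores))[1L]
    core <- cores[[best]]
    data.frame(set = k,
               family_id = as.integer(families$families[[best]]$family_id),
               overlap = ov[best],
               precision = if (length(core)) ov[best] / length(core) else 0,
               recall = ov[best] / length(planted),
               exact = setequal(core, planted))
  })
  do.call(rbind, rows)
}
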