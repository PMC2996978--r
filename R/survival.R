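#' Column-sum score of a gene set
#'
#' The per-sample score of a set is the plain sum of its probes' expression
#' values — no weighting or averaging. It orders heatmap columns and defines
#' the survival splits.
#'
#' @param x an [expr_matrix()].
#' @param probes probe IDs of the set; all must be present.
#' @return Named numeric vector, one score per sample.
#' @export
column_sum_score <- function(x, probes) {
  if (!length(probes)) stop("'probes' must be nonempty")
  missing <- setdiff(probes, rownames(x$values))
  if (length(missing))
    stop("unknown probe(s): ", paste(missing, collapse = ", "))
  colSums(x$values[probes, , drop = FALSE])
}

#' Median split of a score vector
#'
#' Samples at or below the median score go to the low group, the rest to the
#' high group (ties at the median go low).
#'
#' @param scores numeric vector, length >= 4, not all equal.
#' @return Character vector of `"low"` / `"high"`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 4L) stop("median split needs >= 4 samples")
  if (max(scores) == min(scores)) stop("degenerate split: all scores identical")
  ifelse(scores <= stats::median(scores), "low", "high")
}

#' First-versus-last-quartile split of a score vector
#'
#' The floor(n/4) lowest scorers versus the floor(n/4) highest; the middle
#' half is excluded. Boundary ties are resolved by ascending sample index.
#'
#' @param scores numeric vector, length >= 8, not all equal.
#' @return Character vector of `"Q1"` / `"Q4"` / `"excluded"`.
#' @export
quartile_split <- function(scores) {
  n <- length(scores)
  if (n < 8L) stop("quartile split needs >= 8 samples")
  if (max(scores) == min(scores)) stop("degenerate split: all scores identical")
  q <- n %/% 4L
  ord <- order(scores, seq_len(n))
  out <- rep("excluded", n)
  out[ord[seq_len(q)]] <- "Q1"
  out[ord[seq.int(n - q + 1L, n)]] <- "Q4"
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time the observed minus
#' expected events in one group, with hypergeometric variance over the
#' simultaneous risk sets; chi2 = (sum O - E)^2 / sum V on 1 degree of
#' freedom, p from the upper chi-square tail. Computed via
#' [survival::survdiff()]. With zero events in total the test is undefined
#' and (chi2 = 0, p = 1) is returned with a warning.
#'
#' @param time nonnegative survival times.
#' @param event binary event indicators (1 = event, 0 = censored).
#' @param group two-level grouping; entries `NA` or `"excluded"` are dropped.
#' @return List with `chi2`, `p`, `n_low`, `n_high`, `n_events` (group
#'   counts follow the alphabetically first level as "low").
#' @export
logrank <- function(time, event, group) {
  keep <- !is.na(group) & group != "excluded" & !is.na(time) & !is.na(event)
  time <- time[keep]; event <- event[keep]; group <- as.character(group)[keep]
  lev <- sort(unique(group))
  if (length(lev) != 2L) stop("'group' must have exactly two nonempty levels")
  if (setequal(lev, c("low", "high"))) lev <- c("low", "high")
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("'event' must be binary")
  n1 <- sum(group == lev[1L]); n2 <- sum(group == lev[2L])
  if (sum(event) == 0) {
    warning("no events in either group; log-rank undefined")
    return(list(chi2 = 0, p = 1, n_low = n1, n_high = n2, n_events = 0L))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n_low = n1, n_high = n2, n_events = as.integer(sum(event)))
}

.survival_row <- function(family_id, stratum, split, res) {
  data.frame(family_id = family_id, stratum = stratum, split = split,
             chi2 = res$chi2, p = res$p, n_low = res$n_low,
             n_high = res$n_high, n_events = res$n_events,
             stringsAsFactors = FALSE)
}

.na_row <- function(family_id, stratum, split) {
  data.frame(family_id = family_id, stratum = stratum, split = split,
             chi2 = NA_real_, p = NA_real_, n_low = NA_integer_,
             n_high = NA_integer_, n_events = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Five-way log-rank evaluation of a gene-set family
#'
#' Evaluates the family's core set against outcome with up to five log-rank
#' tests of its column-sum score: all samples at the median, all samples by
#' first versus last quartile, ER-positive at the median, ER-positive by
#' quartiles, and ER-negative at the median. The ER-negative stratum is
#' never split by quartiles (class sizes are too small), and both ER strata
#' are skipped — with a warning — when ER status is unknown for every
#' sample, leaving two results. Degenerate strata (too few samples, constant
#' score, no events) yield NA rows with a warning rather than dropping the
#' row, so the result shape is stable.
#'
#' @param x an imputed [expr_matrix()].
#' @param clinical a `clinical_table` aligned to `x` (see [read_clinical()]);
#'   samples with missing time or event are excluded.
#' @param family a `gene_set_family` with nonempty core, or a character
#'   vector of probe IDs.
#' @param family_id identifier used in the output (default taken from
#'   `family`).
#' @return Data frame of class `survival_eval`, one row per evaluation:
#'   `family_id`, `stratum`, `split`, `chi2`, `p`, `n_low`, `n_high`,
#'   `n_events`.
#' @export
evaluate_family <- function(x, clinical, family, family_id = NULL) {
  if (inherits(family, "gene_set_family")) {
    if (is.null(family_id)) family_id <- family$family_id
    probes <- family$core_probes
  } else probes <- family
  if (!length(probes)) stop("family has an empty core set")
  if (is.null(family_id)) family_id <- NA_integer_
  clinical <- align_clinical(clinical, x)
  score <- column_sum_score(x, probes)
  usable <- !is.na(clinical$time) & !is.na(clinical$event)
  if (!all(usable))
    message(sum(!usable), " sample(s) without clinical data excluded")
  run <- function(stratum, split, sel) {
    res <- tryCatch({
      sc <- score[sel]
      grp <- if (split == "median") {
        g <- median_split(sc)
        factor(g, levels = c("low", "high"))
      } else {
        g <- quartile_split(sc)
        factor(g, levels = c("Q1", "Q4", "excluded"))
      }
      lr <- logrank(clinical$time[sel], clinical$event[sel], as.character(grp))
      .survival_row(family_id, stratum, split, lr)
    }, error = function(e) {
      warning(sprintf("%s/%s evaluation degenerate: %s",
                      stratum, split, conditionMessage(e)), call. = FALSE)
      .na_row(family_id, stratum, split)
    })
    res
  }
  er <- clinical$er_status
  rows <- list(run("all", "median", usable),
               run("all", "quartiles", usable))
  if (all(er[usable] == "unknown")) {
    warning("ER status unknown for all samples; ER strata skipped")
  } else {
    rows <- c(rows,
              list(run("ER+", "median", usable & er == "positive"),
                   run("ER+", "quartiles", usable & er == "positive"),
                   run("ER-", "median", usable & er == "negative")))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("survival_eval", "data.frame")
  out
}

#' Evaluate every consolidated family against survival
#'
#' Applies [evaluate_family()] to each family with a nonempty core; families
#' with empty cores are skipped.
#'
#' @param families a `gene_set_families` object.
#' @inheritParams evaluate_family
#' @return A `survival_eval` data frame with a `significant` flag
#'   (p <= 0.05).
#' @export
evaluate_survival <- function(families, x, clinical) {
  keep <- Filter(function(f) length(f$core_probes) > 0L, families$families)
  rows <- lapply(keep, function(f) evaluate_family(x, clinical, f))
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p <= 0.05
  class(out) <- c("survival_eval", "data.frame")
  out
}
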