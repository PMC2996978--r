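test_that("column-sum score is the plain per-sample sum", {
  m <- matrix(1, 2, 4, dimnames = list(c("P1", "P2"), sprintf("S%d", 1:4)))
  x <- expr_matrix(m)
  expect_identical(unname(column_sum_score(x, c("P1", "P2"))), rep(2, 4))
  expect_identical(column_sum_score(x, "P1"), m["P1", ])
  withr::local_seed(61)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(sprintf("P%d", 1:6), sprintf("S%02d", 1:10)))
  x <- expr_matrix(m)
  want <- vapply(1:10, function(j) sum(m[, j]), 0)   # exhaustive sum oracle
  expect_equal(unname(column_sum_score(x, rownames(m))), want)
  expect_error(column_sum_score(x, c("P1", "PX")), "PX")
})

test_that("median split sends ties at the median low", {
  expect_identical(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_identical(median_split(c(1, 2, 2, 3)), c("low", "low", "low", "high"))
  expect_error(median_split(c(1, 1, 1, 1)), "degenerate")
  expect_error(median_split(c(1, 2, 3)), ">= 4")
  withr::local_seed(62)
  for (rep in 1:20) {
    sc <- rnorm(sample(4:40, 1))
    g <- median_split(sc)
    expect_identical(sum(g == "low"), sum(sc <= median(sc)))
  }
})

test_that("quartile split takes floor(n/4) from each tail", {
  g <- quartile_split(c(8, 1, 2, 7, 3, 6, 4, 5))
  expect_identical(sum(g == "Q1"), 2L)
  expect_identical(sum(g == "Q4"), 2L)
  expect_identical(g[2], "Q1"); expect_identical(g[1], "Q4")
  expect_identical(sum(quartile_split(rnorm(251)) != "excluded"), 124L)  # 62+62
  withr::local_seed(63)
  for (rep in 1:20) {
    n <- sample(8:60, 1)
    sc <- rnorm(n)
    g <- quartile_split(sc)
    ord <- order(sc, seq_len(n))            # sort-based oracle
    expect_identical(which(g == "Q1"), sort(ord[seq_len(n %/% 4)]))
    expect_identical(which(g == "Q4"), sort(ord[seq.int(n - n %/% 4 + 1, n)]))
  }
})

test_that("log-rank is zero on identical groups and matches the O/E/V oracle", {
  time <- c(1, 3, 5, 7); ev <- c(1, 1, 0, 1)
  r <- logrank(c(time, time), c(ev, ev), rep(c("low", "high"), each = 4))
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  # 8-subject worked example, two groups of 4, no censoring; expected value
  # frozen from an independent O/E/V hand tabulation
  time <- c(1, 3, 5, 7, 2, 4, 6, 8)
  ev <- rep(1, 8)
  grp <- rep(c("low", "high"), each = 4)
  r <- logrank(time, ev, grp)
  expect_equal(r$chi2, 0.4114552893, tolerance = 1e-9)
  expect_equal(r$chi2, oracle_logrank_chi2(time, ev, grp), tolerance = 1e-9)
  expect_identical(r$n_low, 4L)
  expect_identical(r$n_events, 8L)

  # censored random data still agrees with the tabulation oracle
  withr::local_seed(64)
  for (rep in 1:20) {
    n <- sample(12:40, 1)
    time <- round(rexp(n, 0.3), 2)
    ev <- rbinom(n, 1, 0.7)
    grp <- sample(c("low", "high"), n, TRUE)
    if (length(unique(grp)) < 2 || sum(ev) == 0) next
    expect_equal(logrank(time, ev, grp)$chi2,
                 oracle_logrank_chi2(time, ev, grp), tolerance = 1e-8)
  }
})

test_that("log-rank p equals the closed-form chi-square(1) tail", {
  withr::local_seed(65)
  time <- rexp(40); ev <- rbinom(40, 1, 0.6)
  grp <- rep(c("low", "high"), 20)
  r <- logrank(time, ev, grp)
  expect_equal(r$p, exp(pchisq(r$chi2, 1, lower.tail = FALSE, log.p = TRUE)))
  # erfc form of the chi-square(1) survival function
  expect_equal(r$p, 2 * pnorm(sqrt(r$chi2), lower.tail = FALSE))
})

test_that("log-rank is invariant to group relabeling and time rescaling", {
  withr::local_seed(66)
  time <- rexp(30); ev <- rbinom(30, 1, 0.6); grp <- rep(c("a", "b"), 15)
  r1 <- logrank(time, ev, grp)
  r2 <- logrank(time, ev, ifelse(grp == "a", "b", "a"))
  expect_equal(r1$chi2, r2$chi2)
  r3 <- logrank(time * 7.3, ev, grp)
  expect_equal(r1$chi2, r3$chi2)
})

test_that("zero events yield chi2 = 0, p = 1 with a warning", {
  expect_warning(r <- logrank(c(1, 2, 3, 4), c(0, 0, 0, 0),
                              c("low", "low", "high", "high")), "no events")
  expect_identical(r$chi2, 0)
  expect_identical(r$p, 1)
})

test_that("evaluate_family emits the five-way (or two-way) evaluation shape", {
  withr::local_seed(67)
  sim <- generate_synthetic(synth_config(
    n_probes = 30, n_samples = 80, seed = 67,
    planted_sets = list(list(n_probes = 10, n_active = 30, delta = 3,
                             hazard_ratio = 2))))
  probes <- sim$truth[[1]]$probes
  res <- evaluate_family(sim$expression, sim$clinical, probes, family_id = 1)
  expect_s3_class(res, "survival_eval")
  expect_identical(nrow(res), 5L)
  expect_identical(res$stratum, c("all", "all", "ER+", "ER+", "ER-"))
  expect_identical(res$split, c("median", "quartiles", "median", "quartiles", "median"))
  expect_false(any(res$stratum == "ER-" & res$split == "quartiles"))

  # ER-free cohort: ER strata skipped with a warning, two results remain
  clin2 <- sim$clinical
  clin2$er_status <- "unknown"
  expect_warning(res2 <- evaluate_family(sim$expression, clin2, probes, 1),
                 "ER status unknown")
  expect_identical(nrow(res2), 2L)
  expect_identical(res2$stratum, c("all", "all"))
})

test_that("scores independent of survival are rarely significant", {
  withr::local_seed(68)
  hits <- 0L; B <- 40L
  for (b in seq_len(B)) {
    sim <- generate_synthetic(synth_config(
      n_probes = 20, n_samples = 80, seed = 8000 + b,
      planted_sets = list(list(n_probes = 8, n_active = 40, delta = 3,
                               hazard_ratio = 1))))
    res <- suppressWarnings(
      evaluate_family(sim$expression, sim$clinical, sim$truth[[1]]$probes, 1))
    p <- res$p[res$stratum == "all" & res$split == "median"]
    if (!is.na(p) && p < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, B * 0.25)    # near-nominal false-positive rate
})

test_that("quartile split beats a coin-flip split on a monotone score-hazard link", {
  withr::local_seed(69)
  chi_q <- chi_r <- numeric(30)
  for (b in 1:30) {
    n <- 120
    score <- rnorm(n)
    haz <- 0.1 * exp(0.8 * score)          # hazard rises with score
    time <- rexp(n, haz); cens <- runif(n, 0, 10)
    ev <- as.integer(time <= cens); tt <- pmin(time, cens)
    g <- quartile_split(score)
    chi_q[b] <- suppressWarnings(logrank(tt, ev, g)$chi2)
    g2 <- sample(rep(c("low", "high"), each = n / 2))
    chi_r[b] <- suppressWarnings(logrank(tt, ev, g2)$chi2)
  }
  expect_gt(mean(chi_q), mean(chi_r))
})
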