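test_that("build_match_graph handles duplicated and non-matching probes", {
  withr::local_seed(31)
  m <- matrix(rnorm(5 * 12), 5, 12)
  m[2, ] <- m[1, ]                        # exact duplicate pair
  parts <- lapply(1:5, function(g) induce_partition(m[g, ], 4, sprintf("P%d", g)))
  comps <- build_match_graph(parts, t = 0)
  sizes <- unname(lengths(comps))
  expect_true(any(vapply(comps, function(cc) setequal(cc, c("P1", "P2")), NA)))
  # with distinct random rows at t=0, everything else is a singleton
  expect_identical(sort(sizes), sort(c(2L, 1L, 1L, 1L)))
})

test_that("pruned match graph equals the brute-force all-pairs oracle", {
  withr::local_seed(32)
  for (rep in 1:25) {
    G <- sample(10:60, 1); n <- sample(8:40, 1)
    s <- sample(2:(n - 1), 1); t <- sample(0:s, 1)
    parts <- rand_partitions(G, n, s)
    got <- build_match_graph(parts, t)
    want <- canon_partition(oracle_components(parts, t))
    ids <- sprintf("P%03d", seq_len(G))
    want <- lapply(want, function(ix) sort(ids[ix]))
    expect_identical(canon_components(got), canon_components(want))
  }
})

test_that("components_at saturates to one all-probe instance at t >= s", {
  withr::local_seed(33)
  m <- matrix(rnorm(20 * 15), 20, 15,
              dimnames = list(sprintf("P%02d", 1:20), sprintf("S%02d", 1:15)))
  x <- expr_matrix(m)
  inst <- components_at(x, s = 5, t = 5, cfg = grid_config())
  expect_length(inst, 1L)
  expect_identical(inst[[1]]$probes, sort(rownames(m)))
  expect_identical(inst[[1]]$cell, "5t5")
})

test_that("a planted block with identical top-s sets is the only instance at t=0", {
  x <- planted_block_matrix(50, 30, block_probes = 1:10,
                            block_samples = 3:10)
  inst <- components_at(x, s = 8, t = 0, cfg = grid_config())
  expect_length(inst, 1L)
  expect_identical(inst[[1]]$probes, sprintf("P%03d", 1:10))
  expect_identical(inst[[1]]$consensus_samples, 3:10)
})

test_that("stringent t on pure noise yields no instance of size >= 6", {
  withr::local_seed(34)
  m <- matrix(rnorm(100 * 40), 100, 40,
              dimnames = list(sprintf("P%03d", 1:100), sprintf("S%02d", 1:40)))
  x <- expr_matrix(m)
  expect_length(components_at(x, s = 10, t = 0, cfg = grid_config()), 0L)
  expect_length(components_at(x, s = 10, t = 1, cfg = grid_config()), 0L)
})

test_that("consensus_samples follows majority then rank score", {
  # identical partitions: consensus is that same set
  v <- c(9, 8, 7, 1, 2, 3)
  comp <- list(induce_partition(v, 3, "a"), induce_partition(v, 3, "b"))
  expect_identical(consensus_samples(comp), c(1L, 2L, 3L))
  # frequencies {1:3, 2:2, 3:1} over three members, s = 2 -> {1, 2}
  comp <- list(induce_partition(c(9, 8, 0, 0, 0, 0), 2, "a"),
               induce_partition(c(9, 8, 0, 0, 0, 0), 2, "b"),
               induce_partition(c(9, 0, 8, 0, 0, 0), 2, "c"))
  expect_identical(consensus_samples(comp), c(1L, 2L))
  # random small components agree with an exhaustive frequency count oracle
  withr::local_seed(35)
  for (rep in 1:30) {
    n <- sample(6:15, 1); s <- sample(2:4, 1)
    comp <- rand_partitions(sample(2:5, 1), n, s)
    freq <- tabulate(unlist(lapply(comp, `[[`, "samples")), n)
    cons <- consensus_samples(comp)
    expect_length(cons, s)
    # no excluded sample may have strictly higher frequency than an included one
    expect_gte(min(freq[cons]), max(freq[-cons][freq[-cons] > 0], 0))
  }
})

test_that("match-graph components only merge, never split, as t grows", {
  withr::local_seed(36)
  for (rep in 1:100) {
    G <- sample(8:25, 1); n <- sample(8:20, 1); s <- sample(2:(n - 1), 1)
    parts <- rand_partitions(G, n, s)
    t <- sample(0:(s - 1), 1)
    c1 <- oracle_components(parts, t)          # membership vectors
    ids <- sprintf("P%03d", seq_len(G))
    g1 <- build_match_graph(parts, t)
    g2 <- build_match_graph(parts, t + 1)
    # refinement: every component at t is inside one component at t+1
    where <- function(p, comps) which(vapply(comps, function(cc) p %in% cc, NA))
    for (cc in g1) {
      hosts <- unique(vapply(cc, function(p) where(p, g2), 0L))
      expect_length(hosts, 1L)
    }
  }
})

test_that("sentinel stop rule: duplicated sentinel/foil rows merge at t = 0", {
  withr::local_seed(37)
  m <- matrix(rnorm(12 * 20), 12, 20,
              dimnames = list(sprintf("P%02d", 1:12), sprintf("S%02d", 1:20)))
  m[7:12, ] <- m[1:6, ]                   # foils duplicate the sentinels
  x <- expr_matrix(m)
  cfg <- grid_config(sentinel = sentinel_config(sprintf("P%02d", 1:6),
                                                sprintf("P%02d", 7:12)))
  expect_identical(t_max_for_s(x, s = 5, cfg), -1L)
})

test_that("sentinel and foil blocks with disjoint supports stay separate", {
  s <- 6L
  # two planted blocks on disjoint sample supports, no background rows that
  # could bridge them by chance chains
  x <- planted_block_matrix(12, 20, block_probes = 1:6, block_samples = 1:6)
  x$values[7:12, 7:12] <- x$values[7:12, 7:12] + 100   # foil block, disjoint
  cfg <- grid_config(sentinel = sentinel_config(sprintf("P%03d", 1:6),
                                                sprintf("P%03d", 7:12)))
  tmax <- t_max_for_s(x, s = s, cfg)
  expect_gte(tmax, 0L)
  # disjoint size-s supports mismatch by s: no merge below t = s
  expect_identical(tmax, s - 1L)
})

test_that("without a sentinel the tolerance ceiling is floor(s/2)", {
  withr::local_seed(38)
  m <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(sprintf("P%02d", 1:10), sprintf("S%02d", 1:30)))
  x <- expr_matrix(m)
  expect_identical(t_max_for_s(x, 9, grid_config()), 4L)
  expect_identical(t_max_for_s(x, 8, grid_config(t_cap = 2L)), 2L)
})

test_that("sentinel probes absent from the matrix are a hard error", {
  withr::local_seed(39)
  m <- matrix(rnorm(80), 4, 20,
              dimnames = list(sprintf("P%d", 1:4), sprintf("S%02d", 1:20)))
  x <- expr_matrix(m)
  cfg <- grid_config(sentinel = sentinel_config(c("P1", "PX", "PY"), "P4"))
  expect_error(enumerate_gene_sets(x, cfg), "PX, PY")
})

test_that("spiral search with unit coarse steps equals the exhaustive scan", {
  x <- planted_block_matrix(30, 24, block_probes = 1:8, block_samples = 1:7)
  cfg <- grid_config()
  enum <- enumerate_gene_sets(x, cfg)
  exhaustive <- enum$cells[enum$cells$n_instances > 0, c("s", "t", "n_instances")]
  rownames(exhaustive) <- NULL
  got <- spiral_search(x, cfg, coarse_s_step = 1, coarse_t_step = 1)
  expect_identical(got, exhaustive)
})

test_that("spiral search flags cells around a planted block and none on noise", {
  x <- planted_block_matrix(40, 24, block_probes = 1:8, block_samples = 1:7)
  got <- spiral_search(x, grid_config(), coarse_s_step = 4, coarse_t_step = 2)
  expect_gt(nrow(got), 0)
  expect_true(any(abs(got$s - 7) <= 4))   # hits near the planted size
  withr::local_seed(40)
  m <- matrix(rnorm(40 * 16), 40, 16,
              dimnames = list(sprintf("P%03d", 1:40), sprintf("S%02d", 1:16)))
  noise <- expr_matrix(m)
  got <- spiral_search(noise, grid_config(t_cap = 1L),
                       coarse_s_step = 3, coarse_t_step = 1)
  expect_identical(nrow(got), 0L)
})

test_that("enumeration is deterministic and coarser s_step yields a subset", {
  x <- planted_block_matrix(40, 30, block_probes = 1:10, block_samples = 1:8)
  e1 <- enumerate_gene_sets(x, grid_config())
  e2 <- enumerate_gene_sets(x, grid_config())
  expect_identical(e1$instances, e2$instances)     # byte-identical rerun
  e3 <- enumerate_gene_sets(x, grid_config(s_step = 2))
  key <- function(e) vapply(e$instances, function(z)
    paste(z$cell, paste(z$probes, collapse = ","), sep = "|"), "")
  expect_true(all(key(e3) %in% key(e1)))
})

test_that("planted-block instances vary by at most one probe between adjacent t cells", {
  x <- planted_block_matrix(50, 40, block_probes = 1:10, block_samples = 1:8,
                            shift = 100)
  cfg <- grid_config()
  prev <- NULL
  for (t in 0:3) {
    inst <- components_at(x, s = 8, t = t, cfg)
    planted <- Filter(function(z) "P001" %in% z$probes, inst)
    expect_length(planted, 1L)
    cur <- planted[[1]]$probes
    if (!is.null(prev))
      expect_lte(length(setdiff(union(cur, prev), intersect(cur, prev))), 1L)
    prev <- cur
  }
})

test_that("three disjoint planted blocks are recovered unmixed at t = 0", {
  withr::local_seed(41)
  sim <- generate_synthetic(synth_config(
    n_probes = 60, n_samples = 36, noise_sd = 1, seed = 41,
    multiprobe_rate = 0,
    planted_sets = list(list(n_probes = 10, n_active = 8, delta = 10, hazard_ratio = 1),
                        list(n_probes = 10, n_active = 8, delta = 10, hazard_ratio = 1),
                        list(n_probes = 10, n_active = 8, delta = 10, hazard_ratio = 1))))
  enum <- enumerate_gene_sets(sim$expression, grid_config())
  planted <- lapply(sim$truth, `[[`, "probes")
  for (pp in planted) {
    hit <- Filter(function(z) all(pp %in% z$probes), enum$instances)
    expect_gt(length(hit), 0)
  }
  at0 <- Filter(function(z) z$t == 0, enum$instances)
  for (z in at0) {
    touched <- vapply(planted, function(pp) any(z$probes %in% pp), NA)
    expect_lte(sum(touched), 1L)          # no instance mixes blocks at t=0
  }
})
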