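test_that("gene list loading filters against matrix and enforces unique headers", {
  m <- toy_matrix(matrix(1, nrow = 5, ncol = 1,
                         dimnames = list(paste0("g", 1:5), "TF_x")))
  f <- withr::local_tempfile()
  writeLines(c("bg\tup", "g1\tg2", "g2\tg4", "g3\t", "g4\t", "g5\t"), f)
  ls <- read_gene_lists(f, m)
  expect_equal(length(ls$background), 5L)
  expect_equal(ls$queries$up, c("g2", "g4"))
  expect_equal(ls$triaged_genes, character())

  # a query gene absent from the matrix is triaged and X shrinks
  f2 <- withr::local_tempfile()
  writeLines(c("bg\tup", "g1\tg2", "g2\tg9", "g9\t", "g3\t"), f2)
  ls2 <- read_gene_lists(f2, m)
  expect_equal(ls2$triaged_genes, "g9")
  expect_equal(ls2$queries$up, "g2")
  expect_equal(length(ls2$background), 3L)

  dupf <- withr::local_tempfile()
  writeLines(c("bg\tup\tup", "g1\tg2\tg3"), dupf)
  expect_error(read_gene_lists(dupf), "unique names for each column")

  # query gene outside the background is dropped with a warning
  expect_warning(
    magic_gene_lists(paste0("g", 1:4), list(q = c("g1", "g7"))),
    "absent from the background")
  expect_error(
    suppressWarnings(magic_gene_lists(paste0("g", 1:4), list(q = "g7"))),
    "empty after filtering")
})

test_that("ecdf_dsup matches its worked examples", {
  expect_equal(ecdf_dsup(c(1, 2, 3, 4), c(3, 4))[c("d_sup", "arg_dsup")],
               list(d_sup = 0.5, arg_dsup = 2))
  # a query identical in distribution to the background
  b <- rep(c(1, 2, 3, 4), 10)
  expect_equal(ecdf_dsup(b, c(1, 2, 3, 4))$d_sup, 0)
  # signal-depleted query: B - Q <= 0 on the support, supremum below it
  dep <- ecdf_dsup(c(1, 2, 3, 4), c(1, 2))
  expect_equal(dep$d_sup, 0)
  expect_equal(dep$arg_dsup, -Inf)
  # both cumulatives are proper CDFs ending at 1
  ed <- ecdf_dsup(rlnorm(50), rlnorm(20))
  expect_true(all(diff(ed$b_cdf) >= 0) && all(diff(ed$q_cdf) >= 0))
  expect_equal(ed$b_cdf[length(ed$b_cdf)], 1)
  expect_equal(ed$q_cdf[length(ed$q_cdf)], 1)
})

test_that("d_sup and arg_dsup equal a brute-force scan on random instances", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(5:400, 1)
    x <- sample(1:min(n, 60), 1)
    b <- ifelse(runif(n) < 0.4, 0, round(rlnorm(n, 1, 1), 2))
    q <- sample(b, x)
    got <- ecdf_dsup(b, q)
    want <- bf_dsup(b, q)
    expect_equal(got$d_sup, want$d_sup)
    expect_equal(got$arg_dsup, want$arg_dsup)
  }
})

test_that("ks_pvalue boundary behavior and mode formulas", {
  expect_equal(ks_pvalue(100, 20, 0), 1)
  expect_lt(ks_pvalue(4000, 800, 1), 1e-10)
  expect_error(ks_pvalue(10, 5, 1.2), "\\[0, 1\\]")
  n_e <- 100 * 20 / 120
  expect_equal(ks_pvalue(100, 20, 0.3, mode = "onesided"),
               exp(-2 * n_e * 0.09))
  expect_equal(ks_pvalue(100, 20, 0.3, mode = "nested"),
               exp(-2 * (100 * 20 / 80) * 0.09))
  # asymptotic survival function is monotone in d
  d <- seq(0, 1, by = 0.05)
  p <- vapply(d, function(x) ks_pvalue(200, 40, x), numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_error(ks_pvalue(10, 5, 0.5, mode = "permutation"),
               "requires the background")
})

test_that("default p-value is conservative and nested mode tracks the permutation oracle", {
  set.seed(31)
  z_def <- numeric(10)
  gap_nested <- numeric(10)
  for (i in 1:10) {
    n <- sample(80:200, 1)
    x <- sample(10:40, 1)
    b <- ifelse(runif(n) < 0.3, 0, rlnorm(n, 1, 1))
    d <- ecdf_dsup(b, sample(b, x))$d_sup
    p_perm <- ks_pvalue(n, x, d, mode = "permutation", b = b,
                        n_perm = 20000L)
    z_def[i] <- ks_pvalue(n, x, d) - p_perm
    gap_nested[i] <- abs(ks_pvalue(n, x, d, mode = "nested") - p_perm)
  }
  # two-sample default never understates the nested-null p-value
  expect_true(all(z_def >= -0.01))
  # finite-population one-sided form is close in absolute terms
  expect_lt(max(gap_nested), 0.15)
})

test_that("tail statistics use n = ceil(0.05 X) with floor 1", {
  b <- c(10, 9, 8, 7, rep(1, 96))
  expect_equal(tail_stats(b, rep(1, 100))$n_tail, 5L)
  expect_equal(tail_stats(b, rep(1, 10))$n_tail, 1L)
  expect_equal(tail_stats(b, rep(1, 41))$n_tail, 3L)  # ceil(2.05)
  # identical tails give ratio 1
  q <- c(10, rep(0, 19))
  ts <- tail_stats(b, q)
  expect_equal(ts$ratio, 1)
  expect_equal(ts$obs_tail_mean, 10)
  # hand-checked means at n = 2
  ts2 <- tail_stats(c(5, 4, 3, 2, 1), c(4, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                                        1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  expect_equal(ts2$n_tail, 2L)
  expect_equal(ts2$obs_tail_mean, 3)
  expect_equal(ts2$exp_tail_mean, 4.5)
  expect_equal(ts2$ratio, 3 / 4.5)
  # an all-zero background tail is a degenerate track
  expect_equal(tail_stats(rep(0, 50), rep(0, 10))$ratio, 0)
})

test_that("targets are the strict > arg_dsup subset and triage flips at five", {
  q <- c(a = 0, b = 2, c = 5, d = 7, e = 9, f = 11)
  expect_equal(names(magic_targets(q, 5)), c("d", "e", "f"))
  expect_equal(names(magic_targets(q, -Inf)), names(q))
  expect_equal(length(magic_targets(q, 11)), 0L)

  # engineered toy: background of 100 genes; query where exactly k genes
  # exceed the critical ChIP
  make_report <- function(k) {
    genes <- sprintf("g%03d", 1:100)
    sig <- c(rep(10, k), rep(0, 100 - k))
    vals <- cbind(TF_x = sig, TF2_y = rlnorm(100))
    rownames(vals) <- genes
    m <- toy_matrix(vals)
    ls <- magic_gene_lists(genes, list(q = genes[1:20]))
    run_query(m, ls, "q")
  }
  set.seed(5)
  r4 <- make_report(4)$results
  expect_true(r4$triaged[r4$track_id == "TF_x"])
  r5 <- make_report(5)$results
  expect_false(r5$triaged[r5$track_id == "TF_x"])
  # a query of three genes can never reach five targets
  vals <- cbind(TF_x = rlnorm(50))
  rownames(vals) <- sprintf("g%02d", 1:50)
  ls3 <- magic_gene_lists(rownames(vals), list(q = rownames(vals)[1:3]))
  expect_true(all(run_query(toy_matrix(vals), ls3, "q")$results$triaged))
})

test_that("BH correction matches the hand-rolled step-up oracle", {
  expect_equal(p.adjust(0.05, "BH"), 0.05)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  expect_equal(bf_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bf_bh(p))
  }
})

test_that("Score is -log10(P_corr) * r with a floor, monotone in both arguments", {
  expect_equal(magic_score(1, 5), 0)
  expect_equal(magic_score(0.01, 2), 4)
  expect_equal(magic_score(0.1, 1), 1)
  expect_true(is.finite(magic_score(0, 3)))
  expect_gt(magic_score(1e-5, 2), magic_score(1e-4, 2))
  expect_gt(magic_score(0.01, 3), magic_score(0.01, 2))
})

test_that("run_query ranks a planted factor first and reports it once in the summary", {
  sim <- toy_planted(seed = 2)
  rep <- run_query(sim$matrix, sim$lists, "query")
  expect_equal(rep$results$track_id[1L], sim$planted_track_id)
  expect_equal(rep$n_background, 500L)
  expect_equal(rep$n_query, 60L)
  # summary keeps one row per factor, the best-scoring track
  det <- report_details(rep)
  summ <- report_summary(rep)
  expect_equal(anyDuplicated(summ$factor), 0L)
  for (f in summ$factor) {
    expect_equal(summ$score[summ$factor == f],
                 max(det$score[det$factor == f]))
  }
  # results are sorted by descending score among non-triaged rows
  expect_true(all(diff(det$score) <= 0))
})

test_that("two tracks of one factor collapse to the higher-scoring one", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:200)
  base <- rlnorm(200)
  strong <- base; strong[1:30] <- strong[1:30] * 8
  weak <- base; weak[1:30] <- weak[1:30] * 2
  vals <- cbind(TF_strong = strong, TF_weak = weak, OTHER_x = rlnorm(200))
  rownames(vals) <- genes
  m <- magic_matrix(vals, data.frame(factor = c("TF", "TF", "OTHER"),
                                     description = c("strong", "weak", "x"),
                                     stringsAsFactors = FALSE))
  ls <- magic_gene_lists(genes, list(q = genes[1:30]))
  rep <- run_query(m, ls, "q")
  summ <- report_summary(rep)
  expect_equal(sum(summ$factor == "TF"), 1L)
  expect_equal(summ$track_id[summ$factor == "TF"], "TF_strong")
})

test_that("a random background subset is almost never called significant", {
  set.seed(17)
  sim <- simulate_magic_matrix(magic_scenario(n_genes = 400, n_tracks = 10,
                                              query_size = 40, effect = 0,
                                              seed = 17))
  hits <- 0L
  total <- 0L
  for (r in 1:25) {
    q <- sample(sim$lists$background, 40)
    ls <- magic_gene_lists(sim$lists$background, list(q = q))
    res <- run_query(sim$matrix, ls, "q")$results
    hits <- hits + sum(res$significant, na.rm = TRUE)
    total <- total + sum(!res$triaged)
  }
  expect_lt(hits / total, 0.05)
})

test_that("null raw p-values are conservative: P(raw_p < alpha) <= 2 alpha", {
  set.seed(23)
  sim <- simulate_magic_matrix(magic_scenario(n_genes = 500, n_tracks = 10,
                                              query_size = 50, effect = 0,
                                              seed = 23))
  raw <- unlist(lapply(1:20, function(r) {
    q <- sample(sim$lists$background, 50)
    ls <- magic_gene_lists(sim$lists$background, list(q = q))
    res <- run_query(sim$matrix, ls, "q")$results
    res$raw_p[!res$triaged]
  }))
  for (alpha in c(0.01, 0.05)) {
    expect_lte(mean(raw < alpha), 2 * alpha)
  }
})
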