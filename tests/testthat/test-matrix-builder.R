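test_that("gene domains follow the three definitions with strand-aware promoters", {
  ann <- data.frame(symbol = c("p", "m"), chrom = "chr1",
                    strand = c("+", "-"), tx_start = 10000, tx_end = 15000,
                    stringsAsFactors = FALSE)
  g1 <- gene_domains(ann, "gene1kb")
  expect_equal(g1$start, c(9000, 9000))
  expect_equal(g1$end, c(16000, 16000))
  g5 <- gene_domains(ann, "gene5kb")
  expect_equal(g5$end - g5$start, rep((15000 - 10000) + 2 * 5000, 2))
  pr <- gene_domains(ann, "promoter")
  expect_equal(pr$start[pr$symbol == "p"], 9000)
  expect_equal(pr$end[pr$symbol == "p"], 10300)
  # minus strand: TSS at tx_end, upstream 5'-ward
  expect_equal(pr$start[pr$symbol == "m"], 14700)
  expect_equal(pr$end[pr$symbol == "m"], 16000)
  expect_equal(pr$end - pr$start, c(1300, 1300))
  # clipping at zero for a gene near the chromosome start
  near0 <- data.frame(symbol = "z", chrom = "chr1", strand = "+",
                      tx_start = 200, tx_end = 900)
  expect_equal(gene_domains(near0, "gene1kb")$start, 0)
})

test_that("annotation validation rejects bad strands and resolves duplicate symbols", {
  ann <- data.frame(symbol = c("a", "a", "b", "c"), chrom = "chr1",
                    strand = c("+", "+", "*", "-"),
                    tx_start = c(100, 50, 10, 10),
                    tx_end = c(500, 400, 90, 80), stringsAsFactors = FALSE)
  expect_warning(expect_warning(out <- validate_gene_annotation(ann),
                                "unknown strand"), "duplicated")
  expect_false("b" %in% out$symbol)
  # duplicates on the same chrom/strand collapse to the isoform-extreme span
  expect_equal(out$tx_start[out$symbol == "a"], 50)
  expect_equal(out$tx_end[out$symbol == "a"], 500)
  expect_error(validate_gene_annotation(
    data.frame(symbol = "x", chrom = "c", strand = "+", tx_start = 5,
               tx_end = 5)), "tx_start < tx_end")
})

test_that("max signal in domain uses any-overlap on half-open intervals", {
  peaks <- data.frame(start = c(100, 300), end = c(200, 400),
                      signal_value = c(3.2, 7.5))
  expect_equal(max_signal_in_domain(peaks, c(0, 500)), 7.5)
  expect_equal(max_signal_in_domain(peaks, c(600, 700)), 0)
  # 1 bp of overlap beats a weaker interior peak
  straddle <- data.frame(start = c(50, 120), end = c(101, 150),
                         signal_value = c(9.0, 4.0))
  expect_equal(max_signal_in_domain(straddle, c(100, 200)), 9.0)
  # half-open: a peak ending exactly at the domain start does not overlap
  expect_equal(max_signal_in_domain(
    data.frame(start = 50, end = 100, signal_value = 9), c(100, 200)), 0)
})

test_that("toy matrix build matches hand-computed cells and filters engineered tracks", {
  fx <- toy_build_fixture(withr::local_tempdir())
  ann <- read_gene_annotation(fx$annotation)
  m <- build_magic_matrix(ann, fx$manifest, "gene1kb")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(colnames(m$values), c("TFA_cellX", "TFB_cellY"))
  expect_equal(m$values["gA", "TFA_cellX"], 7.5)
  expect_equal(m$values["gB", "TFA_cellX"], 2.0)
  expect_equal(m$values["gA", "TFB_cellY"], 9.0)  # 1 bp straddle wins
  # gC sits on chr2, untouched by both tracks -> row of zeros
  expect_equal(unname(m$values["gC", ]), c(0, 0))

  # engineered filtering drops the column but leaves others untouched
  man <- read_track_manifest(fx$manifest)
  man$engineered[2L] <- TRUE
  m2 <- build_magic_matrix(ann, man, "gene1kb")
  expect_equal(colnames(m2$values), "TFA_cellX")
  expect_equal(m2$values[, "TFA_cellX"], m$values[, "TFA_cellX"])
  m3 <- build_magic_matrix(ann, man, "gene1kb", include_engineered = TRUE)
  expect_equal(m3$values, m$values)
})

test_that("unreadable narrowPeak lines are skipped with a count", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200\tp\t0\t.\t5\t-1\t-1\t-1",
               "chr1\tnotanumber\t200\tp\t0\t.\t5\t-1\t-1\t-1",
               "chr1\t100\t200",
               "chr1\t300\t250\tp\t0\t.\t5\t-1\t-1\t-1"), f)
  expect_warning(pk <- read_narrowpeak(f), "skipped 3 unreadable")
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$signal_value, 5)
})

test_that("every built cell equals a brute-force peak scan", {
  set.seed(11)
  dir <- withr::local_tempdir()
  for (rep in 1:3) {
    n_genes <- c(30L, 100L, 100L)[rep]
    n_peaks <- c(200L, 1000L, 600L)[rep]
    ann <- data.frame(
      symbol = sprintf("g%03d", seq_len(n_genes)),
      chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      tx_start = sample.int(500000L, n_genes), stringsAsFactors = FALSE)
    ann$tx_end <- ann$tx_start + sample(500:20000, n_genes, replace = TRUE)
    peaks <- data.frame(
      chrom = sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
      start = sample.int(520000L, n_peaks), stringsAsFactors = FALSE)
    peaks$end <- peaks$start + sample(50:2000, n_peaks, replace = TRUE)
    pf <- file.path(dir, sprintf("r%d.narrowPeak", rep))
    peaks$signal_value <- round(rlnorm(n_peaks, 1, 1), 4)
    writeLines(sprintf("%s\t%d\t%d\tp\t0\t.\t%g\t-1\t-1\t-1", peaks$chrom,
                       peaks$start, peaks$end, peaks$signal_value), pf)
    manifest <- data.frame(file_path = pf, factor = "TF",
                           description = "x", engineered = 0L)
    domain <- c("gene1kb", "gene5kb", "promoter")[rep]
    m <- build_magic_matrix(ann, manifest, domain)
    doms <- gene_domains(ann, domain)
    expected <- vapply(seq_len(n_genes), function(i) {
      bf_max_signal(peaks[peaks$chrom == doms$chrom[i], , drop = FALSE],
                    doms$start[i], doms$end[i])
    }, numeric(1L))
    expect_equal(unname(m$values[, 1L]), expected)
  }
})

test_that("matrix files round-trip exactly and reject malformed input", {
  vals <- matrix(c(0, 1/3, 7.5, pi, 0, 2e-12), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), c("A_x", "B_y")))
  m <- magic_matrix(vals)
  f <- withr::local_tempfile(fileext = ".mtx")
  write_magic_matrix(m, f)
  m2 <- read_magic_matrix(f)
  expect_identical(m2$values, m$values)
  expect_equal(m2$tracks$factor, c("A", "B"))
  expect_equal(m2$tracks$description, c("x", "y"))

  dup <- withr::local_tempfile()
  writeLines(c("Gene\tA_x", "g1\t1", "g1\t2"), dup)
  expect_error(read_magic_matrix(dup), "duplicate gene symbol.*g1")
  ragged <- withr::local_tempfile()
  writeLines(c("Gene\tA_x\tB_y", "g1\t1"), ragged)
  expect_error(read_magic_matrix(ragged), "ragged row.*line 2")
  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_error(read_magic_matrix(empty), "empty")
})

test_that("matrix file names follow the domain convention", {
  expect_equal(magic_matrix_filename("gene1kb"), "1Kb_gene.mtx")
  expect_equal(magic_matrix_filename("gene5kb"), "5Kb_gene.mtx")
  expect_equal(magic_matrix_filename("promoter"), "1Kb_promoter.mtx")
  expect_equal(magic_matrix_filename("gene1kb", with_engineered = TRUE),
               "1Kb_gene_with_engineered_factors.mtx")
})
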