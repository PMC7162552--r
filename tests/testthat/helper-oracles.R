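# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# O(P * G) interval scan: max signal over peaks intersecting [start, end)
# by >= 1 bp, checking every peak explicitly.
bf_max_signal <- function(peaks, start, end) {
  best <- 0
  for (i in seq_len(nrow(peaks))) {
    a <- peaks$start[i]; b <- peaks$end[i]
    if (max(a, start) < min(b, end)) best <- max(best, peaks$signal_value[i])
  }
  best
}

# Brute-force ECDF sup-difference: evaluate B(c) - Q(c) at every distinct
# background value with plain means.
bf_dsup <- function(b, q) {
  grid <- sort(unique(b))
  diffs <- vapply(grid, function(cc) mean(b <= cc) - mean(q <= cc),
                  numeric(1L))
  best <- max(c(0, diffs))
  arg <- if (best <= 0) -Inf else grid[which(diffs == best)[1L]]
  list(d_sup = best, arg_dsup = arg)
}

# Hand-rolled Benjamini-Hochberg step-up with monotonicity enforcement.
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  stepped <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  out <- numeric(m)
  out[ord] <- pmin(1, adj)
  out
}

# ROC AUC as the normalized Mann-Whitney count over all (positive,
# negative) score pairs; ties count one half.
bf_roc_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (sp in pos) for (sn in neg) {
    total <- total + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# A 3-gene annotation and two small narrowPeak tracks on disk; cell values
# are hand-computable.
toy_build_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- data.frame(
    symbol = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(10000, 40000, 10000),
    tx_end = c(15000, 44000, 12000),
    stringsAsFactors = FALSE
  )
  write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  np <- function(chrom, start, end, signal) {
    sprintf("%s\t%d\t%d\tpk\t0\t.\t%g\t-1\t-1\t-1", chrom, start, end,
            signal)
  }
  # track 1: two peaks in gA's 1kb domain (max 7.5), one in gB's
  writeLines(c(np("chr1", 10500, 10700, 3.2),
               np("chr1", 14000, 14200, 7.5),
               np("chr1", 41000, 41100, 2.0)),
             file.path(dir, "t1.narrowPeak"))
  # track 2: 1 bp straddle into gA's domain (ends at 9001; domain starts
  # 9000), plus interior peak with lower signal; nothing for gB/gC
  writeLines(c(np("chr1", 8800, 9001, 9.0),
               np("chr1", 12000, 12100, 4.0)),
             file.path(dir, "t2.narrowPeak"))
  manifest <- data.frame(
    file_path = c("t1.narrowPeak", "t2.narrowPeak"),
    factor = c("TFA", "TFB"),
    description = c("cellX", "cellY"),
    engineered = c(0L, 0L),
    stringsAsFactors = FALSE
  )
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(dir = dir, annotation = file.path(dir, "annotation.tsv"),
       manifest = file.path(dir, "manifest.tsv"))
}

# Small in-memory matrix with hand-set signal columns.
toy_matrix <- function(values) {
  magic_matrix(values)
}

# A matrix + lists pair where one track ("PLANT_t") has strongly shifted
# query signals; deterministic under seed.
toy_planted <- function(seed = 1L, n_genes = 500L, query_size = 60L,
                        effect = 6) {
  sim <- simulate_magic_matrix(magic_scenario(
    n_genes = n_genes, n_tracks = 8L, query_size = query_size,
    effect = effect, seed = seed))
  sim
}
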