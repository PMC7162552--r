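# The enrichment statistic: per-Factor comparison of query vs background
# ChIP-signal ECDFs, triage, KS p-values, BH correction, tail ratio, Score.

#' Read a gene lists file
#'
#' Tab-delimited with a header row of unique column names. Column 1 is the
#' background list (all genes relevant to the experiment); subsequent
#' columns are query lists (each a subset of the background). Empty cells
#' pad shorter columns.
#'
#' @param path Path to the lists file.
#' @param matrix Optional [magic_matrix]; when supplied the lists are
#'   immediately filtered against it (see [filter_gene_lists()]).
#' @return A `magic_gene_lists` object.
#' @export
read_gene_lists <- function(path, matrix = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("lists file '", path, "' is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (anyDuplicated(header)) {
    stop("lists file must have unique names for each column; duplicated: ",
         header[duplicated(header)][1L])
  }
  cols <- lapply(seq_along(header), function(j) {
    v <- vapply(fields[-1L], function(f) {
      if (length(f) >= j) f[[j]] else ""
    }, character(1L))
    v[nzchar(trimws(v))]
  })
  names(cols) <- header
  lists <- magic_gene_lists(background = cols[[1L]], queries = cols[-1L],
                            background_name = header[1L])
  if (!is.null(matrix)) lists <- filter_gene_lists(lists, matrix)
  lists
}

#' Gene list set: background plus named query lists
#'
#' @param background Character vector of gene symbols (the gene universe of
#'   the experiment). Duplicates are dropped with a warning.
#' @param queries Named list of character vectors, each a subset of the
#'   background; query genes absent from the background are dropped with a
#'   warning.
#' @param background_name Label for the background column in written output.
#' @return A `magic_gene_lists` object with elements `background`,
#'   `queries`, `background_name`, `triaged_genes` (genes removed because
#'   absent from a matrix; empty until filtered).
#' @export
magic_gene_lists <- function(background, queries = list(),
                             background_name = "Background") {
  if (length(queries) > 0L && is.null(names(queries))) {
    stop("query lists must be named")
  }
  if (anyDuplicated(names(queries)) ||
      any(names(queries) == background_name)) {
    stop("lists must have unique names for each column")
  }
  if (anyDuplicated(background)) {
    warning("dropping ", sum(duplicated(background)),
            " duplicated background gene(s)")
    background <- unique(background)
  }
  queries <- lapply(stats::setNames(names(queries), names(queries)),
                    function(nm) {
    q <- queries[[nm]]
    if (anyDuplicated(q)) {
      warning("dropping ", sum(duplicated(q)),
              " duplicated gene(s) in query '", nm, "'")
      q <- unique(q)
    }
    outside <- setdiff(q, background)
    if (length(outside) > 0L) {
      warning(length(outside), " gene(s) in query '", nm,
              "' absent from the background list were dropped")
      q <- intersect(q, background)
    }
    if (length(q) == 0L) stop("query '", nm, "' is empty after filtering")
    q
  })
  structure(list(background = background, queries = queries,
                 background_name = background_name,
                 triaged_genes = character()),
            class = "magic_gene_lists")
}

#' Filter gene lists against a matrix
#'
#' Genes absent from the matrix are moved to `triaged_genes` and removed
#' from the background and every query. The resulting accepted lists are
#' what all statistics are computed on.
#'
#' @param lists A `magic_gene_lists` object.
#' @param matrix A [magic_matrix].
#' @return The filtered `magic_gene_lists`.
#' @export
filter_gene_lists <- function(lists, matrix) {
  known <- matrix_genes(matrix)
  dropped <- setdiff(unique(c(lists$background,
                              unlist(lists$queries, use.names = FALSE))),
                     known)
  background <- intersect(lists$background, known)
  if (length(background) == 0L) {
    stop("background list shares no genes with the matrix")
  }
  queries <- lapply(stats::setNames(names(lists$queries),
                                    names(lists$queries)), function(nm) {
    q <- intersect(lists$queries[[nm]], known)
    if (length(q) == 0L) stop("query '", nm, "' is empty after filtering")
    q
  })
  out <- lists
  out$background <- background
  out$queries <- queries
  out$triaged_genes <- sort(unique(c(lists$triaged_genes, dropped)))
  out
}

#' @export
print.magic_gene_lists <- function(x, ...) {
  cat("magic_gene_lists: background of", length(x$background), "genes;",
      length(x$queries), "query list(s)\n")
  for (nm in names(x$queries)) {
    cat("  ", nm, ": ", length(x$queries[[nm]]), " genes\n", sep = "")
  }
  if (length(x$triaged_genes) > 0L) {
    cat("  triaged (absent from matrix):", length(x$triaged_genes), "genes\n")
  }
  invisible(x)
}

#' ECDF sup-difference statistic
#'
#' Computes the supremum over signal values c of `B(c) - Q(c)`, where `B(c)`
#' is the fraction of the N background genes with ChIP signal <= c and
#' `Q(c)` the same for the X query genes. The evaluation grid is the set of
#' distinct background signals plus a point below the minimum where both
#' cumulatives are 0, so the statistic is always >= 0. `arg_dsup` (the
#' "Critical ChIP") is the smallest c attaining the supremum; when the
#' supremum is only attained below the support, `arg_dsup` is `-Inf` and
#' every query gene lies above it.
#'
#' @param b Numeric vector of background signals (length N >= 1).
#' @param q Numeric vector of query signals (length X >= 1).
#' @return List with `d_sup`, `arg_dsup`, and the step curves `grid`,
#'   `b_cdf`, `q_cdf`.
#' @examples
#' ecdf_dsup(c(1, 2, 3, 4), c(3, 4))  # d_sup = 0.5 at c = 2
#' @export
ecdf_dsup <- function(b, q) {
  stopifnot(length(b) >= 1L, length(q) >= 1L)
  grid <- sort(unique(b))
  g <- length(grid)
  b_cdf <- cumsum(tabulate(findInterval(b, grid), g)) / length(b)
  fi <- findInterval(q, grid)
  below <- sum(fi == 0L)
  q_cdf <- (below + cumsum(tabulate(fi, g))) / length(q)
  diffs <- b_cdf - q_cdf
  best <- max(diffs)
  if (best <= 0) {
    list(d_sup = 0, arg_dsup = -Inf, grid = grid, b_cdf = b_cdf,
         q_cdf = q_cdf)
  } else {
    list(d_sup = best, arg_dsup = grid[which.max(diffs)], grid = grid,
         b_cdf = b_cdf, q_cdf = q_cdf)
  }
}

# Survival function of the Kolmogorov distribution, P(K > lambda).
# Alternating-series form for large lambda; Jacobi-theta dual form for small
# lambda where the alternating series converges slowly.
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  if (lambda < 1) {
    k <- 1:20
    cdf <- sqrt(2 * pi) / lambda *
      sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2)))
    return(min(1, max(0, 1 - cdf)))
  }
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
}

#' Kolmogorov-Smirnov p-value for the sup-difference
#'
#' The test is performed on N, X and `d_sup` via the effective sample size
#' `N_e = N * X / (N + X)`. Modes:
#' * `"asymptotic"` (default): the two-sided Kolmogorov survival function
#'   evaluated at `sqrt(N_e) * d_sup`;
#' * `"onesided"`: the one-sided exponential bound
#'   `exp(-2 * N_e * d_sup^2)`;
#' * `"nested"`: the one-sided bound with the finite-population correction
#'   for a query drawn without replacement from the background,
#'   `exp(-2 * (N * X / (N - X)) * d_sup^2)` — the correct asymptotic
#'   scaling when Q is a subset of B, which the two modes above ignore;
#' * `"permutation"`: empirical tail probability of `d_sup` under resampling
#'   X genes without replacement from the background (requires `b`); the
#'   calibrated reference for the nested sampling scheme.
#'
#' The default is deliberately the conventional two-sample form (it is what
#' a stock KS routine applied to N, X and D would give) and is conservative
#' under nested sampling; use `"nested"` or `"permutation"` for calibrated
#' p-values.
#'
#' @param n Background size N.
#' @param x Query size X.
#' @param d_sup Observed statistic in `[0, 1]`.
#' @param mode P-value mode, see above.
#' @param b Background signal vector (permutation mode only).
#' @param n_perm Number of permutation resamples.
#' @return A p-value in `[0, 1]`.
#' @export
ks_pvalue <- function(n, x, d_sup,
                      mode = c("asymptotic", "onesided", "nested",
                               "permutation"),
                      b = NULL, n_perm = 10000L) {
  mode <- match.arg(mode)
  if (!is.finite(d_sup) || d_sup < 0 || d_sup > 1) {
    stop("d_sup must lie in [0, 1]")
  }
  stopifnot(n >= 1L, x >= 1L)
  n_e <- n * x / (n + x)
  switch(mode,
    asymptotic = kolmogorov_sf(sqrt(n_e) * d_sup),
    onesided = min(1, exp(-2 * n_e * d_sup^2)),
    nested = if (x >= n) 1 else min(1, exp(-2 * n * x / (n - x) * d_sup^2)),
    permutation = {
      if (is.null(b) || length(b) != n) {
        stop("permutation mode requires the background signal vector b")
      }
      draws <- perm_dsup_null(b, x, n_perm)
      (1 + sum(draws >= d_sup - 1e-12)) / (n_perm + 1)
    })
}

#' Null distribution of the sup-difference under resampling
#'
#' Draws `n_perm` query sets of size `x` without replacement from the
#' background signals and returns the sup-difference statistic of each.
#'
#' @inheritParams ks_pvalue
#' @return Numeric vector of length `n_perm`.
#' @export
perm_dsup_null <- function(b, x, n_perm = 10000L) {
  stopifnot(x >= 1L, x <= length(b))
  grid <- sort(unique(b))
  idx <- findInterval(b, grid)
  b_cdf <- cumsum(tabulate(idx, length(grid))) / length(b)
  cpp_perm_dsup(as.integer(idx), b_cdf, as.integer(x), as.integer(n_perm))
}

#' Tail-enrichment statistics
#'
#' Compares the mean of the top `n = 0.05 X` ChIP signals in the query list
#' (length X) with the mean of the top n signals in the background
#' population. `n` is `ceiling(0.05 * X)` with a floor of 1 so the tail is
#' never empty. A background tail mean of 0 yields ratio 0 (the track
#' carries no signal).
#'
#' @inheritParams ecdf_dsup
#' @return List with `n_tail`, `obs_tail_mean`, `exp_tail_mean`, `ratio`.
#' @export
tail_stats <- function(b, q) {
  n <- max(1L, as.integer(ceiling(0.05 * length(q))))
  obs <- mean(sort(q, decreasing = TRUE)[seq_len(n)])
  expc <- mean(sort(b, decreasing = TRUE)[seq_len(min(n, length(b)))])
  list(n_tail = n, obs_tail_mean = obs, exp_tail_mean = expc,
       ratio = if (expc == 0) 0 else obs / expc)
}

#' Target genes of a Factor
#'
#' The query genes whose ChIP signal is strictly greater than the Critical
#' ChIP (`arg_dsup`).
#'
#' @param query_signals Named numeric vector of query-gene signals.
#' @param arg_dsup Critical ChIP value.
#' @return Named numeric vector, the targeted subset of `query_signals`.
#' @export
magic_targets <- function(query_signals, arg_dsup) {
  query_signals[query_signals > arg_dsup]
}

#' Ranking score
#'
#' `S = -log10(P_corr) * r`. `P_corr` is floored at the smallest positive
#' normalized double before taking the log, so a zero corrected p-value
#' yields a large finite score rather than infinity.
#'
#' @param corrected_p BH-corrected p-value(s) in `(0, 1]`.
#' @param ratio Tail-enrichment ratio(s), >= 0.
#' @return Numeric score(s), >= 0 for `ratio >= 0`.
#' @export
magic_score <- function(corrected_p, ratio) {
  -log10(pmax(corrected_p, .Machine$double.xmin)) * ratio
}

#' Run the enrichment analysis for one query list
#'
#' For every track in the matrix (restricted to the accepted background),
#' computes the ECDF sup-difference `D_sup` and its argument, the target
#' genes (query genes with signal above `arg_dsup`), the triage flag
#' (fewer than five targets removes the track from further consideration),
#' the tail-enrichment ratio, the KS p-value, the Benjamini-Hochberg
#' corrected p-value over the non-triaged tracks, and the Score. Tracks are
#' sorted by descending Score (ties: ascending corrected p, then track id);
#' triaged tracks follow, sorted by descending `D_sup`.
#'
#' @param matrix A [magic_matrix].
#' @param lists A `magic_gene_lists`, already filtered against `matrix`
#'   (unfiltered lists are filtered on the fly).
#' @param query Name of the query list to analyze (default: the first).
#' @param pvalue_mode See [ks_pvalue()].
#' @param fdr_threshold Corrected-p threshold below which a Factor is
#'   flagged significant (default 0.10, i.e. "P_corr < 10%").
#' @param n_perm Permutation resamples (permutation mode only).
#' @return A `magic_report`: list with `query`, `results` (per-track
#'   data.frame), `targets` (per-track named signal vectors), `n_background`,
#'   `n_query`, `query_genes`, `fdr_threshold`.
#' @export
run_query <- function(matrix, lists, query = names(lists$queries)[1L],
                      pvalue_mode = c("asymptotic", "onesided", "nested",
                                      "permutation"),
                      fdr_threshold = 0.10, n_perm = 10000L) {
  pvalue_mode <- match.arg(pvalue_mode)
  stopifnot(inherits(matrix, "magic_matrix"),
            inherits(lists, "magic_gene_lists"),
            fdr_threshold > 0, fdr_threshold < 1)
  if (!all(lists$background %in% matrix_genes(matrix))) {
    lists <- filter_gene_lists(lists, matrix)
  }
  if (!query %in% names(lists$queries)) {
    stop("no query list named '", query, "'")
  }
  bg <- lists$background
  qg <- lists$queries[[query]]
  vals <- matrix$values[bg, , drop = FALSE]
  ids <- colnames(vals)
  n_tr <- length(ids)

  res <- data.frame(
    track_id = ids,
    factor = matrix$tracks$factor,
    description = matrix$tracks$description,
    d_sup = numeric(n_tr), arg_dsup = numeric(n_tr),
    n_tail = integer(n_tr), obs_tail_mean = numeric(n_tr),
    exp_tail_mean = numeric(n_tr), tail_enrichment = numeric(n_tr),
    raw_p = numeric(n_tr), corrected_p = NA_real_, score = NA_real_,
    n_targets = integer(n_tr), triaged = logical(n_tr),
    stringsAsFactors = FALSE
  )
  targets <- vector("list", n_tr)
  names(targets) <- ids
  for (j in seq_len(n_tr)) {
    b <- vals[, j]
    q <- b[qg]
    ed <- ecdf_dsup(b, q)
    ts <- tail_stats(b, q)
    tg <- magic_targets(q, ed$arg_dsup)
    res$d_sup[j] <- ed$d_sup
    res$arg_dsup[j] <- ed$arg_dsup
    res$n_tail[j] <- ts$n_tail
    res$obs_tail_mean[j] <- ts$obs_tail_mean
    res$exp_tail_mean[j] <- ts$exp_tail_mean
    res$tail_enrichment[j] <- ts$ratio
    res$n_targets[j] <- length(tg)
    res$triaged[j] <- length(tg) < 5L || ts$ratio == 0
    res$raw_p[j] <- ks_pvalue(length(b), length(q), ed$d_sup,
                              mode = pvalue_mode, b = b, n_perm = n_perm)
    targets[[j]] <- tg
  }
  keep <- !res$triaged
  if (any(keep)) {
    res$corrected_p[keep] <- stats::p.adjust(res$raw_p[keep], method = "BH")
    res$score[keep] <- magic_score(res$corrected_p[keep],
                                   res$tail_enrichment[keep])
  }
  res$significant <- !res$triaged & res$corrected_p < fdr_threshold
  ord_kept <- which(keep)[order(-res$score[keep], res$corrected_p[keep],
                                res$track_id[keep])]
  ord_tri <- which(!keep)[order(-res$d_sup[!keep], res$track_id[!keep])]
  ord <- c(ord_kept, ord_tri)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(list(query = query, results = res, targets = targets[ord],
                 n_background = length(bg), n_query = length(qg),
                 query_genes = qg, fdr_threshold = fdr_threshold),
            class = "magic_report")
}

#' @export
print.magic_report <- function(x, ...) {
  kept <- x$results[!x$results$triaged, , drop = FALSE]
  cat("magic_report for query '", x$query, "': N = ", x$n_background,
      ", X = ", x$n_query, "\n", sep = "")
  cat(" ", nrow(kept), "non-triaged track(s),",
      sum(x$results$triaged), "triaged,",
      sum(kept$significant), "significant at P_corr <",
      x$fdr_threshold, "\n")
  if (nrow(kept) > 0L) {
    show <- utils::head(kept[, c("track_id", "d_sup", "tail_enrichment",
                                 "corrected_p", "score")], 10L)
    print(show, digits = 4L)
  }
  invisible(x)
}

#' Per-track details of the non-triaged Factors
#' @param report A `magic_report`.
#' @return Data.frame of non-triaged rows in Score order.
#' @export
report_details <- function(report) {
  report$results[!report$results$triaged, , drop = FALSE]
}

#' Best-scoring track per Factor
#'
#' Where the matrix carries multiple tracks for a Factor, the best-scoring
#' non-triaged track represents the Factor; each Factor appears once.
#'
#' @param report A `magic_report`.
#' @return Data.frame with one row per Factor, in Score order.
#' @export
report_summary <- function(report) {
  det <- report_details(report)
  det[!duplicated(det$factor), , drop = FALSE]
}
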