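# Benchmarking protocol for ranked Factor predictions: positive classes
# from protein-link tables, scaled-rank calls vectors, PR/ROC curves and
# AUCs, and the D(r) - r rank-cumulative analysis.

#' Read a protein-links table
#'
#' Whitespace-delimited with a header; requires columns `protein1`,
#' `protein2`, `combined_score` (the STRING layout).
#'
#' @param path Path to the links file.
#' @return Data.frame with those three columns.
#' @export
read_protein_links <- function(path) {
  # colClasses guards symbols like "T" or "F" from logical coercion
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$combined_score <- as.numeric(df$combined_score)
  required <- c("protein1", "protein2", "combined_score")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("links file '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df[required]
}

#' Positive class from a protein-links table
#'
#' The positive class for evaluating a manipulated Factor is the Factor
#' itself plus all its potential interactors (PIs): partners linked to it
#' with a combined score strictly greater than `threshold` (default 300,
#' the 75th percentile of STRING combined scores). Matching is
#' case-insensitive; symmetric duplicate links count once.
#'
#' @param links Data.frame with `protein1`, `protein2`, `combined_score`
#'   (or a path, see [read_protein_links()]).
#' @param factor The manipulated Factor's symbol.
#' @param threshold Combined-score cutoff (strict inequality).
#' @return Character vector of positive-class symbols (Factor first).
#' @export
positive_class <- function(links, factor, threshold = 300) {
  if (is.character(links) && length(links) == 1L) {
    links <- read_protein_links(links)
  }
  lf <- tolower(factor)
  hit_a <- tolower(links$protein1) == lf
  hit_b <- tolower(links$protein2) == lf
  if (!any(hit_a | hit_b)) {
    warning("factor '", factor, "' absent from links table; ",
            "positive class is the factor alone")
    return(factor)
  }
  strong <- links$combined_score > threshold
  partners <- c(links$protein2[hit_a & strong],
                links$protein1[hit_b & strong])
  partners <- partners[!duplicated(tolower(partners))]
  partners <- partners[tolower(partners) != lf]
  c(factor, partners)
}

#' Calls vector over a ranked Factor list
#'
#' Labels every entry of a best-first ranked list positive or negative by
#' case-insensitive membership in the positive class, and attaches scaled
#' ranks `i / m` for rank i of m. A Factor appearing at several ranks
#' (multiple library entries) contributes one call per entry.
#'
#' @param ranked Character vector, best prediction first.
#' @param positives Character vector of positive-class symbols.
#' @return Data.frame with columns `factor`, `positive`, `scaled_rank`.
#' @export
calls_vector <- function(ranked, positives) {
  stopifnot(length(ranked) >= 1L)
  pos <- tolower(ranked) %in% tolower(positives)
  if (!any(pos)) {
    warning("no positive-class member present in the ranked list")
  }
  data.frame(factor = ranked, positive = pos,
             scaled_rank = seq_along(ranked) / length(ranked),
             stringsAsFactors = FALSE)
}

#' PR and ROC curves for a calls vector
#'
#' Treats `1 - scaled_rank` as the prediction score (higher is better) and
#' builds the standard ROC and precision-recall point sets by sweeping the
#' ranked list; no class balancing is performed. AUCs are trapezoidal areas
#' over the emitted points; `pr_mode = "average_precision"` instead returns
#' the mean precision at the positive ranks.
#'
#' @param calls Data.frame from [calls_vector()] (needs at least one
#'   positive and one negative call).
#' @param pr_mode `"trapezoid"` (default) or `"average_precision"`.
#' @return List with `roc` (FPR/TPR points), `pr` (recall/precision
#'   points), `roc_auc`, `pr_auc`.
#' @export
pr_roc <- function(calls, pr_mode = c("trapezoid", "average_precision")) {
  pr_mode <- match.arg(pr_mode)
  pos <- calls$positive[order(calls$scaled_rank)]
  p <- sum(pos)
  n <- sum(!pos)
  if (p == 0L) stop("calls vector contains no positive calls")
  if (n == 0L) stop("calls vector contains no negative calls")
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  roc <- data.frame(fpr = c(0, fp / n), tpr = c(0, tp / p))
  recall <- tp / p
  precision <- tp / seq_along(pos)
  pr <- data.frame(recall = c(0, recall), precision = c(1, precision))
  pr_auc <- if (pr_mode == "trapezoid") {
    trapezoid_auc(pr$recall, pr$precision)
  } else {
    mean(precision[pos])
  }
  list(roc = roc, pr = pr,
       roc_auc = trapezoid_auc(roc$fpr, roc$tpr), pr_auc = pr_auc)
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

# Scaled ranks of the positive calls after block collapsing: a contiguous
# run of positive calls is assigned the scaled rank of its first element.
block_positive_ranks <- function(calls) {
  ord <- order(calls$scaled_rank)
  pos <- calls$positive[ord]
  sr <- calls$scaled_rank[ord]
  if (!any(pos)) stop("calls vector contains no positive calls")
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  unlist(lapply(which(runs$values), function(k) {
    rep(sr[starts[k]], runs$lengths[k])
  }), use.names = FALSE)
}

#' Rank-cumulative curve D(r) - r
#'
#' Cumulates the scaled ranks of the positive calls (after block
#' collapsing: contiguous positive runs take the rank of their first
#' element) into D(r), the fraction of positive calls at scaled rank <= r.
#' Uniformly spread positives give D(r) ~ r, so the excess D(r) - r
#' summarizes how early true Factors are ranked; its trapezoidal area over
#' [0, 1] is the curve's AUC. The emitted curve traces the exact step
#' function (each jump contributes two points), so the trapezoidal rule
#' integrates it exactly.
#'
#' @param calls Data.frame from [calls_vector()] with >= 1 positive.
#' @return List with `r`, `excess` (the polyline), `auc`, and
#'   `positive_ranks` (the block-adjusted sample D(r) cumulates).
#' @export
rank_curve <- function(calls) {
  sample <- block_positive_ranks(calls)
  jumps <- sort(unique(sample))
  cdf <- vapply(jumps, function(r) mean(sample <= r), numeric(1L))
  r <- c(0, rep(jumps, each = 2L), 1)
  d <- c(0, as.vector(rbind(c(0, utils::head(cdf, -1L)), cdf)), 1)
  excess <- d - r
  list(r = r, excess = excess, auc = trapezoid_auc(r, d) - 0.5,
       positive_ranks = sample)
}

#' Weight an evaluation metric by the manipulated Factor's rank
#'
#' Multiplies a curve or scalar AUC by the fractional rank
#' `F_R = 1 / integer rank` of the manipulated Factor in the ranked list
#' (rank 1 gives weight 1, rank 2 halves, ...). Matching is
#' case-insensitive on the first occurrence.
#'
#' @param x A scalar (e.g. a PR AUC) or a curve from [rank_curve()].
#' @param ranked The ranked Factor list the metric came from.
#' @param factor The manipulated Factor's symbol.
#' @return `x` scaled by `F_R`; for a curve, `excess` and `auc` are scaled.
#' @export
weight_by_factor_rank <- function(x, ranked, factor) {
  rank <- match(tolower(factor), tolower(ranked))
  if (is.na(rank)) {
    stop("manipulated factor '", factor,
         "' absent from the ranked list; F_R undefined")
  }
  f_r <- 1 / rank
  if (is.list(x)) {
    x$excess <- x$excess * f_r
    x$auc <- x$auc * f_r
    x$f_r <- f_r
    x
  } else {
    x * f_r
  }
}

#' Compare two rank-curve distributions
#'
#' Two-sample two-sided Kolmogorov-Smirnov test on the block-adjusted
#' positive scaled-rank samples of two calls vectors (or two objects from
#' [rank_curve()]).
#'
#' @param a,b Calls vectors or `rank_curve()` results.
#' @return List with `d` (KS statistic) and `p_value`.
#' @export
compare_rank_distributions <- function(a, b) {
  sample_of <- function(x) {
    if (is.data.frame(x)) block_positive_ranks(x) else x$positive_ranks
  }
  sa <- sample_of(a)
  sb <- sample_of(b)
  if (length(sa) == 0L || length(sb) == 0L) {
    stop("both samples must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(sa, sb, exact = FALSE))
  list(d = unname(kt$statistic), p_value = kt$p.value)
}

#' Read ranked Factor lists
#'
#' Tab-delimited with a header; each column is one algorithm's best-first
#' ordered Factor list (shorter columns padded with empty cells).
#'
#' @param path Path to the ranked-lists file.
#' @return Named list of character vectors.
#' @export
read_ranked_lists <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("ranked-lists file '", path, "' is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (anyDuplicated(header)) {
    stop("ranked-lists file must have unique column names")
  }
  out <- lapply(seq_along(header), function(j) {
    v <- vapply(fields[-1L], function(f) {
      if (length(f) >= j) f[[j]] else ""
    }, character(1L))
    v[nzchar(trimws(v))]
  })
  names(out) <- header
  out
}

#' Evaluate ranked Factor lists against a positive class
#'
#' Convenience wrapper: builds a calls vector per ranked list and returns
#' PR/ROC AUCs, the rank-curve AUC, the manipulated Factor's integer rank,
#' and the F_R-weighted PR and rank AUCs.
#'
#' @param ranked_lists Named list of best-first ranked Factor vectors.
#' @param positives Positive-class symbols (see [positive_class()]).
#' @param factor Optional manipulated Factor for the weighted metrics.
#' @param pr_mode See [pr_roc()].
#' @return Data.frame with one row per ranked list.
#' @export
evaluate_rankings <- function(ranked_lists, positives, factor = NULL,
                              pr_mode = "trapezoid") {
  rows <- lapply(names(ranked_lists), function(nm) {
    ranked <- ranked_lists[[nm]]
    calls <- calls_vector(ranked, positives)
    curves <- pr_roc(calls, pr_mode = pr_mode)
    rc <- rank_curve(calls)
    row <- data.frame(algorithm = nm, n_ranked = length(ranked),
                      n_positive = sum(calls$positive),
                      pr_auc = curves$pr_auc, roc_auc = curves$roc_auc,
                      rank_auc = rc$auc, stringsAsFactors = FALSE)
    if (!is.null(factor)) {
      rank <- match(tolower(factor), tolower(ranked))
      row$factor_rank <- rank
      row$weighted_pr_auc <- if (is.na(rank)) NA_real_ else
        curves$pr_auc / rank
      row$weighted_rank_auc <- if (is.na(rank)) NA_real_ else rc$auc / rank
    }
    row
  })
  do.call(rbind, rows)
}
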