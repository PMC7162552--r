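# The output surface: details/summary tables, GMX driver files, auxiliary
# raw results, target-gene files, and CDF diagnostics.

DETAILS_COLUMNS <- c("Factor", "Description", "Critical ChIP",
                     "Obs Tail Mean", "Exp Tail Mean", "Tail Enrichment",
                     "Raw P", "Corrected P", "Score")

details_frame <- function(rows, fdr_threshold) {
  data.frame(
    "Factor" = rows$factor,
    "Description" = rows$description,
    "Critical ChIP" = rows$arg_dsup,
    "Obs Tail Mean" = rows$obs_tail_mean,
    "Exp Tail Mean" = rows$exp_tail_mean,
    "Tail Enrichment" = rows$tail_enrichment,
    "Raw P" = rows$raw_p,
    "Corrected P" = rows$corrected_p,
    "Score" = rows$score,
    "Significant" = ifelse(!is.na(rows$corrected_p) &
                             rows$corrected_p < fdr_threshold, "*", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-track details table
#'
#' Tab-delimited table of all non-triaged tracks in Score order, with the
#' columns Factor, Description, Critical ChIP, Obs Tail Mean, Exp Tail Mean,
#' Tail Enrichment, Raw P, Corrected P, Score, plus a plain-text
#' `Significant` flag column marking rows with corrected p below the
#' report's FDR threshold.
#'
#' @param report A `magic_report` (see [run_query()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_details <- function(report, path) {
  det <- report_details(report)
  if (nrow(det) == 0L) {
    warning("no non-triaged tracks; writing header-only details table")
  }
  write_tsv(details_frame(det, report$fdr_threshold), path)
}

#' Write the best-track-per-Factor summary table
#'
#' Same layout as [write_details()] but with one row per Factor (its
#' best-scoring non-triaged track).
#'
#' @inheritParams write_details
#' @return `path`, invisibly.
#' @export
write_summary <- function(report, path) {
  write_tsv(details_frame(report_summary(report), report$fdr_threshold),
            path)
}

#' Write the GSEA driver file (GMX format)
#'
#' Column-oriented gene-set file: column 1 is the background list, column 2
#' the query list, and one further column per significant Factor (corrected
#' p below the FDR threshold) holding that Factor's target genes — the query
#' genes with ChIP signal above the Critical ChIP of the Factor's
#' best-scoring track. Row 1 holds set names, row 2 descriptions; shorter
#' columns are padded with empty cells.
#'
#' @param report A `magic_report`.
#' @param lists The `magic_gene_lists` the report was computed from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmx <- function(report, lists, path) {
  summ <- report_summary(report)
  sig <- summ[!is.na(summ$corrected_p) &
                summ$corrected_p < report$fdr_threshold, , drop = FALSE]
  cols <- c(
    list(lists$background, report$query_genes),
    lapply(sig$track_id, function(id) names(report$targets[[id]]))
  )
  headers <- c(lists$background_name, report$query, sig$factor)
  descs <- c("background list", "query list",
             if (nrow(sig) > 0L) paste0("targets|", sig$track_id))
  depth <- max(lengths(cols))
  mat <- vapply(cols, function(v) c(v, rep("", depth - length(v))),
                character(depth))
  lines <- c(paste(headers, collapse = "\t"),
             paste(descs, collapse = "\t"),
             apply(matrix(mat, nrow = depth), 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write auxiliary raw results and triage files
#'
#' Emits, under `dir`:
#' * `<query>_raw_results.csv` — the details layout for **all** tracks,
#'   triaged included, with a `KS D` column; triaged tracks carry their D
#'   with a negative sign (the triage sorting convention);
#' * `<query>_Sub_Matrix.txt` — the matrix restricted to the query genes;
#' * `Triaged_Factors.txt` — track ids removed by triage;
#' * `Triaged_Genes.txt` — query genes absent from the matrix.
#'
#' @param report A `magic_report`.
#' @param matrix The [magic_matrix] analyzed.
#' @param lists The `magic_gene_lists` used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_auxiliary <- function(report, matrix, lists, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- report$results
  raw <- details_frame(res, report$fdr_threshold)
  raw <- cbind("KS D" = ifelse(res$triaged, -res$d_sup, res$d_sup), raw)
  raw$Triaged <- ifelse(res$triaged, "yes", "")
  utils::write.csv(raw, file.path(dir, paste0(report$query,
                                              "_raw_results.csv")),
                   quote = FALSE, row.names = FALSE)
  sub <- magic_matrix(matrix$values[report$query_genes, , drop = FALSE],
                      matrix$tracks)
  write_magic_matrix(sub, file.path(dir, paste0(report$query,
                                                "_Sub_Matrix.txt")))
  writeLines(res$track_id[res$triaged],
             file.path(dir, "Triaged_Factors.txt"))
  writeLines(lists$triaged_genes, file.path(dir, "Triaged_Genes.txt"))
  invisible(dir)
}

#' Write per-Factor target-gene files
#'
#' One comma-separated file per significant Factor (corrected p below the
#' FDR threshold), named `<Factor>.csv`, listing each target gene and its
#' matrix ChIP value.
#'
#' @inheritParams write_auxiliary
#' @return `dir`, invisibly.
#' @export
write_target_data <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- report_summary(report)
  sig <- summ[!is.na(summ$corrected_p) &
                summ$corrected_p < report$fdr_threshold, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    tg <- report$targets[[sig$track_id[i]]]
    utils::write.csv(
      data.frame(gene = names(tg), chip_value = unname(tg)),
      file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", sig$factor[i]),
                            ".csv")),
      quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' CDF diagnostic plot for one track
#'
#' Draws the background cumulative (black) and query cumulative (red)
#' against ChIP signal, a vertical blue line at the Critical ChIP
#' (`arg_dsup`), ticks on the x-axis for every query (red) and background
#' (black) gene, and "lollipop" markers on the `n = 0.05 X` best-signal
#' query and background genes. The file is named `<rank>_<factor>.pdf`
#' where rank is the track's Score rank.
#'
#' @param matrix A [magic_matrix].
#' @param lists The filtered `magic_gene_lists`.
#' @param report A `magic_report`.
#' @param track_id Track to plot (must be non-triaged).
#' @param dir Output directory.
#' @return The figure path, invisibly.
#' @export
plot_cdf <- function(matrix, lists, report, track_id, dir) {
  det <- report_details(report)
  rank <- match(track_id, det$track_id)
  if (is.na(rank)) stop("track '", track_id, "' is triaged or unknown")
  row <- det[rank, ]
  b <- matrix$values[lists$background, track_id]
  q <- b[report$query_genes]
  ed <- ecdf_dsup(b, q)
  n <- row$n_tail
  path <- file.path(dir, paste0(rank, "_",
                                gsub("[^A-Za-z0-9._-]", "_", row$factor),
                                ".pdf"))
  grDevices::pdf(path, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = range(c(0, ed$grid)), ylim = c(0, 1.05),
                 xlab = "ChIP signal", ylab = "cumulative fraction",
                 main = paste0(rank, ": ", track_id))
  graphics::lines(stats::stepfun(ed$grid, c(0, ed$b_cdf)), col = "black",
                  do.points = FALSE)
  graphics::lines(stats::stepfun(ed$grid, c(0, ed$q_cdf)), col = "red",
                  do.points = FALSE)
  if (is.finite(row$arg_dsup)) {
    graphics::abline(v = row$arg_dsup, col = "blue")
  }
  graphics::rug(b, col = "black", ticksize = 0.02)
  graphics::rug(q, col = "red", ticksize = 0.035)
  top_q <- sort(q, decreasing = TRUE)[seq_len(n)]
  top_b <- sort(b, decreasing = TRUE)[seq_len(n)]
  graphics::points(top_q, rep(0.02, n), pch = 21, bg = "red", col = "red")
  graphics::points(top_b, rep(0.05, n), pch = 21, bg = "black",
                   col = "black")
  graphics::legend("bottomright",
                   legend = c("background", "query", "Critical ChIP"),
                   col = c("black", "red", "blue"), lty = 1, bty = "n")
  invisible(path)
}

#' Bar graph of significant Factor Scores
#'
#' @param report A `magic_report`.
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
plot_summary_bars <- function(report, path) {
  summ <- report_summary(report)
  sig <- summ[!is.na(summ$corrected_p) &
                summ$corrected_p < report$fdr_threshold, , drop = FALSE]
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  if (nrow(sig) == 0L) {
    graphics::plot.new()
    graphics::title(main = "no significant Factors")
  } else {
    graphics::barplot(sig$score, names.arg = sig$factor, las = 2,
                      ylab = "Score",
                      main = paste0(report$query, ": P_corr < ",
                                    report$fdr_threshold * 100, "%"))
  }
  invisible(path)
}

#' Write the original lists filtered for matrix genes
#'
#' Same column layout as the input lists file, restricted to accepted genes.
#'
#' @param lists A filtered `magic_gene_lists`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accepted_lists <- function(lists, path) {
  cols <- c(list(lists$background), lists$queries)
  headers <- c(lists$background_name, names(lists$queries))
  depth <- max(lengths(cols))
  mat <- vapply(cols, function(v) c(v, rep("", depth - length(v))),
                character(depth))
  writeLines(c(paste(headers, collapse = "\t"),
               apply(matrix(mat, nrow = depth), 1L, paste,
                     collapse = "\t")),
             path)
  invisible(path)
}

#' Run the full analysis and write the output bundle
#'
#' Analyzes every query list in `lists` against `matrix` and populates
#' `out_dir` with the complete output surface:
#' * `Accepted_Lists.txt` — the input lists filtered for matrix genes;
#' * `Platform_Matrix.txt` — the matrix filtered for the background genes;
#' * per query, a directory `<query>/` with `<query>_Details.txt`,
#'   `<query>_Summary.txt`, `<query>_Drivers.gmx`, `Auxiliary_Files/`
#'   (raw results, sub-matrix, triage listings), `Target_Data/`
#'   (per-significant-Factor CSVs), and — when `plots = TRUE` —
#'   `<query>_summary.pdf` and a `CDFs/` directory of per-track figures.
#'
#' @param matrix A [magic_matrix] or path to a matrix file.
#' @param lists A `magic_gene_lists` or path to a lists file.
#' @param out_dir Output directory (created if needed).
#' @param queries Query names to analyze (default all).
#' @param plots Emit PDF figures? Off by default to keep the pipeline
#'   headless.
#' @param max_cdf_plots Cap on per-track CDF figures per query.
#' @inheritParams run_query
#' @return Named list of `magic_report`s, invisibly.
#' @export
run_magic <- function(matrix, lists, out_dir, queries = NULL,
                      pvalue_mode = "asymptotic", fdr_threshold = 0.10,
                      n_perm = 10000L, plots = FALSE,
                      max_cdf_plots = 25L) {
  if (is.character(matrix)) matrix <- read_magic_matrix(matrix)
  if (is.character(lists)) lists <- read_gene_lists(lists)
  lists <- filter_gene_lists(lists, matrix)
  if (is.null(queries)) queries <- names(lists$queries)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_accepted_lists(lists, file.path(out_dir, "Accepted_Lists.txt"))
  platform <- magic_matrix(matrix$values[lists$background, , drop = FALSE],
                           matrix$tracks)
  write_magic_matrix(platform, file.path(out_dir, "Platform_Matrix.txt"))
  reports <- list()
  for (qn in queries) {
    rep <- run_query(matrix, lists, qn, pvalue_mode = pvalue_mode,
                     fdr_threshold = fdr_threshold, n_perm = n_perm)
    qdir <- file.path(out_dir, qn)
    dir.create(qdir, showWarnings = FALSE, recursive = TRUE)
    write_details(rep, file.path(qdir, paste0(qn, "_Details.txt")))
    write_summary(rep, file.path(qdir, paste0(qn, "_Summary.txt")))
    write_gmx(rep, lists, file.path(qdir, paste0(qn, "_Drivers.gmx")))
    write_auxiliary(rep, matrix, lists, file.path(qdir, "Auxiliary_Files"))
    write_target_data(rep, file.path(qdir, "Target_Data"))
    if (plots) {
      plot_summary_bars(rep, file.path(qdir, paste0(qn, "_summary.pdf")))
      cdf_dir <- file.path(qdir, "CDFs")
      dir.create(cdf_dir, showWarnings = FALSE)
      det <- report_details(rep)
      for (id in utils::head(det$track_id, max_cdf_plots)) {
        plot_cdf(matrix, lists, rep, id, cdf_dir)
      }
    }
    reports[[qn]] <- rep
  }
  invisible(reports)
}
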