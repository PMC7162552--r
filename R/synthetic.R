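# Desk-scale synthetic fixtures with planted structure: signal matrices,
# narrowPeak tracks that rebuild them exactly, gene lists, ranked lists.

#' Parameters of a planted-enrichment simulation
#'
#' Each track draws per-gene signals from a zero-inflated heavy-tailed law:
#' with probability `zero_fraction` a gene has signal 0 (no detectable
#' peak), otherwise a log-normal draw (`meanlog`, `sdlog`) — mimicking ChIP
#' tracks with many sites of very low but detectable signal. One designated
#' track is "planted": the query genes' signals on it are shifted by
#' `effect` (multiplicative: nonzero signals scaled `effect`-fold;
#' additive: `effect` added to every query signal). `effect = 0` disables
#' planting and is the null scenario.
#'
#' @param n_genes Number of genes.
#' @param n_tracks Number of ChIP tracks.
#' @param query_size Number of query genes (drawn uniformly).
#' @param zero_fraction Per-track probability of a zero signal, in `[0, 1)`.
#' @param meanlog,sdlog Log-normal parameters of the nonzero signals.
#' @param planted_track Index of the planted track.
#' @param effect Effect size (fold change for multiplicative planting).
#' @param effect_type `"multiplicative"` or `"additive"`.
#' @param seed Integer seed; every generator call is reproducible under it.
#' @return A `magic_scenario` list.
#' @export
magic_scenario <- function(n_genes = 2000L, n_tracks = 50L,
                           query_size = 100L, zero_fraction = 0.6,
                           meanlog = 1, sdlog = 1, planted_track = 1L,
                           effect = 3,
                           effect_type = c("multiplicative", "additive"),
                           seed = 1L) {
  effect_type <- match.arg(effect_type)
  stopifnot(n_genes >= 2L, n_tracks >= 1L, query_size >= 1L,
            zero_fraction >= 0, zero_fraction < 1,
            planted_track >= 1L, planted_track <= n_tracks, effect >= 0,
            sdlog > 0)
  if (query_size > n_genes) {
    stop("query_size cannot exceed n_genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_tracks = as.integer(n_tracks),
                 query_size = as.integer(query_size),
                 zero_fraction = zero_fraction, meanlog = meanlog,
                 sdlog = sdlog, planted_track = as.integer(planted_track),
                 effect = effect, effect_type = effect_type,
                 seed = as.integer(seed)),
            class = "magic_scenario")
}

scenario_gene_names <- function(s) sprintf("g%05d", seq_len(s$n_genes))
scenario_factor_names <- function(s) sprintf("TF%03d", seq_len(s$n_tracks))

#' Simulate a signal matrix with a planted Factor
#'
#' Generates the matrix described by the scenario together with a gene list
#' set whose background is the full gene universe and whose single query
#' ("query") is the planted gene set. All tracks except the planted one are
#' exchangeable with the background.
#'
#' @param scenario A [magic_scenario()].
#' @return List with `matrix` ([magic_matrix]), `lists`
#'   (`magic_gene_lists`), `planted_track_id`, `query_genes`.
#' @export
simulate_magic_matrix <- function(scenario) {
  s <- scenario
  set.seed(s$seed)
  genes <- scenario_gene_names(s)
  factors <- scenario_factor_names(s)
  values <- matrix(0, nrow = s$n_genes, ncol = s$n_tracks,
                   dimnames = list(genes, paste0(factors, "_synthetic")))
  for (j in seq_len(s$n_tracks)) {
    nonzero <- stats::runif(s$n_genes) >= s$zero_fraction
    values[nonzero, j] <- stats::rlnorm(sum(nonzero), s$meanlog, s$sdlog)
  }
  query <- sort(sample(genes, s$query_size))
  if (s$effect > 0) {
    col <- values[query, s$planted_track]
    if (s$effect_type == "multiplicative") {
      col <- col * s$effect
    } else {
      col <- col + s$effect
    }
    values[query, s$planted_track] <- col
  }
  tracks <- data.frame(factor = factors, description = "synthetic",
                       engineered = FALSE, stringsAsFactors = FALSE)
  m <- magic_matrix(values, tracks)
  lists <- magic_gene_lists(background = genes, queries = list(query = query))
  list(matrix = m, lists = lists,
       planted_track_id = colnames(values)[s$planted_track],
       query_genes = query)
}

#' Simulate annotation and narrowPeak files that rebuild a matrix
#'
#' Lays the scenario's genes along one synthetic chromosome with
#' non-overlapping domains and writes, per track, a narrowPeak file with a
#' single peak wholly inside the domain of every gene with nonzero intended
#' signal (signalValue = the intended matrix cell). Running
#' [build_magic_matrix()] on the emitted annotation and manifest therefore
#' reproduces [simulate_magic_matrix()]'s values exactly.
#'
#' @param scenario A [magic_scenario()].
#' @param dir Output directory.
#' @param domain Domain definition the fixture is built for.
#' @return List with `annotation_path`, `manifest_path`, `lists_path`,
#'   `matrix` (the intended [magic_matrix]), and the simulation fields of
#'   [simulate_magic_matrix()].
#' @export
simulate_peak_fixture <- function(scenario, dir,
                                  domain = c("gene1kb", "gene5kb",
                                             "promoter")) {
  domain <- match.arg(domain)
  sim <- simulate_magic_matrix(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  peaks_dir <- file.path(dir, "peaks")
  dir.create(peaks_dir, showWarnings = FALSE)
  s <- scenario
  gene_len <- 2000
  spacing <- 20000  # > 2 * max flank + gene_len: domains never overlap
  ann <- data.frame(
    symbol = scenario_gene_names(s), chrom = "chrS",
    strand = rep_len(c("+", "-"), s$n_genes),
    tx_start = 10000 + (seq_len(s$n_genes) - 1) * spacing,
    tx_end = 10000 + (seq_len(s$n_genes) - 1) * spacing + gene_len,
    stringsAsFactors = FALSE
  )
  ann_path <- file.path(dir, "annotation.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # a short peak at the TSS lies inside all three domain definitions
  peak_start <- ifelse(ann$strand == "+", ann$tx_start, ann$tx_end - 50)
  manifest <- data.frame(
    file_path = file.path("peaks", paste0(colnames(sim$matrix$values),
                                          ".narrowPeak")),
    factor = sim$matrix$tracks$factor,
    description = sim$matrix$tracks$description,
    engineered = 0L, stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(sim$matrix$values))) {
    v <- sim$matrix$values[, j]
    nz <- which(v > 0)
    lines <- sprintf("chrS\t%d\t%d\tpeak%d\t0\t.\t%.17g\t-1\t-1\t-1",
                     as.integer(peak_start[nz]),
                     as.integer(peak_start[nz] + 50), nz, v[nz])
    writeLines(lines, file.path(dir, manifest$file_path[j]))
  }
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lists_path <- file.path(dir, "lists.txt")
  write_accepted_lists(sim$lists, lists_path)
  c(list(annotation_path = ann_path, manifest_path = man_path,
         lists_path = lists_path), sim)
}

#' Simulate a ranked Factor list with planted positives
#'
#' `quality` interpolates between a uniform shuffle (0) and a perfect
#' ordering with all positives first (1): each entry's latent score is
#' `quality * positive_indicator + (1 - quality) * Uniform(0, 1)` and the
#' list is ranked by descending score.
#'
#' @param n_factors Number of ranked entries.
#' @param n_positives Number of planted positive Factors.
#' @param quality In `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `ranked` (character vector, best first) and
#'   `positives`.
#' @export
simulate_ranked_list <- function(n_factors = 100L, n_positives = 10L,
                                 quality = 0.5, seed = 1L) {
  stopifnot(quality >= 0, quality <= 1, n_positives >= 1L,
            n_positives < n_factors)
  set.seed(seed)
  factors <- sprintf("F%04d", seq_len(n_factors))
  positives <- factors[seq_len(n_positives)]
  is_pos <- factors %in% positives
  score <- quality * is_pos + (1 - quality) * stats::runif(n_factors)
  list(ranked = factors[order(-score)], positives = positives)
}

#' Simulate a co-regulated background inside a larger gene universe
#'
#' Emulates an experiment whose expressed genes (the proper background
#' list) are systematically better-bound than the rest of the genome-wide
#' matrix: a fraction of the universe forms the true background, and the
#' nonzero signals of those genes are drawn with a log-mean elevated by
#' `shift` on every track. The query is a uniform draw from the true
#' background, i.e. null with respect to it — so any significance found
#' when the analysis universe is widened to the full matrix is inflation
#' caused by omitting the background list.
#'
#' @param n_genes Size of the gene universe.
#' @param n_tracks Number of tracks.
#' @param frac_background Fraction of the universe in the true background.
#' @param query_size Query genes drawn from the true background.
#' @param shift Added to `meanlog` for true-background genes.
#' @param zero_fraction,meanlog,sdlog As in [magic_scenario()].
#' @param seed Integer seed.
#' @return List with `matrix`, `true_background`, `query_genes`.
#' @export
simulate_coregulated_matrix <- function(n_genes = 1000L, n_tracks = 20L,
                                        frac_background = 0.5,
                                        query_size = 60L, shift = 1,
                                        zero_fraction = 0.6, meanlog = 0,
                                        sdlog = 1, seed = 1L) {
  stopifnot(frac_background > 0, frac_background < 1,
            query_size <= n_genes * frac_background)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  in_bg <- seq_len(round(n_genes * frac_background))
  mu <- ifelse(seq_len(n_genes) %in% in_bg, meanlog + shift, meanlog)
  values <- matrix(0, n_genes, n_tracks,
                   dimnames = list(genes, sprintf("TF%03d_synthetic",
                                                  seq_len(n_tracks))))
  for (j in seq_len(n_tracks)) {
    nonzero <- stats::runif(n_genes) >= zero_fraction
    values[nonzero, j] <- stats::rlnorm(sum(nonzero), mu[nonzero], sdlog)
  }
  list(matrix = magic_matrix(values), true_background = genes[in_bg],
       query_genes = sort(sample(genes[in_bg], query_size)))
}
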