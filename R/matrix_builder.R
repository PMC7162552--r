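# Building gene x ChIP-track signal matrices from narrowPeak files.
#
# All genomic coordinates are 0-based half-open ([start, end)), the BED
# convention of the narrowPeak inputs. Overlap between a peak and a gene
# domain means intersection by at least 1 bp.

DOMAIN_KINDS <- c("gene1kb", "gene5kb", "promoter")

#' Read a gene annotation table
#'
#' The annotation is a tab-delimited file with a header and the columns
#' `symbol`, `chrom`, `strand`, `tx_start`, `tx_end` (0-based half-open
#' transcript span, promoter through the end of the last exon). Records with
#' a strand other than `+`/`-` are rejected with a warning. Duplicate symbols
#' are collapsed to the union of their isoform extremes (widest span) when
#' all duplicates share a chromosome and strand, otherwise the longest single
#' span is kept; either way one row per symbol survives.
#'
#' @param path Path to the annotation file.
#' @return A `data.frame` with one row per gene symbol.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("symbol", "chrom", "strand", "tx_start", "tx_end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("annotation file '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_gene_annotation(df[required])
}

#' @rdname read_gene_annotation
#' @param annotation A data.frame with columns `symbol`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`.
#' @export
validate_gene_annotation <- function(annotation) {
  df <- as.data.frame(annotation, stringsAsFactors = FALSE)
  bad_strand <- !(df$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    warning(sum(bad_strand), " annotation record(s) with unknown strand rejected")
    df <- df[!bad_strand, , drop = FALSE]
  }
  df$tx_start <- as.numeric(df$tx_start)
  df$tx_end <- as.numeric(df$tx_end)
  if (any(!is.finite(df$tx_start)) || any(!is.finite(df$tx_end)) ||
      any(df$tx_start >= df$tx_end)) {
    stop("annotation requires finite tx_start < tx_end for every record")
  }
  if (anyDuplicated(df$symbol)) {
    df <- resolve_duplicate_symbols(df)
  }
  rownames(df) <- NULL
  df
}

# One row per symbol: union of isoform extremes when chrom+strand agree,
# otherwise the longest individual span.
resolve_duplicate_symbols <- function(df) {
  dup <- unique(df$symbol[duplicated(df$symbol)])
  warning("collapsing ", length(dup), " duplicated gene symbol(s): ",
          paste(utils::head(dup, 5L), collapse = ", "),
          if (length(dup) > 5L) ", ..." else "")
  pieces <- lapply(split(df, df$symbol), function(g) {
    if (nrow(g) == 1L) return(g)
    if (length(unique(g$chrom)) == 1L && length(unique(g$strand)) == 1L) {
      g$tx_start[1L] <- min(g$tx_start)
      g$tx_end[1L] <- max(g$tx_end)
      g[1L, , drop = FALSE]
    } else {
      g[which.max(g$tx_end - g$tx_start), , drop = FALSE]
    }
  })
  out <- do.call(rbind, pieces)
  out[match(unique(df$symbol), out$symbol), , drop = FALSE]
}

#' Compute gene domains
#'
#' Maps each annotated gene to the genomic interval whose ChIP signal is
#' attributed to it:
#' * `gene1kb` — the gene body plus 1 kb flanking sequence either side;
#' * `gene5kb` — the gene body plus 5 kb flanking sequence either side;
#' * `promoter` — 1 kb upstream of the TSS and 300 bp downstream, strand
#'   aware (TSS is `tx_start` on `+`, `tx_end` on `-`; upstream means
#'   5'-ward along the gene's strand).
#'
#' Coordinates are clipped at 0; intervals remain 0-based half-open.
#'
#' @param annotation Validated annotation data.frame
#'   (see [read_gene_annotation()]).
#' @param domain One of `"gene1kb"`, `"gene5kb"`, `"promoter"`.
#' @return The annotation with `start`/`end` columns for the domain.
#' @examples
#' ann <- data.frame(symbol = "g", chrom = "chr1", strand = "+",
#'                   tx_start = 10000, tx_end = 15000)
#' gene_domains(ann, "gene1kb")[, c("start", "end")]  # 9000, 16000
#' @export
gene_domains <- function(annotation, domain = DOMAIN_KINDS) {
  domain <- match.arg(domain)
  ann <- annotation
  if (domain %in% c("gene1kb", "gene5kb")) {
    flank <- if (domain == "gene1kb") 1000 else 5000
    start <- ann$tx_start - flank
    end <- ann$tx_end + flank
  } else {
    plus <- ann$strand == "+"
    tss <- ifelse(plus, ann$tx_start, ann$tx_end)
    start <- ifelse(plus, tss - 1000, tss - 300)
    end <- ifelse(plus, tss + 300, tss + 1000)
  }
  ann$start <- pmax(0, start)
  ann$end <- end
  ann
}

#' Read an ENCODE-style narrowPeak (BED6+4) file
#'
#' Columns: chrom, start, end, name, score, strand, signalValue, pValue,
#' qValue, peak. Lines that cannot be parsed (fewer than 10 fields,
#' non-numeric coordinates or signal, start >= end, negative signal) are
#' skipped and counted in a single warning.
#'
#' @param path Path to the narrowPeak file.
#' @return A `data.frame` with one row per retained peak.
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  ok <- n_fields >= 10L
  parsed <- NULL
  if (any(ok)) {
    m <- do.call(rbind, lapply(fields[ok], function(f) f[1:10]))
    start <- suppressWarnings(as.numeric(m[, 2L]))
    end <- suppressWarnings(as.numeric(m[, 3L]))
    signal <- suppressWarnings(as.numeric(m[, 7L]))
    good <- is.finite(start) & is.finite(end) & start < end &
      is.finite(signal) & signal >= 0
    ok[ok] <- good
    parsed <- data.frame(
      chrom = m[good, 1L],
      start = start[good],
      end = end[good],
      name = m[good, 4L],
      score = suppressWarnings(as.numeric(m[good, 5L])),
      strand = m[good, 6L],
      signal_value = signal[good],
      p_value = suppressWarnings(as.numeric(m[good, 8L])),
      q_value = suppressWarnings(as.numeric(m[good, 9L])),
      peak_offset = suppressWarnings(as.numeric(m[good, 10L])),
      stringsAsFactors = FALSE
    )
  }
  n_skipped <- length(lines) - sum(ok)
  if (n_skipped > 0L) {
    warning("skipped ", n_skipped, " unreadable narrowPeak line(s) in '",
            path, "'")
  }
  if (is.null(parsed)) {
    parsed <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), name = character(),
                         score = numeric(), strand = character(),
                         signal_value = numeric(), p_value = numeric(),
                         q_value = numeric(), peak_offset = numeric(),
                         stringsAsFactors = FALSE)
  }
  parsed
}

#' Maximum peak signal overlapping a domain
#'
#' Returns the largest `signal_value` among peaks whose `[start, end)`
#' interval intersects the half-open `domain` by at least 1 bp, or 0 when no
#' peak overlaps. Peaks are assumed to be on the domain's chromosome.
#'
#' @param peaks A narrowPeak data.frame (see [read_narrowpeak()]).
#' @param domain Numeric length-2 vector `c(start, end)`, 0-based half-open.
#' @return A single non-negative number.
#' @export
max_signal_in_domain <- function(peaks, domain) {
  stopifnot(length(domain) == 2L, domain[1L] < domain[2L])
  hit <- peaks$start < domain[2L] & peaks$end > domain[1L]
  if (!any(hit)) return(0)
  max(peaks$signal_value[hit])
}

#' Read a track manifest
#'
#' Tab-delimited with header and columns `file_path`, `factor`,
#' `description`, `engineered` (0/1 flag: Factor engineered e.g. by CRISPR
#' or stable transfection). Relative `file_path`s are resolved against the
#' manifest's directory.
#'
#' @param path Path to the manifest file.
#' @return A `data.frame` of track metadata.
#' @export
read_track_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("file_path", "factor", "description", "engineered")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("track manifest '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$file_path)
  df$file_path[rel] <- file.path(dirname(path), df$file_path[rel])
  df$engineered <- as.integer(df$engineered) != 0L
  df
}

track_ids <- function(tracks) {
  ifelse(nzchar(tracks$description),
         paste(tracks$factor, tracks$description, sep = "_"),
         tracks$factor)
}

#' Build a signal matrix from narrowPeak tracks
#'
#' For every gene and every retained ChIP-seq track, extracts the highest
#' peak signalValue within the gene's domain, so that each Factor/gene pair
#' is assigned a single signalValue (0 when no peak overlaps, including genes
#' on chromosomes the track does not cover). Tracks flagged as engineered are
#' dropped unless `include_engineered = TRUE`.
#'
#' @param annotation Validated gene annotation (see [read_gene_annotation()]).
#' @param manifest Track manifest data.frame or path (see
#'   [read_track_manifest()]).
#' @param domain Domain definition, one of `"gene1kb"`, `"gene5kb"`,
#'   `"promoter"`.
#' @param include_engineered Keep tracks for engineered Factors?
#' @return A [magic_matrix] object.
#' @export
build_magic_matrix <- function(annotation, manifest,
                               domain = DOMAIN_KINDS,
                               include_engineered = FALSE) {
  domain <- match.arg(domain)
  if (is.character(manifest)) manifest <- read_track_manifest(manifest)
  if (!include_engineered) {
    manifest <- manifest[!manifest$engineered, , drop = FALSE]
  }
  if (nrow(manifest) == 0L) stop("no tracks retained from manifest")
  if (nrow(annotation) == 0L) stop("annotation is empty")
  if (anyDuplicated(paste(manifest$factor, manifest$description))) {
    stop("track manifest has duplicated (factor, description) pairs")
  }
  doms <- gene_domains(annotation, domain)
  # 0-based half-open -> 1-based closed for IRanges
  dom_gr <- GenomicRanges::GRanges(
    doms$chrom, IRanges::IRanges(start = doms$start + 1L, end = doms$end))
  values <- matrix(0, nrow = nrow(doms), ncol = nrow(manifest),
                   dimnames = list(doms$symbol, track_ids(manifest)))
  for (j in seq_len(nrow(manifest))) {
    peaks <- read_narrowpeak(manifest$file_path[j])
    if (nrow(peaks) == 0L) next
    pk_gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
    hits <- GenomicRanges::findOverlaps(dom_gr, pk_gr)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    mx <- tapply(peaks$signal_value[S4Vectors::subjectHits(hits)], qh, max)
    values[as.integer(names(mx)), j] <- mx
  }
  magic_matrix(values, manifest[, c("factor", "description", "engineered")])
}

#' Gene x track signal matrix
#'
#' Container for a genes-by-ChIP-tracks matrix of maximal peak signalValues.
#' Row names are gene symbols; column names are track identifiers of the form
#' `FACTOR_description`. `tracks` carries per-track metadata (`factor`,
#' `description`, optionally `engineered`).
#'
#' @param values Non-negative numeric matrix with unique row and column
#'   names.
#' @param tracks Optional data.frame of track metadata (one row per column
#'   of `values`); reconstructed from column names when absent.
#' @return An object of class `magic_matrix` with elements `values` and
#'   `tracks`.
#' @export
magic_matrix <- function(values, tracks = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("matrix requires gene row names and track column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbol in matrix: ",
         rownames(values)[duplicated(rownames(values))][1L])
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate track identifier in matrix: ",
         colnames(values)[duplicated(colnames(values))][1L])
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("matrix values must be finite and non-negative")
  }
  if (is.null(tracks)) {
    ids <- colnames(values)
    us <- regexpr("_", ids, fixed = TRUE)
    tracks <- data.frame(
      factor = ifelse(us > 0L, substr(ids, 1L, us - 1L), ids),
      description = ifelse(us > 0L, substr(ids, us + 1L, nchar(ids)), ""),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(tracks) == ncol(values))
  rownames(tracks) <- NULL
  structure(list(values = values, tracks = tracks), class = "magic_matrix")
}

#' @export
dim.magic_matrix <- function(x) dim(x$values)

#' @export
print.magic_matrix <- function(x, ...) {
  cat("magic_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "tracks (", length(unique(x$tracks$factor)), "Factors )\n")
  invisible(x)
}

#' Genes covered by a matrix
#' @param m A [magic_matrix].
#' @return Character vector of gene symbols.
#' @export
matrix_genes <- function(m) rownames(m$values)

#' Write / read a matrix file
#'
#' Tab-delimited text: a header row (`Gene` then track identifiers), then one
#' row per gene symbol. Values are written with 17 significant digits so that
#' `read_magic_matrix(write_magic_matrix(m, f))` reproduces `m$values`
#' exactly.
#'
#' @param m A [magic_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_magic_matrix <- function(m, path) {
  header <- paste(c("Gene", colnames(m$values)), collapse = "\t")
  body <- vapply(seq_len(nrow(m$values)), function(i) {
    paste(c(rownames(m$values)[i], sprintf("%.17g", m$values[i, ])),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_magic_matrix
#' @export
read_magic_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("matrix file '", path, "' is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) {
    stop("malformed matrix header in '", path, "': expected gene column ",
         "plus at least one track column")
  }
  ids <- header[-1L]
  widths <- lengths(fields[-1L])
  ragged <- which(widths != length(header))
  if (length(ragged) > 0L) {
    stop("ragged row in matrix file '", path, "' at line ", ragged[1L] + 1L,
         ": expected ", length(header), " fields, found ", widths[ragged[1L]])
  }
  genes <- vapply(fields[-1L], `[[`, character(1L), 1L)
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol in matrix file '", path, "': ",
         genes[duplicated(genes)][1L])
  }
  vals <- vapply(fields[-1L], function(f) as.numeric(f[-1L]),
                 numeric(length(ids)))
  vals <- if (length(ids) == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(vals) <- list(genes, ids)
  if (any(!is.finite(vals))) {
    stop("non-numeric value in matrix file '", path, "'")
  }
  magic_matrix(vals)
}

#' Conventional matrix file name for a domain definition
#' @param domain One of `"gene1kb"`, `"gene5kb"`, `"promoter"`.
#' @param with_engineered Does the matrix include engineered-Factor tracks?
#' @return File name such as `"1Kb_gene.mtx"`.
#' @export
magic_matrix_filename <- function(domain = DOMAIN_KINDS,
                                  with_engineered = FALSE) {
  domain <- match.arg(domain)
  stem <- switch(domain, gene1kb = "1Kb_gene", gene5kb = "5Kb_gene",
                 promoter = "1Kb_promoter")
  paste0(stem, if (with_engineered) "_with_engineered_factors", ".mtx")
}
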