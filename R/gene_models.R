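#' Gene model container
#'
#' A light container for predicted gene structures: one row per gene plus one
#' row per exon. All coordinates are 1-based inclusive genomic positions (the
#' GFF3 convention used throughout the package). Exons of a gene must be
#' sorted by start and non-overlapping, with at least 1 nt between consecutive
#' exons (the intron).
#'
#' @param genes tibble with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end`, and optionally `cds_start`, `cds_end` (genomic bounds of
#'   the coding region; used to anchor flanking regions at the translation
#'   start/stop).
#' @param exons tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(exons)))
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(genes$cds_start)) genes$cds_start <- genes$start
  if (is.null(genes$cds_end)) genes$cds_end <- genes$end
  exons <- exons %>% arrange(.data$gene_id, .data$start)
  # exons sorted and non-overlapping, introns >= 1 nt
  bad <- exons %>%
    group_by(.data$gene_id) %>%
    summarise(ok = all(diff(.data$start) > 0) &&
                all(head(.data$end, -1) < tail(.data$start, -1)),
              .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("overlapping or unsorted exons in gene(s): ",
         paste(bad$gene_id, collapse = ", "))
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "sequence(s)\n")
  invisible(x)
}

#' Annotated introns of a gene model set
#'
#' @param models a [gene_models] object.
#' @return tibble with `gene_id`, `chrom`, `strand`, `start`, `end` — one row
#'   per intron (the gap between consecutive exons), 1-based inclusive.
#' @export
gene_introns <- function(models) {
  ex <- models$exons %>% arrange(.data$gene_id, .data$start)
  rows <- lapply(split(seq_len(nrow(ex)), ex$gene_id), function(ix) {
    if (length(ix) < 2) return(NULL)
    tibble(gene_id = ex$gene_id[ix[1]], chrom = ex$chrom[ix[1]],
           strand = ex$strand[ix[1]],
           start = ex$end[head(ix, -1)] + 1L,
           end = ex$start[tail(ix, -1)] - 1L)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(0), chrom = character(0),
                  strand = character(0), start = integer(0), end = integer(0))
  }
  out
}

# Map transcript positions to genomic positions for a set of exons
# (genomic-sorted, 1-based inclusive) on a given strand. Vectorised over pos.
tx_to_genome <- function(starts, ends, strand, pos) {
  lens <- ends - starts + 1L
  total <- sum(lens)
  stopifnot(all(pos >= 1L), all(pos <= total))
  p <- if (strand == "+") pos else total - pos + 1L
  cum <- cumsum(lens)
  idx <- findInterval(p - 1L, c(0L, cum), rightmost.closed = FALSE)
  starts[idx] + (p - c(0L, cum)[idx]) - 1L
}

# Extract spliced transcript sequences (transcript orientation) for a set of
# transcripts given as exon tables. `genome` is a named character vector or
# DNAStringSet; returns a named character vector.
extract_tx_seqs <- function(genome, exon_tbl, tx_ids = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  ids <- tx_ids %||% unique(exon_tbl$tx_id)
  out <- vapply(ids, function(id) {
    ex <- exon_tbl[exon_tbl$tx_id == id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    parts <- substring(genome[[ex$chrom[1]]], ex$start, ex$end)
    s <- paste(parts, collapse = "")
    if (ex$strand[1] == "-") s <- revcomp(s)
    s
  }, character(1))
  stats::setNames(out, ids)
}

#' Spliced transcript sequences of the annotated (reference) gene models
#'
#' Concatenates exon sequences in transcript orientation; these play the role
#' of the assembled unigene set in downstream SSR mining and SNP pileups.
#'
#' @param genome named character vector or `Biostrings::DNAStringSet`.
#' @param models a [gene_models] object.
#' @return named character vector, one sequence per gene.
#' @export
transcript_seqs <- function(genome, models) {
  ex <- models$exons
  ex$tx_id <- ex$gene_id
  extract_tx_seqs(genome, ex)
}
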