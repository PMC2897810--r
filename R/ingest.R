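#' Read externally produced spliced alignments (PSL or GFF3)
#'
#' Ingests BLAT-style PSL or GFF3 `match`/`match_part` alignments, converts
#' them to the package's block representation (1-based inclusive), assigns
#' each alignment to the gene whose flanked region it overlaps most, and
#' applies the same identity/coverage acceptance rule as the built-in
#' aligner. PSL identity and coverage are taken from the PSL count fields
#' (`(matches+repMatches)/(matches+repMatches+misMatches)` and
#' `(matches+repMatches+misMatches)/qSize`); for GFF3 they are recomputed
#' from the sequences when `reads` are supplied, otherwise the `score` column
#' is used as identity and coverage is computed against the Target span.
#'
#' Malformed lines are skipped with a message (count in attribute
#' `n_skipped`); an alignment to an unknown chromosome is an error.
#'
#' @param path file path.
#' @param format `"psl"` or `"gff3"`.
#' @param genome named character vector or `DNAStringSet`.
#' @param models [gene_models] (used to assign genes via their regions).
#' @param reads optional named character vector of read sequences, used to
#'   recompute identity/coverage for GFF3 input.
#' @param params [align_params()] (acceptance thresholds, `min_intron`).
#' @return tibble shaped like `map_reads()$alignments` (accepted alignments
#'   only), with attribute `n_skipped` / `n_rejected`.
#' @export
read_alignments <- function(path, format = c("psl", "gff3"), genome, models,
                            reads = NULL, params = align_params()) {
  format <- match.arg(format)
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  regions <- define_gene_regions(models, chrom_lengths = nchar(genome))
  if (format == "psl") {
    out <- parse_psl(path, genome, params)
  } else {
    out <- parse_gff3_alignments(path, genome, reads, params)
  }
  aln <- out$aln
  n_rejected <- 0L
  rows <- list()
  for (i in seq_along(aln)) {
    a <- aln[[i]]
    if (!a$chrom %in% names(genome)) {
      stop("alignment targets unknown chromosome: ", a$chrom)
    }
    if (a$identity < params$min_identity ||
        a$coverage < params$min_coverage) {
      n_rejected <- n_rejected + 1L
      next
    }
    span <- c(min(a$blocks$gstart), max(a$blocks$gend))
    cand <- regions %>% filter(.data$chrom == a$chrom,
                               .data$start <= span[2], .data$end >= span[1])
    if (nrow(cand) == 0) {
      stop("alignment of ", a$read_id, " overlaps no gene region on ",
           a$chrom, ":", span[1], "-", span[2])
    }
    ovl <- pmin(cand$end, span[2]) - pmax(cand$start, span[1]) + 1L
    gene <- cand$gene_id[order(-ovl, cand$gene_id)][1]
    introns <- tibble(start = integer(0), end = integer(0))
    if (nrow(a$blocks) > 1) {
      gap_s <- head(a$blocks$gend, -1) + 1L
      gap_e <- tail(a$blocks$gstart, -1) - 1L
      big <- (gap_e - gap_s + 1L) >= params$min_intron
      introns <- tibble(start = gap_s[big], end = gap_e[big])
    }
    rows[[length(rows) + 1L]] <- tibble(
      read_id = a$read_id, library = sub("\\|.*$", "", a$read_id),
      gene_id = gene, chrom = a$chrom, strand = a$strand,
      identity = a$identity, coverage = a$coverage,
      aligned_len = sum(a$blocks$qend - a$blocks$qstart + 1L),
      n_blocks = nrow(a$blocks),
      blocks = list(a$blocks), introns = list(introns)
    )
  }
  res <- bind_rows(rows)
  if (out$n_skipped > 0) {
    message(out$n_skipped, " malformed line(s) skipped")
  }
  attr(res, "n_skipped") <- out$n_skipped
  attr(res, "n_rejected") <- n_rejected
  res
}

parse_psl <- function(path, genome, params) {
  lines <- readLines(path)
  # drop the optional psLayout header block
  lines <- lines[!grepl("^(psLayout|match\\b|\\s*match|-{5,})", lines) &
                   nzchar(lines)]
  aln <- list(); n_skipped <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 21) { n_skipped <- n_skipped + 1L; next }
    num <- suppressWarnings(as.integer(f[c(1:8, 11:13, 15:18)]))
    if (anyNA(num)) { n_skipped <- n_skipped + 1L; next }
    matches <- as.integer(f[1]); mis <- as.integer(f[2])
    rep_ <- as.integer(f[3])
    strand <- substr(f[9], 1, 1)
    qname <- f[10]; qsize <- as.integer(f[11])
    tname <- f[14]
    sizes <- as.integer(strsplit(f[19], ",", fixed = TRUE)[[1]])
    qst <- as.integer(strsplit(f[20], ",", fixed = TRUE)[[1]])
    tst <- as.integer(strsplit(f[21], ",", fixed = TRUE)[[1]])
    if (length(sizes) != length(qst) || length(sizes) != length(tst)) {
      n_skipped <- n_skipped + 1L; next
    }
    denom <- matches + rep_ + mis
    aln[[length(aln) + 1L]] <- list(
      read_id = qname, chrom = tname, strand = strand,
      identity = if (denom > 0) (matches + rep_) / denom else 0,
      coverage = denom / qsize,
      blocks = tibble(qstart = qst + 1L, qend = qst + sizes,
                      gstart = tst + 1L, gend = tst + sizes)
    )
  }
  list(aln = aln, n_skipped = n_skipped)
}

parse_gff3_alignments <- function(path, genome, reads, params) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  is_part <- type == "match_part"
  is_match <- grepl("match$", type) & !is_part
  # group parts under their parent match; standalone matches are one block
  parse_target <- function(tg) {
    p <- strsplit(tg, " ", fixed = TRUE)[[1]]
    list(id = p[1], qs = as.integer(p[2]), qe = as.integer(p[3]))
  }
  groups <- list()
  if (any(is_part)) {
    parent <- vapply(md$Parent[is_part], function(x) as.character(x)[1],
                     character(1))
    for (pid in unique(parent)) {
      idx <- which(is_part)[parent == pid]
      groups[[pid]] <- idx
    }
  }
  solo <- which(is_match & !(as.character(md$ID %||% "") %in% names(groups)))
  for (i in solo) groups[[paste0(".solo", i)]] <- i
  aln <- list()
  for (g in groups) {
    tgt <- lapply(as.character(md$Target[g]), parse_target)
    ord <- order(GenomicRanges::start(gr)[g])
    g <- g[ord]; tgt <- tgt[ord]
    qname <- tgt[[1]]$id
    blocks <- tibble(
      qstart = vapply(tgt, function(t) t$qs, integer(1)),
      qend = vapply(tgt, function(t) t$qe, integer(1)),
      gstart = GenomicRanges::start(gr)[g],
      gend = GenomicRanges::end(gr)[g]
    )
    chrom <- as.character(GenomicRanges::seqnames(gr))[g[1]]
    strand <- as.character(GenomicRanges::strand(gr))[g[1]]
    if (!strand %in% c("+", "-")) strand <- "+"
    alen <- sum(blocks$qend - blocks$qstart + 1L)
    if (!is.null(reads) && qname %in% names(reads)) {
      read <- reads[[qname]]
      oriented <- if (strand == "-") revcomp(read) else read
      matched <- 0L
      for (b in seq_len(nrow(blocks))) {
        rb <- strsplit(substr(oriented, blocks$qstart[b], blocks$qend[b]),
                       "")[[1]]
        gb <- strsplit(substr(genome[[chrom]], blocks$gstart[b],
                              blocks$gend[b]), "")[[1]]
        n <- min(length(rb), length(gb))
        matched <- matched + sum(rb[seq_len(n)] == gb[seq_len(n)])
      }
      identity <- matched / alen
      coverage <- alen / nchar(read)
    } else {
      sc <- md$score[g[1]]
      identity <- if (!is.null(sc) && !is.na(sc) && sc <= 1) sc else 1
      coverage <- alen / max(blocks$qend)
    }
    aln[[length(aln) + 1L]] <- list(read_id = qname, chrom = chrom,
                                    strand = strand, identity = identity,
                                    coverage = coverage, blocks = blocks)
  }
  list(aln = aln, n_skipped = 0L)
}
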