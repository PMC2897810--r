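#' Write gene models as GFF3
#'
#' One `gene` feature per gene with nested `exon` features and a `CDS`
#' feature spanning the annotated coding bounds. Coordinates are written
#' 1-based inclusive per the GFF3 specification.
#'
#' @param models [gene_models].
#' @param path output file.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  ex <- models$exons %>% arrange(.data$gene_id, .data$start)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, paste(
      g$chrom[i], "florest", "gene", g$start[i], g$end[i], ".", g$strand[i],
      ".", paste0("ID=", g$gene_id[i]), sep = "\t"))
    exi <- ex[ex$gene_id == g$gene_id[i], ]
    lines <- c(lines, paste(
      exi$chrom, "florest", "exon", exi$start, exi$end, ".", exi$strand, ".",
      paste0("Parent=", exi$gene_id), sep = "\t"))
    if (!is.null(g$cds_start)) {
      lines <- c(lines, paste(
        g$chrom[i], "florest", "CDS", g$cds_start[i], g$cds_end[i], ".",
        g$strand[i], "0", paste0("Parent=", g$gene_id[i]), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Accepts `gene`/`exon`/`CDS` features with exons parented on the gene (or
#' on an mRNA parented on the gene). CDS bounds become the translation
#' anchors; genes without CDS rows anchor at their bounds.
#'
#' @param path GFF3 file.
#' @return a [gene_models] object.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID %||% rep(NA, length(gr)))
  parent <- vapply(seq_along(gr), function(i) {
    p <- md$Parent[[i]]
    if (length(p) == 0) NA_character_ else as.character(p)[1]
  }, character(1))
  # resolve mRNA -> gene indirection if present
  mrna <- type %in% c("mRNA", "transcript")
  mrna_gene <- stats::setNames(parent[mrna], ids[mrna])
  to_gene <- function(p) ifelse(p %in% names(mrna_gene), mrna_gene[p], p)
  gi <- type == "gene"
  genes <- tibble(
    gene_id = ids[gi],
    chrom = as.character(GenomicRanges::seqnames(gr))[gi],
    strand = as.character(GenomicRanges::strand(gr))[gi],
    start = GenomicRanges::start(gr)[gi],
    end = GenomicRanges::end(gr)[gi]
  )
  ci <- type == "CDS"
  if (any(ci)) {
    cds <- tibble(gene_id = unname(to_gene(parent[ci])),
                  s = GenomicRanges::start(gr)[ci],
                  e = GenomicRanges::end(gr)[ci]) %>%
      group_by(.data$gene_id) %>%
      summarise(cds_start = min(.data$s), cds_end = max(.data$e),
                .groups = "drop")
    genes <- genes %>% left_join(cds, by = "gene_id") %>%
      mutate(cds_start = ifelse(is.na(.data$cds_start), .data$start,
                                .data$cds_start),
             cds_end = ifelse(is.na(.data$cds_end), .data$end, .data$cds_end))
  }
  ei <- type == "exon"
  exons <- tibble(
    gene_id = unname(to_gene(parent[ei])),
    chrom = as.character(GenomicRanges::seqnames(gr))[ei],
    strand = as.character(GenomicRanges::strand(gr))[ei],
    start = GenomicRanges::start(gr)[ei],
    end = GenomicRanges::end(gr)[ei]
  )
  gene_models(genes, exons)
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub(" .*$", "", names(x)))
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Write a simulated fixture to disk
#'
#' Writes `genome.fa`, `genes.gff3`, `reads_G.fa`, `reads_H.fa` and the
#' truth tables (`truth_de.tsv`, `truth_as.tsv`, `truth_snp.tsv`,
#' `truth_ssr.tsv`, `truth_expression.tsv`). Empty truth tables produce
#' header-only files. Re-reading with [read_fixture()] round-trips all
#' records.
#'
#' @param bundle a `sim_libraries` (from [simulate_libraries()]) or a
#'   `sim_genome` (no read files are written then).
#' @param dir output directory, created if needed.
#' @return invisibly, the directory.
#' @export
write_fixture <- function(bundle, dir) {
  if (inherits(bundle, "sim_libraries")) {
    sim <- bundle$sim; truth <- bundle$truth; reads <- bundle$reads
  } else if (inherits(bundle, "sim_genome")) {
    sim <- bundle; truth <- bundle$truth; reads <- NULL
  } else {
    stop("bundle must come from simulate_libraries() or generate_genome()")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gff3(sim$models, file.path(dir, "genes.gff3"))
  if (!is.null(reads)) {
    write_fasta(reads$G, file.path(dir, "reads_G.fa"))
    write_fasta(reads$H, file.path(dir, "reads_H.fa"))
  }
  write_tsv_plain(truth$de, file.path(dir, "truth_de.tsv"))
  write_tsv_plain(truth$as, file.path(dir, "truth_as.tsv"))
  write_tsv_plain(truth$snp, file.path(dir, "truth_snp.tsv"))
  write_tsv_plain(truth$ssr, file.path(dir, "truth_ssr.tsv"))
  write_tsv_plain(truth$expression, file.path(dir, "truth_expression.tsv"))
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir the fixture directory.
#' @return list with `genome` (named character), `models` ([gene_models]),
#'   `reads` (list `G`, `H`, if present) and `truth` (list of tibbles).
#' @export
read_fixture <- function(dir) {
  out <- list(
    genome = read_fasta(file.path(dir, "genome.fa")),
    models = read_gff3_genes(file.path(dir, "genes.gff3")),
    truth = list(
      de = read_tsv_plain(file.path(dir, "truth_de.tsv")),
      as = read_tsv_plain(file.path(dir, "truth_as.tsv")),
      snp = read_tsv_plain(file.path(dir, "truth_snp.tsv")),
      ssr = read_tsv_plain(file.path(dir, "truth_ssr.tsv")),
      expression = read_tsv_plain(file.path(dir, "truth_expression.tsv"))
    )
  )
  if (file.exists(file.path(dir, "reads_G.fa"))) {
    out$reads <- list(G = read_fasta(file.path(dir, "reads_G.fa")),
                      H = read_fasta(file.path(dir, "reads_H.fa")))
  }
  out
}
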