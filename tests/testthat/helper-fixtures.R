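# Shared fixtures built in code.

# A tiny two-gene annotation on one chromosome for alignment/junction tests.
# g1: + strand, exons 1001..1200 and 1351..1550 (intron 1201..1350, GT..AG).
# g2: + strand, single exon 5001..5400.
toy_genome_models <- function(seed = 42L) {
  set.seed(seed)
  chr <- rand_dna(8000L)
  substr(chr, 1201, 1202) <- "GT"
  substr(chr, 1349, 1350) <- "AG"
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "chrT", strand = "+",
    start = c(1001L, 5001L), end = c(1550L, 5400L),
    cds_start = c(1051L, 5051L), cds_end = c(1500L, 5350L)
  )
  exons <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"), chrom = "chrT", strand = "+",
    start = c(1001L, 1351L, 5001L), end = c(1200L, 1550L, 5400L)
  )
  list(genome = c(chrT = chr), models = gene_models(genes, exons))
}

# Minimal alignment tibble builder (one alignment per call() spec).
aln_row <- function(read_id, gene_id, blocks, chrom = "chrT", strand = "+",
                    library = sub("\\|.*$", "", read_id)) {
  introns <- tibble::tibble(start = integer(0), end = integer(0))
  if (nrow(blocks) > 1) {
    gs <- utils::head(blocks$gend, -1) + 1L
    ge <- utils::tail(blocks$gstart, -1) - 1L
    big <- ge - gs + 1L >= 40L
    introns <- tibble::tibble(start = gs[big], end = ge[big])
  }
  tibble::tibble(
    read_id = read_id, library = library, gene_id = gene_id, chrom = chrom,
    strand = strand, identity = 1, coverage = 1,
    aligned_len = sum(blocks$qend - blocks$qstart + 1L),
    n_blocks = nrow(blocks), blocks = list(blocks), introns = list(introns)
  )
}

blocks_df <- function(qstart, qend, gstart, gend) {
  tibble::tibble(qstart = as.integer(qstart), qend = as.integer(qend),
                 gstart = as.integer(gstart), gend = as.integer(gend))
}

# Junction table builder for classifier unit tests (bypasses alignment).
jc_tbl <- function(gene_id, start, end, strand = "+", support = 2L,
                   chrom = "chrT") {
  sup <- as.integer(support)[1]
  start <- as.integer(start); end <- as.integer(end)
  reads <- lapply(seq_along(start), function(i) {
    paste0("G|x|r", i, "_", seq_len(sup))
  })
  donor <- if (strand[1] == "+") start else end
  acceptor <- if (strand[1] == "+") end else start
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end, donor = donor, acceptor = acceptor,
    support = sup, annotated = FALSE,
    read_ids = reads
  )
}

# Mirror a fixture: reverse-complement the genome and flip all coordinates,
# producing the biologically identical annotation on the opposite strand.
mirror_fixture <- function(genome, models) {
  L <- stats::setNames(nchar(genome), names(genome))
  mg <- stats::setNames(rc(genome), names(genome))
  flip <- function(chrom, a, b) {
    list(start = L[chrom] - b + 1L, end = L[chrom] - a + 1L)
  }
  g <- models$genes
  fg <- flip(g$chrom, g$start, g$end)
  fc <- flip(g$chrom, g$cds_start, g$cds_end)
  genes <- tibble::tibble(
    gene_id = g$gene_id, chrom = g$chrom,
    strand = ifelse(g$strand == "+", "-", "+"),
    start = unname(fg$start), end = unname(fg$end),
    cds_start = unname(fc$start), cds_end = unname(fc$end)
  )
  e <- models$exons
  fe <- flip(e$chrom, e$start, e$end)
  exons <- tibble::tibble(
    gene_id = e$gene_id, chrom = e$chrom,
    strand = ifelse(e$strand == "+", "-", "+"),
    start = unname(fe$start), end = unname(fe$end)
  )
  list(genome = mg, models = gene_models(genes, exons), len = L)
}

# Match classified events against the simulator's AS truth table; returns a
# logical vector over truth rows.
match_as_truth <- function(events, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    tv <- truth[i, ]
    ev <- events[events$gene_id == tv$gene_id & events$type == tv$type, ,
                 drop = FALSE]
    if (nrow(ev) == 0) return(FALSE)
    if (tv$type %in% c("AltD", "AltA", "AltP")) {
      any((ev$intron1_start == tv$alt_start & ev$intron1_end == tv$alt_end &
             ev$intron2_start == tv$ref_start & ev$intron2_end == tv$ref_end) |
            (ev$intron2_start == tv$alt_start & ev$intron2_end == tv$alt_end &
               ev$intron1_start == tv$ref_start & ev$intron1_end == tv$ref_end))
    } else {
      any(ev$intron1_start == tv$alt_start & ev$intron1_end == tv$alt_end)
    }
  }, logical(1))
}

# Hand-constructed site-column table exercising each SNP filter criterion.
snp_filter_fixture <- function() {
  consensus <- paste0("TTGACGTAGCATCAGTACGATCGA",  # pos 1..24, no long runs
                      "AAA",                        # pos 25..27 homopolymer
                      "GCTAGCTAGTCGATCAGCTA")
  col <- function(pos, aG, aH, cons = substr(consensus, pos, pos)) {
    tibble::tibble(chrom = "ctg1", pos = as.integer(pos), ins = 0L,
                   consensus = cons,
                   cov_G = sum(aG), cov_H = sum(aH),
                   alleles_G = list(aG), alleles_H = list(aH))
  }
  columns <- dplyr::bind_rows(
    col(5, c(G = 3L), c(A = 2L)),            # clean transition
    col(9, c(A = 3L), c(C = 3L)),            # clean transversion
    col(15, c(A = 4L), c(`-` = 2L)),         # clean indel (no run nearby)
    col(19, c(G = 1L), c(A = 3L)),           # fails coverage (criterion 1)
    col(26, c(C = 3L), c(`-` = 3L)),         # indel inside AAA (criterion 2)
    col(33, c(G = 2L, A = 1L), c(A = 3L))    # shared allele (criterion 3)
  )
  truth <- tibble::tibble(
    pos = c(5L, 9L, 15L, 19L, 26L, 33L),
    class = c("transition", "transversion", "indel", "transition", "indel",
              "transition"),
    pass_coverage = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    pass_homopolymer = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    pass_disjoint = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    pass = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  list(columns = columns, genome = c(ctg1 = consensus), truth = truth)
}

# A 10-term toy DAG (child -> parents) for slim-mapping oracle checks.
toy_dag <- function() {
  edges <- list(
    t01 = c("t02", "t03"),
    t02 = c("t04"),
    t03 = c("t05"),
    t04 = c("t06"),
    t05 = c("t06"),
    t06 = c("t07"),
    t07 = character(0),
    t08 = c("t04", "t09"),
    t09 = c("t07"),
    t10 = c("t08")
  )
  ids <- names(edges)
  ont <- ontology(
    tibble::tibble(id = ids),
    dplyr::bind_rows(lapply(ids, function(i) {
      if (length(edges[[i]]) == 0) return(NULL)
      tibble::tibble(id = i, parent = edges[[i]])
    }))
  )
  list(ont = ont, edges = edges)
}
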