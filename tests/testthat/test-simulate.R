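small_cfg <- function(...) {
  args <- utils::modifyList(list(
    n_chromosomes = 1L, n_genes = 16L, n_de_genes = 2L,
    base_expression = 20, library_sizes = c(G = 500L, H = 500L),
    n_as_events_per_type = c(1L, 1L, 1L, 1L, 1L),
    n_snps = 2L, n_indels = 2L, n_ssr_loci = 2L, seed = 7L
  ), list(...))
  do.call(simulation_config, args)
}

test_that("a fixed seed reproduces the genome and libraries byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  l1 <- simulate_libraries(generate_genome(small_cfg()))
  l2 <- simulate_libraries(generate_genome(small_cfg()))
  write_fixture(l1, d1)
  write_fixture(l2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("infeasible configurations fail with a named constraint", {
  expect_error(
    simulation_config(exons_per_gene = c(1L, 1L),
                      n_as_events_per_type = c(0L, 0L, 0L, 1L, 0L)),
    "intron")
  expect_error(
    simulation_config(exons_per_gene = c(2L, 2L),
                      n_as_events_per_type = c(0L, 0L, 0L, 0L, 2L)),
    "ExonS")
  expect_error(simulation_config(de_fold = 1), "de_fold")
  expect_error(simulation_config(n_genes = 4L), "n_genes")
})

test_that("AS truth has exactly one event per requested type, on multi-exon genes", {
  sim <- generate_genome(small_cfg())
  expect_equal(sort(sim$truth$as$type),
               sort(c("AltD", "AltA", "AltP", "IntronR", "ExonS")))
  expect_equal(anyDuplicated(sim$truth$as$gene_id), 0L)
  ng <- sim$models$genes$n_exons[match(sim$truth$as$gene_id,
                                       sim$models$genes$gene_id)]
  expect_true(all(ng >= 2L))
  expect_true(all(ng[sim$truth$as$type == "ExonS"] >= 3L))
})

test_that("a null configuration has an empty DE truth table", {
  sim <- generate_genome(small_cfg(n_de_genes = 0L))
  expect_equal(nrow(sim$truth$de), 0L)
  expect_true(all(sim$truth$expression$fold == 1))
})

test_that("library sizes are met exactly and tags are encoded as LIB|", {
  lib <- simulate_libraries(generate_genome(small_cfg()))
  expect_length(lib$reads$G, 500L)
  expect_length(lib$reads$H, 500L)
  expect_true(all(startsWith(names(lib$reads$G), "G|")))
  expect_true(all(startsWith(names(lib$reads$H), "H|")))
  expect_equal(sum(lib$source_counts$G), 500L)
  expect_equal(sum(lib$source_counts$H), 500L)
})

test_that("empirical read length matches the 175 nt model", {
  cfg <- simulation_config(n_genes = 40L, base_expression = 25,
                           library_sizes = c(G = 10000L, H = 10000L),
                           n_as_events_per_type = rep(0L, 5),
                           n_snps = 0L, n_indels = 0L, n_ssr_loci = 0L,
                           seed = 11L)
  lib <- simulate_libraries(generate_genome(cfg))
  lens <- nchar(c(lib$reads$G, lib$reads$H))
  expect_length(lens, 20000L)
  expect_lt(abs(mean(lens) - 175), 5)
})

test_that("with zero error rate every read is an exact substring of a line-specific transcript", {
  sim <- generate_genome(small_cfg(homopolymer_error_rate = 0))
  lib <- simulate_libraries(sim)
  ref_tx <- transcript_seqs(sim$genome, sim$models)
  alt_tx <- florest:::extract_tx_seqs(sim$genome, sim$iso_exons)
  snp_by_gene <- split(sim$truth$snp, sim$truth$snp$gene_id)
  for (lib_tag in c("G", "H")) {
    reads <- lib$reads[[lib_tag]]
    idx <- sample(length(reads), 120)
    for (i in idx) {
      gid <- strsplit(names(reads)[i], "|", fixed = TRUE)[[1]][2]
      sources <- ref_tx[gid]
      if (lib_tag == "H" && gid %in% names(snp_by_gene)) {
        sources <- florest:::apply_line_edits(ref_tx[[gid]],
                                              snp_by_gene[[gid]])
      }
      alt_id <- paste0(gid, ".alt")
      if (alt_id %in% names(alt_tx)) sources <- c(sources, alt_tx[[alt_id]])
      rd <- reads[[i]]
      hit <- any(vapply(sources, function(s) {
        grepl(rd, s, fixed = TRUE) || grepl(rc(rd), s, fixed = TRUE)
      }, logical(1)))
      expect_true(hit, label = paste("read", names(reads)[i]))
    }
  }
})

test_that("injected SNP sites are covered by reads of both lines at moderate expression", {
  sim <- generate_genome(small_cfg(homopolymer_error_rate = 0))
  lib <- simulate_libraries(sim)
  reads <- c(lib$reads$G, lib$reads$H)
  snp_genes <- unique(sim$truth$snp$gene_id)
  sel <- reads[vapply(strsplit(names(reads), "|", fixed = TRUE), `[`,
                      character(1), 2) %in% snp_genes]
  mp <- map_reads(sel, sim$genome, sim$models)
  cols <- pileup_columns(mp$alignments, sel, sim$genome)
  src <- lib$source_counts
  for (i in seq_len(nrow(sim$truth$snp))) {
    tv <- sim$truth$snp[i, ]
    cnt <- src[src$gene_id == tv$gene_id, ]
    if (cnt$G < 5 || cnt$H < 5) next
    cc <- cols[cols$chrom == tv$chrom & cols$pos == tv$gpos, ]
    expect_gt(sum(cc$cov_G), 0)
    expect_gt(sum(cc$cov_H), 0)
  }
})

test_that("fixtures round-trip through disk losslessly", {
  d <- withr::local_tempdir()
  sim <- generate_genome(small_cfg())
  lib <- simulate_libraries(sim)
  write_fixture(lib, d)
  back <- read_fixture(d)
  expect_identical(back$genome, sim$genome)
  expect_equal(back$models$genes$start, sim$models$genes$start)
  expect_equal(back$models$genes$cds_start, sim$models$genes$cds_start)
  expect_equal(back$models$exons$end, sim$models$exons$end)
  expect_identical(back$reads$G, lib$reads$G)
  expect_equal(as.data.frame(back$truth$ssr), as.data.frame(lib$truth$ssr))
  expect_equal(back$truth$snp$gpos, lib$truth$snp$gpos)
  expect_equal(back$truth$de$fold, lib$truth$de$fold)
  # empty truth table round-trips as a header-only TSV
  sim0 <- generate_genome(small_cfg(n_de_genes = 0L))
  d0 <- withr::local_tempdir()
  write_fixture(sim0, d0)
  expect_length(readLines(file.path(d0, "truth_de.tsv")), 1L)
  expect_equal(nrow(read_fixture(d0)$truth$de), 0L)
})

test_that("GFF3 output uses 1-based inclusive coordinates", {
  d <- withr::local_tempdir()
  sim <- generate_genome(small_cfg())
  write_fixture(sim, d)
  lines <- grep("\tgene\t", readLines(file.path(d, "genes.gff3")),
                value = TRUE)
  f <- strsplit(lines[1], "\t")[[1]]
  g1 <- sim$models$genes[sim$models$genes$gene_id == sub("ID=", "", f[9]), ]
  expect_equal(as.integer(f[4]), g1$start)
  expect_equal(as.integer(f[5]), g1$end)
  # the annotated span really is the gene: its first/last bases are exonic
  ex <- sim$models$exons[sim$models$exons$gene_id == g1$gene_id, ]
  expect_equal(min(ex$start), g1$start)
  expect_equal(max(ex$end), g1$end)
})
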