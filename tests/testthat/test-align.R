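test_that("an exact two-exon read yields two blocks and the annotated intron", {
  tf <- toy_genome_models()
  region <- substr(tf$genome[["chrT"]], 1, 2550)
  read <- paste0(substr(tf$genome[["chrT"]], 1101, 1200),
                 substr(tf$genome[["chrT"]], 1351, 1450))
  al <- align_est(c(r1 = read), region)
  expect_equal(al$n_blocks, 2L)
  expect_equal(al$identity, 1)
  expect_equal(al$coverage, 1)
  expect_equal(al$introns[[1]]$start, 1201L)
  expect_equal(al$introns[[1]]$end, 1350L)
  expect_equal(al$strand, "+")
})

test_that("reverse-complemented reads align on the minus strand", {
  tf <- toy_genome_models()
  region <- substr(tf$genome[["chrT"]], 1, 2550)
  read <- rc(paste0(substr(tf$genome[["chrT"]], 1101, 1200),
                    substr(tf$genome[["chrT"]], 1351, 1450)))
  al <- align_est(c(r1 = read), region)
  expect_equal(al$strand, "-")
  expect_equal(al$introns[[1]]$start, 1201L)
})

test_that("identity below 95% is rejected", {
  tf <- toy_genome_models()
  region <- substr(tf$genome[["chrT"]], 1, 2550)
  read <- substr(tf$genome[["chrT"]], 1001, 1200)
  set.seed(1)
  ch <- strsplit(read, "")[[1]]
  mut <- seq(3, 195, by = 10)  # 20 substitutions in 200 nt -> identity 0.90
  ch[mut] <- vapply(ch[mut], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    character(1))
  expect_null(align_est(c(r1 = paste(ch, collapse = "")), region))
})

test_that("query coverage below 80% is rejected", {
  tf <- toy_genome_models()
  region <- substr(tf$genome[["chrT"]], 1, 2550)
  set.seed(2)
  read <- paste0(substr(tf$genome[["chrT"]], 1001, 1140), rand_dna(60))
  # 140 of 200 nt alignable -> coverage 0.70
  expect_null(align_est(c(r1 = read), region))
  # the same aligned core with a short tail passes
  read2 <- paste0(substr(tf$genome[["chrT"]], 1001, 1180), rand_dna(20))
  expect_false(is.null(align_est(c(r1 = read2), region)))
})

test_that("small indels inside a read stay within one exonic stretch", {
  tf <- toy_genome_models()
  region <- substr(tf$genome[["chrT"]], 4500, 5900)
  base <- substr(region, 5051 - 4499, 5250 - 4499)
  ch <- strsplit(base, "")[[1]]
  del <- paste(ch[-100], collapse = "")
  al <- align_est(c(r1 = del), region)
  expect_false(is.null(al))
  expect_equal(nrow(al$introns[[1]]), 0L)   # a 1 nt gap is not an intron
  expect_gte(al$identity, 0.99)
  expect_equal(sum(al$blocks[[1]]$qend - al$blocks[[1]]$qstart + 1L), 199L)
})

test_that("map_reads assigns every zero-error read to its source gene", {
  cfg <- simulation_config(
    n_chromosomes = 1L, n_genes = 12L, n_de_genes = 0L,
    base_expression = 20, library_sizes = c(G = 300L, H = 300L),
    n_as_events_per_type = c(1L, 1L, 0L, 1L, 1L),
    n_snps = 2L, n_indels = 1L, n_ssr_loci = 1L,
    homopolymer_error_rate = 0, seed = 3L)
  sim <- generate_genome(cfg)
  lib <- simulate_libraries(sim)
  reads <- c(lib$reads$G, lib$reads$H)
  mp <- map_reads(reads, sim$genome, sim$models)
  expect_length(mp$unmapped, 0L)
  src <- vapply(strsplit(mp$alignments$read_id, "|", fixed = TRUE), `[`,
                character(1), 2)
  expect_true(all(mp$alignments$gene_id == src))
  expect_true(all(mp$alignments$identity >= 0.95))
  expect_true(all(mp$alignments$coverage >= 0.80))
})

test_that("assign_to_gene breaks ties deterministically", {
  cand <- tibble::tibble(
    read_id = c("r1", "r1", "r2"),
    gene_id = c("gB", "gA", "gC"),
    identity = c(1, 1, 0.97), coverage = c(0.9, 0.9, 0.9),
    aligned_len = c(90L, 90L, 90L))
  best <- assign_to_gene(cand)
  expect_equal(best$gene_id[best$read_id == "r1"], "gA")
  # longer aligned length beats the lexicographic rule
  cand2 <- cand
  cand2$aligned_len <- c(95L, 90L, 90L)
  expect_equal(assign_to_gene(cand2)$gene_id[1], "gB")
})

test_that("unalignable reads are reported as unmapped", {
  tf <- toy_genome_models()
  set.seed(9)
  mp <- map_reads(c(`G|x|junk` = rand_dna(150)), tf$genome, tf$models)
  expect_equal(nrow(mp$alignments), 0L)
  expect_equal(mp$unmapped, "G|x|junk")
})

test_that("PSL ingestion applies the identity and coverage rule", {
  tf <- toy_genome_models()
  psl <- file.path(withr::local_tempdir(), "aln.psl")
  row1 <- paste(c(200, 0, 0, 0, 0, 0, 0, 0, "+", "G|g1|r1", 200, 0, 200,
                  "chrT", 8000, 1000, 1200, 1, "200,", "0,", "1000,"),
                collapse = "\t")
  # qSize 200, matches 150 -> coverage 0.75, rejected
  row2 <- paste(c(150, 0, 0, 0, 0, 0, 0, 0, "+", "G|g1|r2", 200, 0, 150,
                  "chrT", 8000, 1000, 1150, 1, "150,", "0,", "1000,"),
                collapse = "\t")
  writeLines(c(row1, row2, "garbage line"), psl)
  expect_message(
    aln <- read_alignments(psl, "psl", tf$genome, tf$models),
    "1 malformed")
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$read_id, "G|g1|r1")
  expect_equal(aln$gene_id, "g1")
  expect_equal(aln$n_blocks, 1L)
  expect_equal(nrow(aln$introns[[1]]), 0L)
  expect_equal(aln$blocks[[1]]$gstart, 1001L)  # PSL is 0-based
  expect_equal(attr(aln, "n_rejected"), 1L)
})

test_that("GFF3 match/match_part ingestion rebuilds spliced blocks", {
  tf <- toy_genome_models()
  read <- paste0(substr(tf$genome[["chrT"]], 1101, 1200),
                 substr(tf$genome[["chrT"]], 1351, 1450))
  gff <- file.path(withr::local_tempdir(), "aln.gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\tblat\tmatch\t1101\t1450\t.\t+\t.\tID=m1;Target=G|g1|r9 1 200",
    paste0("chrT\tblat\tmatch_part\t1101\t1200\t.\t+\t.\t",
           "Parent=m1;Target=G|g1|r9 1 100"),
    paste0("chrT\tblat\tmatch_part\t1351\t1450\t.\t+\t.\t",
           "Parent=m1;Target=G|g1|r9 101 200")
  ), gff)
  aln <- read_alignments(gff, "gff3", tf$genome, tf$models,
                         reads = c(`G|g1|r9` = read))
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$n_blocks, 2L)
  expect_equal(aln$identity, 1)
  expect_equal(aln$coverage, 1)
  expect_equal(aln$introns[[1]]$start, 1201L)
  # unknown chromosome is an error
  writeLines(gsub("chrT", "chrZ", readLines(gff)), gff)
  expect_error(read_alignments(gff, "gff3", tf$genome, tf$models),
               "unknown")
})
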