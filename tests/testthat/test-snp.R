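test_that("pileup tallies alleles per line with gap alleles at deletions", {
  tf <- toy_genome_models()
  al <- dplyr::bind_rows(
    lapply(1:5, function(i) {
      aln_row(paste0("G|g2|r", i), "g2", blocks_df(1, 100, 5051, 5150))
    }),
    aln_row("H|g2|r6", "g2", blocks_df(c(1, 61), c(60, 100),
                                       c(5051, 5112), c(5110, 5151)))
  )
  reads <- c(
    stats::setNames(rep(substr(tf$genome[["chrT"]], 5051, 5150), 5),
                    paste0("G|g2|r", 1:5)),
    stats::setNames(paste0(substr(tf$genome[["chrT"]], 5051, 5110),
                           substr(tf$genome[["chrT"]], 5112, 5151)),
                    "H|g2|r6"))
  cols <- pileup_columns(al, reads, tf$genome)
  c1 <- cols[cols$pos == 5060, ]
  expect_equal(unname(c1$cov_G), 5L)
  expect_equal(length(c1$alleles_G[[1]]), 1L)
  expect_equal(names(c1$alleles_G[[1]]),
               substr(tf$genome[["chrT"]], 5060, 5060))
  cdel <- cols[cols$pos == 5111, ]
  expect_equal(names(cdel$alleles_H[[1]]), "-")
  expect_equal(unname(cdel$cov_H), 1L)
  expect_equal(unname(cdel$cov_G), 5L)
})

test_that("candidate sites need two alleles across the line union", {
  fx <- snp_filter_fixture()
  mono <- tibble::tibble(chrom = "ctg1", pos = 2L, ins = 0L, consensus = "T",
                         cov_G = 4L, cov_H = 4L,
                         alleles_G = list(c(A = 4L)),
                         alleles_H = list(c(A = 4L)))
  cand <- candidate_sites(dplyr::bind_rows(mono, fx$columns))
  expect_false(2L %in% cand$pos)
  expect_equal(nrow(cand), nrow(fx$columns))   # within-line variation stays
})

test_that("the three filters and the class calls match the designed truth", {
  fx <- snp_filter_fixture()
  rec <- apply_filters(candidate_sites(fx$columns), fx$genome)
  rec <- rec[match(fx$truth$pos, rec$pos), ]
  expect_equal(rec$class, fx$truth$class)
  expect_equal(rec$pass_coverage, fx$truth$pass_coverage)
  expect_equal(rec$pass_homopolymer, fx$truth$pass_homopolymer)
  expect_equal(rec$pass_disjoint, fx$truth$pass_disjoint)
  expect_equal(rec$pass, fx$truth$pass)
})

test_that("variant classes are definitional", {
  expect_equal(classify_variant(c("A", "G")), "transition")
  expect_equal(classify_variant(c("C", "T")), "transition")
  expect_equal(classify_variant(c("A", "C")), "transversion")
  expect_equal(classify_variant(c("A", "-")), "indel")
})

test_that("multi-allelic non-indel candidates are rejected", {
  col <- tibble::tibble(chrom = "ctg1", pos = 5L, ins = 0L, consensus = "G",
                        cov_G = 4L, cov_H = 3L,
                        alleles_G = list(c(G = 2L, T = 2L)),
                        alleles_H = list(c(A = 3L)))
  rec <- apply_filters(col, c(ctg1 = "ACGTGTACGT"))
  expect_false(rec$biallelic)
  expect_false(rec$pass)
  expect_true(rec$pass_coverage && rec$pass_disjoint)
})

test_that("the within-line fixation switch tightens criterion 3", {
  col <- tibble::tibble(chrom = "ctg1", pos = 5L, ins = 0L, consensus = "G",
                        cov_G = 4L, cov_H = 3L,
                        alleles_G = list(c(G = 2L, T = 2L)),
                        alleles_H = list(c(A = 3L)))
  g <- c(ctg1 = "ACGTGTACGT")
  expect_true(apply_filters(col, g)$pass_disjoint)
  expect_false(apply_filters(col, g,
                             require_within_line_fixation = TRUE)$pass_disjoint)
})

test_that("passing records partition into the three classes", {
  fx <- snp_filter_fixture()
  rec <- apply_filters(candidate_sites(fx$columns), fx$genome)
  passing <- rec[rec$pass, ]
  expect_equal(sum(passing$class == "transition") +
                 sum(passing$class == "transversion") +
                 sum(passing$class == "indel"), nrow(passing))
})

test_that("simulated inter-line variants are recovered with no false calls at zero error", {
  cfg <- simulation_config(
    n_chromosomes = 1L, n_genes = 14L, n_de_genes = 0L,
    base_expression = 40, library_sizes = c(G = 700L, H = 700L),
    n_as_events_per_type = rep(0L, 5), n_snps = 4L, n_indels = 2L,
    n_ssr_loci = 0L, homopolymer_error_rate = 0, seed = 23L)
  sim <- generate_genome(cfg)
  lib <- simulate_libraries(sim)
  reads <- c(lib$reads$G, lib$reads$H)
  mp <- map_reads(reads, sim$genome, sim$models)
  rec <- call_snps(mp$alignments, reads, sim$genome)
  passing <- rec[rec$pass, ]
  truth <- lib$truth$snp
  tkey <- paste(truth$chrom, truth$gpos)
  pkey <- paste(passing$chrom, passing$pos)
  # no false positives at zero error rate
  expect_true(all(pkey %in% tkey))
  # every truth site with >= 2 reads per line at the site is recovered
  cols <- pileup_columns(mp$alignments, reads, sim$genome)
  for (i in seq_len(nrow(truth))) {
    cc <- cols[cols$chrom == truth$chrom[i] & cols$pos == truth$gpos[i], ]
    if (nrow(cc) == 0 || min(sum(cc$cov_G), sum(cc$cov_H)) < 2) next
    expect_true(tkey[i] %in% pkey, label = paste("site", tkey[i]))
    got <- passing[pkey == tkey[i], ]
    expect_equal(got$class[1], truth$class[i])
  }
})
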