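test_that("junctions are read off alignment gaps with overhang filtering", {
  tf <- toy_genome_models()
  al <- dplyr::bind_rows(
    aln_row("G|g1|r1", "g1", blocks_df(1, 100, 1101, 1200) |>
              rbind(blocks_df(101, 200, 1351, 1450))),
    aln_row("G|g1|r2", "g1", blocks_df(1, 100, 1101, 1200) |>
              rbind(blocks_df(101, 200, 1351, 1450))),
    aln_row("H|g1|r3", "g1", blocks_df(1, 100, 1101, 1200) |>
              rbind(blocks_df(101, 200, 1351, 1450))),
    # only 5 nt beyond the intron: junction dropped
    aln_row("G|g1|r4", "g1", blocks_df(1, 100, 1101, 1200) |>
              rbind(blocks_df(101, 105, 1351, 1355)))
  )
  jc <- extract_junctions(al, tf$models)
  expect_equal(nrow(jc), 1L)
  expect_equal(jc$start, 1201L)
  expect_equal(jc$end, 1350L)
  expect_equal(jc$support, 3L)   # distinct ESTs, de-duplicated
  expect_true(jc$annotated)
  expect_equal(jc$donor, 1201L)  # + strand: donor at the 5' boundary
})

test_that("concordance is the exact-interval match fraction", {
  tf <- toy_genome_models()
  jc <- jc_tbl("g1", c(1201L, 1201L, 1210L, 1220L, 1230L),
               c(1350L, 1340L, 1350L, 1360L, 1370L))
  jc$annotated <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(junction_concordance(jc), 0.2)
  expect_equal(junction_concordance(jc, tf$models), 0.2)
  jc_all <- jc_tbl("g1", 1201L, 1350L)
  expect_equal(junction_concordance(jc_all, tf$models), 1)
  # 4 of 5 observed annotated -> 0.8
  jc4 <- jc
  jc4$annotated <- c(rep(TRUE, 4), FALSE)
  expect_equal(junction_concordance(jc4), 0.8)
})

test_that("intron pairs classify into AltD/AltA/AltP by shared boundaries", {
  tf <- toy_genome_models()
  al <- aln_row("G|g2|r0", "g2", blocks_df(1, 50, 1101, 1150))
  # shared 5' coordinate, different 3' -> AltA on the + strand
  ev <- classify_events(jc_tbl("g2", c(201, 201) + 1000,
                               c(350, 380) + 1000), al, tf$models)
  ev <- ev[ev$type != "IntronR", ]
  expect_equal(ev$type, "AltA")
  # shared 3' coordinate -> AltD
  ev <- classify_events(jc_tbl("g2", c(201, 181) + 1000,
                               c(350, 350) + 1000), al, tf$models)
  ev <- ev[ev$type != "IntronR", ]
  expect_equal(ev$type, "AltD")
  # overlap, no shared boundary -> AltP
  ev <- classify_events(jc_tbl("g2", c(201, 231) + 1000,
                               c(350, 370) + 1000), al, tf$models)
  ev <- ev[ev$type != "IntronR", ]
  expect_equal(ev$type, "AltP")
})

test_that("the same junction pattern swaps AltD and AltA on the minus strand", {
  tf <- toy_genome_models()
  al <- aln_row("G|g2|r0", "g2", blocks_df(1, 50, 1101, 1150))
  jc_minus <- jc_tbl("g2", c(1201, 1201), c(1350, 1380), strand = "-")
  models_m <- tf$models
  models_m$genes$strand[models_m$genes$gene_id == "g2"] <- "-"
  ev <- classify_events(jc_minus, al, models_m)
  ev <- ev[ev$type != "IntronR", ]
  expect_equal(ev$type, "AltD")  # shared 5' coordinate = shared acceptor here
})

test_that("an ExonS triple is recognised and consumes its side pairs", {
  tf <- toy_genome_models()
  al <- aln_row("G|g2|r0", "g2", blocks_df(1, 50, 1101, 1150))
  jc <- jc_tbl("g2", c(1201, 1341, 1201), c(1300, 1420, 1420))
  ev <- classify_events(jc, al, tf$models)
  ev <- ev[ev$type != "IntronR", ]
  expect_equal(ev$type, "ExonS")
  expect_equal(ev$skipped_start, 1301L)
  expect_equal(ev$skipped_end, 1340L)
  expect_equal(nrow(ev), 1L)  # no residual AltD/AltA from the triple
})

test_that("intron retention needs contiguous coverage beyond both boundaries", {
  tf <- toy_genome_models()
  # one EST spans the whole annotated intron with wide margins
  al <- dplyr::bind_rows(
    aln_row("G|g1|r1", "g1", blocks_df(1, 250, 1151, 1400)),
    # another EST stops 3 nt past the donor: no retention evidence
    aln_row("G|g1|r2", "g1", blocks_df(1, 100, 1105, 1204))
  )
  jc <- extract_junctions(al, tf$models)  # no junctions at all here
  ev <- classify_events(jc, al, tf$models)
  expect_equal(ev$type, "IntronR")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$intron1_start, 1201L)
  expect_equal(ev$intron1_end, 1350L)
  # with only the truncated EST there is no event
  ev2 <- classify_events(jc, al[2, ], tf$models)
  expect_equal(nrow(ev2), 0L)
})

test_that("event introns come from the junction union and tallies add up", {
  tf <- toy_genome_models()
  al <- aln_row("G|g2|r0", "g2", blocks_df(1, 50, 1101, 1150))
  jc <- jc_tbl("g2", c(1201, 1201, 1211), c(1350, 1380, 1370))
  ev <- classify_events(jc, al, tf$models)
  uni_key <- paste(jc$start, jc$end)
  for (i in seq_len(nrow(ev))) {
    expect_true(paste(ev$intron1_start[i], ev$intron1_end[i]) %in% uni_key)
    if (!is.na(ev$intron2_start[i])) {
      expect_true(paste(ev$intron2_start[i], ev$intron2_end[i]) %in% uni_key)
    }
  }
  sm <- summarize_as(ev)
  expect_equal(sum(sm$n_events), nrow(ev))
  expect_equal(sum(sm$pct_events), 100)
})

test_that("summaries tabulate events and genes per type, zeros included", {
  ev <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g1", type = "AltA"),
    tibble::tibble(gene_id = "g1", type = "AltA"),
    tibble::tibble(gene_id = "g2", type = "IntronR"))
  sm <- summarize_as(ev)
  expect_equal(sm$n_events[sm$type == "AltA"], 2L)
  expect_equal(sm$n_genes[sm$type == "AltA"], 1L)
  expect_equal(sm$n_events[sm$type == "IntronR"], 1L)
  expect_equal(sm$n_events[sm$type == "ExonS"], 0L)
  sm0 <- summarize_as(ev[0, ])
  expect_true(all(sm0$n_events == 0L))
  expect_equal(nrow(sm0), 5L)
})

test_that("the simulator's injected events are recovered as the event table", {
  cfg <- simulation_config(
    n_chromosomes = 1L, n_genes = 12L, n_de_genes = 0L,
    base_expression = 20, library_sizes = c(G = 400L, H = 400L),
    n_as_events_per_type = c(1L, 1L, 1L, 1L, 1L),
    n_snps = 0L, n_indels = 0L, n_ssr_loci = 0L,
    homopolymer_error_rate = 0, seed = 5L)
  sim <- generate_genome(cfg)
  lib <- simulate_libraries(sim)
  mp <- map_reads(c(lib$reads$G, lib$reads$H), sim$genome, sim$models)
  jc <- extract_junctions(mp$alignments, sim$models)
  ev <- classify_events(jc, mp$alignments, sim$models)
  expect_true(all(match_as_truth(ev, sim$truth$as)))
  expect_equal(nrow(ev), nrow(sim$truth$as))
  sm <- summarize_as(ev)
  expect_true(all(sm$n_events == 1L))
})
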