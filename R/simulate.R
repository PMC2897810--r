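#' Simulation configuration for the synthetic EST study
#'
#' Defines the conditions of the emulated two-library 454-style EST study:
#' two cDNA libraries (tagged `G` and `H`, one per near-isogenic line) are
#' sampled from multi-exon gene models on a small synthetic genome, with
#' injected differential expression, all five alternative-splicing event
#' types, UTR microsatellites, inter-line SNPs/indels, and homopolymer
#' sequencing errors.
#'
#' @param n_chromosomes number of chromosomes.
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param exon_len,intron_len integer ranges (nt) for exon and intron lengths.
#'   Introns always carry GT..AG splice signals on the transcribed strand.
#' @param flank_utr_len target UTR length (nt) at each transcript end; the
#'   realised UTR is capped by the terminal exon length. SSRs are injected
#'   into UTRs, mirroring their known enrichment there.
#' @param n_de_genes number of differentially expressed genes; half are
#'   up-regulated in library G (true fold `de_fold`), half in H (`1/de_fold`).
#' @param de_fold true fold change (> 1) of DE genes.
#' @param base_expression mean expected reads per gene per library (the
#'   per-gene rates are gamma-distributed around this mean; reads are then
#'   multinomial given the fixed library size).
#' @param library_sizes exact read counts of libraries G and H.
#' @param read_len_mean,read_len_sd,read_len_min read-length model (nt);
#'   lengths are normal, rounded, clamped to `[read_len_min, transcript]`.
#' @param homopolymer_error_rate per-homopolymer-run probability of a 1-base
#'   insertion or deletion (equal odds), applied to runs of length >= 3 —
#'   the characteristic 454 error mode.
#' @param n_as_events_per_type counts of injected alternative-splicing events,
#'   in the order AltD, AltA, AltP, IntronR, ExonS (one event per gene).
#' @param alt_isoform_fraction fraction of a spliced gene's reads drawn from
#'   its alternative isoform.
#' @param n_snps,n_indels inter-line substitutions / 1-base indels.
#' @param n_ssr_loci number of injected UTR microsatellites.
#' @param seed integer seed driving a single RNG stream; all sub-stages draw
#'   from it in a fixed order.
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_chromosomes = 2L,
                              n_genes = 60L,
                              exons_per_gene = c(2L, 6L),
                              exon_len = c(90L, 300L),
                              intron_len = c(60L, 400L),
                              flank_utr_len = 250L,
                              n_de_genes = 6L,
                              de_fold = 4,
                              base_expression = 25,
                              library_sizes = c(G = 2000L, H = 2000L),
                              read_len_mean = 175,
                              read_len_sd = 50,
                              read_len_min = 60L,
                              homopolymer_error_rate = 0.01,
                              n_as_events_per_type = c(AltD = 2L, AltA = 2L,
                                                       AltP = 2L, IntronR = 2L,
                                                       ExonS = 2L),
                              alt_isoform_fraction = 0.5,
                              n_snps = 8L,
                              n_indels = 4L,
                              n_ssr_loci = 6L,
                              seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene), exon_len = as.integer(exon_len),
    intron_len = as.integer(intron_len), flank_utr_len = as.integer(flank_utr_len),
    n_de_genes = as.integer(n_de_genes), de_fold = de_fold,
    base_expression = base_expression,
    library_sizes = stats::setNames(as.integer(library_sizes), c("G", "H")),
    read_len_mean = read_len_mean, read_len_sd = read_len_sd,
    read_len_min = as.integer(read_len_min),
    homopolymer_error_rate = homopolymer_error_rate,
    n_as_events_per_type = stats::setNames(
      as.integer(n_as_events_per_type),
      c("AltD", "AltA", "AltP", "IntronR", "ExonS")),
    alt_isoform_fraction = alt_isoform_fraction,
    n_snps = as.integer(n_snps), n_indels = as.integer(n_indels),
    n_ssr_loci = as.integer(n_ssr_loci), seed = as.integer(seed)
  )
  counts <- c(cfg$n_chromosomes, cfg$n_genes, cfg$n_de_genes,
              cfg$library_sizes, cfg$n_as_events_per_type, cfg$n_snps,
              cfg$n_indels, cfg$n_ssr_loci)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$n_de_genes > 0 && cfg$de_fold <= 1) stop("de_fold must be > 1")
  if (cfg$read_len_mean <= 0) stop("read_len_mean must be > 0")
  if (cfg$intron_len[1] < 40L) stop("intron_len minimum must be >= 40 nt")
  if (cfg$exon_len[1] < 30L) stop("exon_len minimum must be >= 30 nt")
  ev <- cfg$n_as_events_per_type
  if (sum(ev[c("AltD", "AltA", "AltP", "IntronR")]) > 0 &&
      cfg$exons_per_gene[2] < 2L) {
    stop("infeasible config: AltD/AltA/AltP/IntronR events need an intron, ",
         "but exons_per_gene allows only single-exon genes")
  }
  if (ev[["ExonS"]] > 0 && cfg$exons_per_gene[2] < 3L) {
    stop("infeasible config: ExonS events need >= 3 exons, ",
         "but exons_per_gene caps below 3")
  }
  if (sum(ev) + cfg$n_ssr_loci > cfg$n_genes) {
    stop("infeasible config: n_genes too small to host the requested ",
         "AS events and SSR loci on distinct genes")
  }
  structure(cfg, class = "sim_config")
}

ssr_threshold <- function(u) ifelse(u == 2L, 6L, 5L)

# TRUE if a homopolymer run of length >= 3 overlaps [pos-1, pos+1] on seq
# (the rejection window of the indel SNP filter).
has_run3_near <- function(seq, pos) {
  lo <- max(1L, pos - 3L)
  win <- substr(seq, lo, min(nchar(seq), pos + 3L))
  runs <- homopolymer_runs(win)
  runs$start <- runs$start + lo - 1L
  runs$end <- runs$end + lo - 1L
  any(runs$length >= 3L & runs$start <= pos + 1L & runs$end >= pos - 1L)
}

sample_range <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(rng[1]:rng[2], n, replace = TRUE)
}

set_substr <- function(s, start, value) {
  substr(s, start, start + nchar(value) - 1L) <- value
  s
}

# Write the splice signal of an intron (genomic interval, gene strand) into a
# chromosome string: donor at the transcribed 5' boundary, acceptor at the 3'.
write_splice_signal <- function(chrom_seq, start, end, strand) {
  if (strand == "+") {
    chrom_seq <- set_substr(chrom_seq, start, "GT")
    chrom_seq <- set_substr(chrom_seq, end - 1L, "AG")
  } else {
    chrom_seq <- set_substr(chrom_seq, start, "CT")
    chrom_seq <- set_substr(chrom_seq, end - 1L, "AC")
  }
  chrom_seq
}

#' Generate a synthetic genome with gene models and (partial) truth tables
#'
#' Builds random multi-exon genes with GT..AG introns on the transcribed
#' strand, places them with intergenic spacing on `n_chromosomes`, then
#' injects: alternative isoforms realising the five alternative-splicing
#' event types (one event per gene, splice signals written into the genome),
#' UTR microsatellites, inter-line SNP/indel alleles (recorded, not written —
#' the genome is the line-G reference), per-gene expression rates, and the DE
#' gene set. Deterministic for a fixed `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list of class `sim_genome` with elements `genome` (named character
#'   vector), `models` ([gene_models]), `isoforms` / `iso_exons` (alternative
#'   isoform structures), `truth` (list of tibbles `de`, `as`, `snp`, `ssr`,
#'   `expression`), and `config`.
#' @export
generate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  ## -- stage 1: gene structures (transcript orientation) ------------------
  structs <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    n_ex <- sample_range(cfg$exons_per_gene)
    ex_lens <- sample_range(cfg$exon_len, n_ex)
    in_lens <- if (n_ex > 1) sample_range(cfg$intron_len, n_ex - 1L) else integer(0)
    ex_seqs <- vapply(ex_lens, random_dna, character(1))
    in_seqs <- vapply(in_lens, function(l) {
      paste0("GT", random_dna(l - 4L), "AG")
    }, character(1))
    structs[[i]] <- list(n_ex = n_ex, ex_lens = ex_lens, in_lens = in_lens,
                         ex_seqs = ex_seqs, in_seqs = in_seqs,
                         strand = sample(c("+", "-"), 1))
  }

  ## -- stage 2: chromosome assembly ---------------------------------------
  gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), cfg$n_genes))
  chrom_ids <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  chrom_seqs <- stats::setNames(rep("", cfg$n_chromosomes), chrom_ids)
  gene_rows <- list(); exon_rows <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    parts <- list(random_dna(1000L))
    cursor <- 1000L
    for (i in which(chrom_of == ci)) {
      st <- structs[[i]]
      # interleave exons/introns in transcript orientation, then orient
      tx_parts <- character(2L * st$n_ex - 1L)
      tx_parts[seq(1L, by = 2L, length.out = st$n_ex)] <- st$ex_seqs
      if (st$n_ex > 1)
        tx_parts[seq(2L, by = 2L, length.out = st$n_ex - 1L)] <- st$in_seqs
      gseq <- paste(tx_parts, collapse = "")
      if (st$strand == "-") gseq <- revcomp(gseq)
      gstart <- cursor + 1L
      gend <- cursor + nchar(gseq)
      # genomic exon lengths: transcript order for '+', reversed for '-'
      glens_ex <- if (st$strand == "+") st$ex_lens else rev(st$ex_lens)
      glens_in <- if (st$strand == "+") st$in_lens else rev(st$in_lens)
      piece_lens <- integer(2L * st$n_ex - 1L)
      piece_lens[seq(1L, by = 2L, length.out = st$n_ex)] <- glens_ex
      if (st$n_ex > 1)
        piece_lens[seq(2L, by = 2L, length.out = st$n_ex - 1L)] <- glens_in
      piece_ends <- gstart - 1L + cumsum(piece_lens)
      piece_starts <- piece_ends - piece_lens + 1L
      ex_idx <- seq(1L, by = 2L, length.out = st$n_ex)
      # UTR lengths in transcript orientation
      utr5 <- min(cfg$flank_utr_len, st$ex_lens[1] - 10L)
      utr3 <- min(cfg$flank_utr_len, st$ex_lens[st$n_ex] - 10L)
      txlen <- sum(st$ex_lens)
      if (st$strand == "+") {
        cds_start <- gstart + utr5
        cds_end <- gend - utr3
      } else {
        cds_start <- gstart + utr3
        cds_end <- gend - utr5
      }
      gene_rows[[i]] <- tibble(
        gene_id = gene_ids[i], chrom = chrom_ids[ci], strand = st$strand,
        start = gstart, end = gend, cds_start = cds_start, cds_end = cds_end,
        n_exons = st$n_ex, tx_len = txlen, utr5 = utr5, utr3 = utr3
      )
      exon_rows[[i]] <- tibble(
        gene_id = gene_ids[i], chrom = chrom_ids[ci], strand = st$strand,
        start = piece_starts[ex_idx], end = piece_ends[ex_idx]
      )
      parts <- c(parts, list(gseq, random_dna(sample(2100:3500, 1))))
      cursor <- gend + nchar(parts[[length(parts)]])
    }
    chrom_seqs[ci] <- paste(unlist(parts), collapse = "")
  }
  genes_tbl <- bind_rows(gene_rows)
  exons_tbl <- bind_rows(exon_rows)

  ## -- stage 3: alternative isoforms ---------------------------------------
  types <- rep(names(cfg$n_as_events_per_type), cfg$n_as_events_per_type)
  # ExonS first: it needs >= 3 exons
  types <- types[order(types != "ExonS")]
  eligible <- genes_tbl$gene_id[genes_tbl$n_exons >= 2L]
  eligible3 <- genes_tbl$gene_id[genes_tbl$n_exons >= 3L]
  as_rows <- list(); iso_rows <- list(); iso_exon_rows <- list()
  used_genes <- character(0)
  for (t in seq_along(types)) {
    ty <- types[t]
    pool <- setdiff(if (ty == "ExonS") eligible3 else eligible, used_genes)
    if (length(pool) == 0) {
      stop("infeasible config: no remaining multi-exon gene for a ", ty,
           " event (", if (ty == "ExonS") ">= 3 exons" else ">= 2 exons",
           " required)")
    }
    gid <- sample(pool, 1)
    used_genes <- c(used_genes, gid)
    g <- genes_tbl[genes_tbl$gene_id == gid, ]
    ex <- exons_tbl[exons_tbl$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    istarts <- head(ex$end, -1) + 1L
    iends <- tail(ex$start, -1) - 1L
    strand <- g$strand
    d <- 9L
    alt_ex <- ex[, c("start", "end")]
    if (ty %in% c("AltD", "AltA", "AltP")) {
      ii <- sample(length(istarts), 1)
      s <- istarts[ii]; e <- iends[ii]
      if (ty == "AltD") {
        alt <- if (strand == "+") c(s + d, e) else c(s, e - d)
      } else if (ty == "AltA") {
        alt <- if (strand == "+") c(s, e - d) else c(s + d, e)
      } else {
        alt <- c(s + 6L, e - 6L)
      }
      chrom_seqs[[g$chrom]] <-
        write_splice_signal(chrom_seqs[[g$chrom]], alt[1], alt[2], strand)
      alt_ex$end[ii] <- alt[1] - 1L
      alt_ex$start[ii + 1L] <- alt[2] + 1L
      as_rows[[t]] <- tibble(
        event_id = sprintf("as%03d", t), type = ty, gene_id = gid,
        chrom = g$chrom, strand = strand,
        alt_start = alt[1], alt_end = alt[2], ref_start = s, ref_end = e,
        ref2_start = NA_integer_, ref2_end = NA_integer_,
        skipped_start = NA_integer_, skipped_end = NA_integer_
      )
    } else if (ty == "IntronR") {
      # prefer a short intron so one EST can bridge it with margin
      ii <- which.min(iends - istarts)
      s <- istarts[ii]; e <- iends[ii]
      alt_ex <- alt_ex[-(ii + 1L), ]
      alt_ex$end[ii] <- ex$end[ii + 1L]
      as_rows[[t]] <- tibble(
        event_id = sprintf("as%03d", t), type = ty, gene_id = gid,
        chrom = g$chrom, strand = strand,
        alt_start = s, alt_end = e, ref_start = s, ref_end = e,
        ref2_start = NA_integer_, ref2_end = NA_integer_,
        skipped_start = NA_integer_, skipped_end = NA_integer_
      )
    } else { # ExonS: skip an internal exon
      m <- sample(2:(nrow(ex) - 1L), 1)
      long_s <- istarts[m - 1L]; long_e <- iends[m]
      alt_ex <- alt_ex[-m, ]
      as_rows[[t]] <- tibble(
        event_id = sprintf("as%03d", t), type = ty, gene_id = gid,
        chrom = g$chrom, strand = strand,
        alt_start = long_s, alt_end = long_e,
        ref_start = istarts[m - 1L], ref_end = iends[m - 1L],
        ref2_start = istarts[m], ref2_end = iends[m],
        skipped_start = ex$start[m], skipped_end = ex$end[m]
      )
    }
    tx_id <- paste0(gid, ".alt")
    iso_rows[[t]] <- tibble(tx_id = tx_id, gene_id = gid, kind = "alt",
                            event_id = sprintf("as%03d", t))
    iso_exon_rows[[t]] <- tibble(tx_id = tx_id, gene_id = gid,
                                 chrom = g$chrom, strand = strand,
                                 start = alt_ex$start, end = alt_ex$end)
  }
  as_truth <- if (length(as_rows)) bind_rows(as_rows) else tibble(
    event_id = character(0), type = character(0), gene_id = character(0),
    chrom = character(0), strand = character(0),
    alt_start = integer(0), alt_end = integer(0),
    ref_start = integer(0), ref_end = integer(0),
    ref2_start = integer(0), ref2_end = integer(0),
    skipped_start = integer(0), skipped_end = integer(0))

  ## -- stage 4: UTR microsatellites ----------------------------------------
  ssr_rows <- list()
  ssr_genes <- character(0)
  if (cfg$n_ssr_loci > 0) {
    pool <- setdiff(genes_tbl$gene_id, used_genes)
    for (t in seq_len(cfg$n_ssr_loci)) {
      u <- sample(2:6, 1, prob = c(0.40, 0.40, 0.10, 0.06, 0.04))
      repeat {
        motif <- random_dna(u)
        if (primitive_motif(motif) &&
            length(unique(strsplit(motif, "")[[1]])) > 1) break
      }
      k <- ssr_threshold(u) + sample(1:4, 1)
      len <- u * k
      placed <- FALSE
      for (try in 1:200) {
        gid <- sample(setdiff(pool, ssr_genes), 1)
        g <- genes_tbl[genes_tbl$gene_id == gid, ]
        which_utr <- sample(c("5", "3"), 1)
        margin <- 60L
        utr_len <- if (which_utr == "5") g$utr5 else g$utr3
        lo <- if (which_utr == "5") margin + 1L else g$tx_len - utr_len + margin + 1L
        hi <- (if (which_utr == "5") utr_len else g$tx_len) - len - margin
        if (hi < lo) next
        p <- sample(lo:hi, 1)
        # write into the genome (UTRs sit inside the terminal exons, so the
        # transcript interval is genomically contiguous)
        ex <- exons_tbl[exons_tbl$gene_id == gid, ]
        gpos <- tx_to_genome(ex$start, ex$end, g$strand,
                             c(p - 1L, p, p + len - 1L, p + len))
        run <- strrep(motif, k)
        mfirst <- substr(motif, 1, 1); mlast <- substr(motif, u, u)
        before <- sample(setdiff(c("A", "C", "G", "T"), mlast), 1)
        after <- sample(setdiff(c("A", "C", "G", "T"), mfirst), 1)
        tx_piece <- paste0(before, run, after)
        gpiece <- if (g$strand == "+") tx_piece else revcomp(tx_piece)
        cs <- chrom_seqs[[g$chrom]]
        gleft <- min(gpos)
        cs <- set_substr(cs, gleft, gpiece)
        chrom_seqs[[g$chrom]] <- cs
        ssr_genes <- c(ssr_genes, gid)
        ssr_rows[[t]] <- tibble(
          seq_id = gid, motif = motif, canonical = canonical_motif(motif),
          unit_len = u, n_repeats = k, tx_start = p, tx_end = p + len - 1L
        )
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place SSR locus ", t,
                        ": no UTR long enough for a ", len, " nt repeat")
    }
  }
  ssr_truth <- if (length(ssr_rows)) bind_rows(ssr_rows) else tibble(
    seq_id = character(0), motif = character(0), canonical = character(0),
    unit_len = integer(0), n_repeats = integer(0),
    tx_start = integer(0), tx_end = integer(0))
  used_genes <- c(used_genes, ssr_genes)

  ## -- stage 5: inter-line SNPs and indels ---------------------------------
  snp_rows <- list()
  n_var <- cfg$n_snps + cfg$n_indels
  if (n_var > 0) {
    pool <- setdiff(genes_tbl$gene_id, used_genes)
    if (length(pool) == 0) pool <- setdiff(genes_tbl$gene_id, as_truth$gene_id)
    taken <- tibble(gene_id = character(0), tx_pos = integer(0))
    for (t in seq_len(n_var)) {
      is_indel <- t > cfg$n_snps
      ok <- FALSE
      for (try in 1:500) {
        gid <- sample(pool, 1)
        g <- genes_tbl[genes_tbl$gene_id == gid, ]
        ex <- exons_tbl[exons_tbl$gene_id == gid, ]
        ex <- ex[order(ex$start), ]
        # transcript positions of exon boundaries
        lens <- if (g$strand == "+") ex$end - ex$start + 1L else rev(ex$end - ex$start + 1L)
        bounds <- cumsum(lens)
        p <- sample(seq(g$utr5 + 11L, g$tx_len - g$utr3 - 10L), 1)
        dist_j <- min(abs(p - c(0L, bounds)), abs(p - (c(0L, bounds) + 1L)))
        if (dist_j < 12L) next
        if (any(taken$gene_id == gid & abs(taken$tx_pos - p) < 25L)) next
        gpos <- tx_to_genome(ex$start, ex$end, g$strand, p)
        cs <- chrom_seqs[[g$chrom]]
        around <- substr(cs, gpos - 3L, gpos + 3L)
        ref_fwd <- substr(cs, gpos, gpos)
        ref_tx <- if (g$strand == "+") ref_fwd else chartr("ACGT", "TGCA", ref_fwd)
        if (!is_indel) {
          alt_tx <- sample(setdiff(c("A", "C", "G", "T"), ref_tx), 1)
          alt_fwd <- if (g$strand == "+") alt_tx else chartr("ACGT", "TGCA", alt_tx)
          cls <- classify_variant(c(ref_tx, alt_tx))
          snp_rows[[t]] <- tibble(
            gene_id = gid, tx_pos = p, chrom = g$chrom, gpos = gpos,
            allele_G = ref_tx, allele_H = alt_tx,
            allele_G_fwd = ref_fwd, allele_H_fwd = alt_fwd,
            class = cls, indel_kind = NA_character_
          )
          ok <- TRUE
        } else {
          kind <- if (t %% 2L == 0L) "del" else "ins"
          if (kind == "del") {
            # delete transcript base p in line H; needs a locally unique base
            # (unambiguous gap placement) and no homopolymer run >= 3
            # overlapping [gpos-1, gpos+1] (so the call survives filtering)
            nb <- strsplit(substr(cs, gpos - 1L, gpos + 1L), "")[[1]]
            if (nb[2] == nb[1] || nb[2] == nb[3]) next
            if (has_run3_near(cs, gpos)) next
            snp_rows[[t]] <- tibble(
              gene_id = gid, tx_pos = p, chrom = g$chrom, gpos = gpos,
              allele_G = ref_tx, allele_H = "-",
              allele_G_fwd = ref_fwd, allele_H_fwd = "-",
              class = "indel", indel_kind = "del"
            )
          } else {
            # insert base b after transcript position p in line H
            nxt_tx_gpos <- tx_to_genome(ex$start, ex$end, g$strand, p + 1L)
            gleft <- min(gpos, nxt_tx_gpos)  # forward-strand left flank
            lbase <- substr(cs, gleft, gleft)
            rbase <- substr(cs, gleft + 1L, gleft + 1L)
            cand <- setdiff(c("A", "C", "G", "T"), c(lbase, rbase))
            if (has_run3_near(cs, gleft) || has_run3_near(cs, gleft + 1L)) next
            b_fwd <- sample(cand, 1)
            b_tx <- if (g$strand == "+") b_fwd else chartr("ACGT", "TGCA", b_fwd)
            snp_rows[[t]] <- tibble(
              gene_id = gid, tx_pos = p, chrom = g$chrom, gpos = gleft,
              allele_G = "-", allele_H = b_tx,
              allele_G_fwd = "-", allele_H_fwd = b_fwd,
              class = "indel", indel_kind = "ins"
            )
          }
          ok <- TRUE
        }
        if (ok) {
          taken <- bind_rows(taken, tibble(gene_id = gid, tx_pos = p))
          break
        }
      }
      if (!ok) stop("could not place variant ", t, " under the homopolymer ",
                    "and uniqueness constraints")
    }
  }
  snp_truth <- if (length(snp_rows)) bind_rows(snp_rows) else tibble(
    gene_id = character(0), tx_pos = integer(0), chrom = character(0),
    gpos = integer(0), allele_G = character(0), allele_H = character(0),
    allele_G_fwd = character(0), allele_H_fwd = character(0),
    class = character(0), indel_kind = character(0))

  ## -- stage 6: expression rates and DE assignment -------------------------
  w <- rgamma(cfg$n_genes, shape = 2, rate = 2) * cfg$base_expression
  fold <- rep(1, cfg$n_genes)
  if (cfg$n_de_genes > 0) {
    de_idx <- sample(cfg$n_genes, cfg$n_de_genes)
    n_up <- ceiling(cfg$n_de_genes / 2)
    fold[de_idx[seq_len(n_up)]] <- cfg$de_fold
    if (cfg$n_de_genes > n_up)
      fold[de_idx[(n_up + 1):cfg$n_de_genes]] <- 1 / cfg$de_fold
  }
  expr <- tibble(gene_id = gene_ids, expr_weight = w, fold = fold)
  de_truth <- expr %>% filter(.data$fold != 1) %>% select("gene_id", "fold")

  models <- gene_models(
    genes_tbl %>% select("gene_id", "chrom", "strand", "start", "end",
                         "cds_start", "cds_end", "n_exons"),
    exons_tbl
  )
  structure(list(
    genome = chrom_seqs,
    models = models,
    genes_extra = genes_tbl %>% select("gene_id", "tx_len", "utr5", "utr3"),
    isoforms = if (length(iso_rows)) bind_rows(iso_rows) else
      tibble(tx_id = character(0), gene_id = character(0),
             kind = character(0), event_id = character(0)),
    iso_exons = if (length(iso_exon_rows)) bind_rows(iso_exon_rows) else
      tibble(tx_id = character(0), gene_id = character(0), chrom = character(0),
             strand = character(0), start = integer(0), end = integer(0)),
    truth = list(de = de_truth, as = as_truth, snp = snp_truth,
                 ssr = ssr_truth, expression = expr),
    config = cfg
  ), class = "sim_genome")
}

# Apply a gene's inter-line edits (from snp_truth) to its reference
# transcript, producing the line-H transcript. Edits are in transcript
# coordinates and applied right-to-left.
apply_line_edits <- function(tx, edits) {
  if (nrow(edits) == 0) return(tx)
  edits <- edits[order(-edits$tx_pos), , drop = FALSE]
  ch <- strsplit(tx, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (is.na(e$indel_kind)) {
      ch[e$tx_pos] <- e$allele_H
    } else if (e$indel_kind == "del") {
      ch <- ch[-e$tx_pos]
    } else {
      ch <- append(ch, e$allele_H, after = e$tx_pos)
    }
  }
  paste(ch, collapse = "")
}

# Inject 454-style homopolymer indels: each run of length >= 3 suffers, with
# probability `rate`, a 1-base insertion or deletion (equal odds).
inject_homopolymer_errors <- function(read, rate) {
  if (rate <= 0) return(read)
  runs <- homopolymer_runs(read)
  runs <- runs[runs$length >= 3L, , drop = FALSE]
  if (nrow(runs) == 0) return(read)
  hit <- runif(nrow(runs)) < rate
  if (!any(hit)) return(read)
  ch <- strsplit(read, "", fixed = TRUE)[[1]]
  for (i in rev(which(hit))) {
    if (runif(1) < 0.5) {
      ch <- append(ch, runs$base[i], after = runs$start[i])
    } else {
      ch <- ch[-runs$start[i]]
    }
  }
  paste(ch, collapse = "")
}

#' Simulate the two EST libraries from a synthetic genome
#'
#' Draws exactly `config$library_sizes` reads per library. Per-gene expected
#' read counts are proportional to the gene's expression rate, with DE genes
#' scaled by their true fold in library G. Reads are sampled uniformly along
#' transcripts with normal lengths, random orientation, line-specific SNP
#' alleles in every library-H read, and homopolymer indels at the configured
#' rate. For every injected alternative-splicing event a small set of
#' deterministic junction-spanning reads is emitted in each library so the
#' event is observable in the EST evidence; they count toward the library
#' size. Read IDs are `LIB|gene|serial` — the library tag is the prefix
#' before the first `|`.
#'
#' @param sim a `sim_genome` from [generate_genome()].
#' @param seed seed for the library-sampling RNG stream (the genome stream is
#'   `config$seed`; library draws get their own documented stream so several
#'   library realisations can share one genome).
#' @return list of class `sim_libraries`: `reads` (list of two named character
#'   vectors, `G` and `H`), `source_counts` (realised per-gene read counts),
#'   updated `truth$expression` with expected counts, and `sim`.
#' @export
simulate_libraries <- function(sim, seed = sim$config$seed + 1000L) {
  stopifnot(inherits(sim, "sim_genome"))
  cfg <- sim$config
  set.seed(seed)
  ref_tx <- transcript_seqs(sim$genome, sim$models)
  alt_tx <- if (nrow(sim$iso_exons) > 0) {
    extract_tx_seqs(sim$genome, sim$iso_exons)
  } else character(0)
  expr <- sim$truth$expression
  gene_ids <- expr$gene_id
  snp_by_gene <- split(sim$truth$snp, sim$truth$snp$gene_id)
  h_tx <- ref_tx
  for (gid in names(snp_by_gene)) {
    h_tx[[gid]] <- apply_line_edits(ref_tx[[gid]], snp_by_gene[[gid]])
  }
  # alt isoforms per gene (AS genes carry no SNPs by construction)
  alt_of <- stats::setNames(sim$isoforms$tx_id, sim$isoforms$gene_id)

  ## deterministic junction-spanning reads per AS event
  guaranteed <- list(G = character(0), H = character(0))
  if (nrow(sim$truth$as) > 0) {
    for (i in seq_len(nrow(sim$truth$as))) {
      ev <- sim$truth$as[i, ]
      iso_id <- alt_of[[ev$gene_id]]
      iso_ex <- sim$iso_exons[sim$iso_exons$tx_id == iso_id, ]
      iso_ex <- iso_ex[order(iso_ex$start), ]
      txseq <- alt_tx[[iso_id]]
      txlen <- nchar(txseq)
      lens <- iso_ex$end - iso_ex$start + 1L
      cum <- cumsum(lens)
      if (ev$type == "IntronR") {
        # cover the retained intron plus 30 nt margins
        ilen <- ev$alt_end - ev$alt_start + 1L
        # transcript position of the intron start within the retention isoform
        k <- which(iso_ex$start <= ev$alt_start & iso_ex$end >= ev$alt_end)
        off_in_exon <- ev$alt_start - iso_ex$start[k]
        pos_fwd <- c(0L, cum)[k] + off_in_exon  # last base before intron, + strand
        jpos <- if (ev$strand == "+") pos_fwd else txlen - (pos_fwd + ilen)
        len <- min(txlen, ilen + 60L)
        center <- jpos + ilen %/% 2L
      } else {
        # junction between the isoform exons flanking the alternative intron
        k <- max(which(iso_ex$end < ev$alt_start))
        jpos <- if (ev$strand == "+") cum[k] else txlen - cum[k]
        len <- min(txlen, as.integer(round(cfg$read_len_mean)))
        center <- jpos
      }
      start <- max(1L, min(center - len %/% 2L + 1L, txlen - len + 1L))
      piece <- substr(txseq, start, start + len - 1L)
      for (lib in c("G", "H")) {
        ids <- sprintf("%s|%s|%s_j%d", lib, ev$gene_id, ev$event_id, 1:2)
        guaranteed[[lib]] <- c(guaranteed[[lib]],
                               stats::setNames(rep(piece, 2), ids))
      }
    }
  }

  ## random reads
  w_G <- expr$expr_weight * ifelse(expr$fold >= 1, expr$fold, 1)
  w_H <- expr$expr_weight * ifelse(expr$fold < 1, 1 / expr$fold, 1)
  reads <- list(G = guaranteed$G, H = guaranteed$H)
  counts_mat <- matrix(0L, nrow = length(gene_ids), ncol = 2,
                       dimnames = list(gene_ids, c("G", "H")))
  for (lib in c("G", "H")) {
    n_rand <- cfg$library_sizes[[lib]] - length(guaranteed[[lib]])
    if (n_rand < 0) {
      stop("library_sizes too small for the guaranteed junction reads (",
           length(guaranteed[[lib]]), " needed)")
    }
    wts <- if (lib == "G") w_G else w_H
    per_gene <- as.integer(rmultinom(1, n_rand, wts))
    serial <- 0L
    out <- character(n_rand)
    nms <- character(n_rand)
    pos <- 1L
    for (gi in seq_along(gene_ids)) {
      ng <- per_gene[gi]
      if (ng == 0) next
      gid <- gene_ids[gi]
      base_tx <- if (lib == "H") h_tx[[gid]] else ref_tx[[gid]]
      a_tx <- if (!is.na(alt_of[gid])) alt_tx[[alt_of[[gid]]]] else NA_character_
      for (r in seq_len(ng)) {
        use_alt <- !is.na(a_tx) && runif(1) < cfg$alt_isoform_fraction
        txseq <- if (use_alt) a_tx else base_tx
        txlen <- nchar(txseq)
        len <- as.integer(round(rnorm(1, cfg$read_len_mean, cfg$read_len_sd)))
        len <- max(cfg$read_len_min, min(len, txlen))
        start <- sample.int(txlen - len + 1L, 1)
        piece <- substr(txseq, start, start + len - 1L)
        piece <- inject_homopolymer_errors(piece, cfg$homopolymer_error_rate)
        if (runif(1) < 0.5) piece <- revcomp(piece)
        serial <- serial + 1L
        out[pos] <- piece
        nms[pos] <- sprintf("%s|%s|r%06d", lib, gid, serial)
        pos <- pos + 1L
      }
    }
    names(out) <- nms
    reads[[lib]] <- c(reads[[lib]], out)
    counts_mat[, lib] <- per_gene
  }
  # guaranteed reads count toward their source genes
  for (lib in c("G", "H")) {
    if (length(guaranteed[[lib]]) > 0) {
      src <- vapply(strsplit(names(guaranteed[[lib]]), "|", fixed = TRUE),
                    `[`, character(1), 2)
      tb <- table(src)
      counts_mat[names(tb), lib] <- counts_mat[names(tb), lib] + as.integer(tb)
    }
  }
  expr$expected_G <- cfg$library_sizes[["G"]] * w_G / sum(w_G)
  expr$expected_H <- cfg$library_sizes[["H"]] * w_H / sum(w_H)
  expr$source_G <- counts_mat[, "G"]
  expr$source_H <- counts_mat[, "H"]
  truth <- sim$truth
  truth$expression <- expr
  structure(list(reads = reads,
                 source_counts = tibble(gene_id = gene_ids,
                                        G = unname(counts_mat[, "G"]),
                                        H = unname(counts_mat[, "H"])),
                 truth = truth, sim = sim, seed = seed),
            class = "sim_libraries")
}
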