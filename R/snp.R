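#' Per-position allele columns from spliced alignments
#'
#' A transparent column caller: every aligned read base is tallied per
#' genomic position and per line (the read-id prefix before the first `|`).
#' Small genomic gaps inside an alignment (below the intron threshold)
#' contribute gap (`-`) alleles at the deleted positions; read insertions
#' create extra columns keyed by (position of the left flanking base,
#' insertion index), where reads that span the flanking bases without the
#' insertion contribute `-`. Intron gaps contribute nothing. Deterministic.
#'
#' @param alignments tibble from [map_reads()] (best alignment per read).
#' @param reads named character vector of the read sequences.
#' @param genome named character vector or `DNAStringSet` (the consensus the
#'   columns are reported against).
#' @param min_intron genomic gaps of at least this size are introns, not
#'   deletions (default matches [align_params()]).
#' @return tibble of site columns: `chrom`, `pos`, `ins` (0 for reference
#'   columns), `consensus`, `cov_G`, `cov_H`, and list-columns `alleles_G`,
#'   `alleles_H` (named integer count vectors over `A,C,G,T,-`).
#' @export
pileup_columns <- function(alignments, reads, genome, min_intron = 40L) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  n_al <- nrow(alignments)
  pos_l <- vector("list", n_al); base_l <- vector("list", n_al)
  n_per <- integer(n_al)
  ins_tall <- list()
  spans <- list()  # contiguously aligned block spans, for insertion coverage
  for (i in seq_len(n_al)) {
    bl <- alignments$blocks[[i]]
    oriented <- reads[[alignments$read_id[i]]]
    if (alignments$strand[i] == "-") oriented <- revcomp(oriented)
    rch <- strsplit(oriented, "", fixed = TRUE)[[1]]
    line <- alignments$library[i]
    chrom <- alignments$chrom[i]
    nb <- nrow(bl)
    pos <- if (nb == 1L) bl$gstart:bl$gend else
      unlist(lapply(seq_len(nb), function(b) bl$gstart[b]:bl$gend[b]))
    base <- rch[if (nb == 1L) bl$qstart:bl$qend else
      unlist(lapply(seq_len(nb), function(b) bl$qstart[b]:bl$qend[b]))]
    spans[[i]] <- quick_df(read = rep(alignments$read_id[i], nb),
                           line = rep(line, nb), chrom = rep(chrom, nb),
                           start = bl$gstart, end = bl$gend)
    if (nb > 1) {
      for (b in 2:nb) {
        ggap <- bl$gstart[b] - bl$gend[b - 1L] - 1L
        qgap <- bl$qstart[b] - bl$qend[b - 1L] - 1L
        if (ggap >= min_intron) next
        if (ggap > 0 && qgap == 0) {
          dpos <- (bl$gend[b - 1L] + 1L):(bl$gstart[b] - 1L)
          pos <- c(pos, dpos)
          base <- c(base, rep("-", length(dpos)))
        } else if (qgap > 0 && ggap == 0) {
          ins_bases <- rch[(bl$qend[b - 1L] + 1L):(bl$qstart[b] - 1L)]
          ins_tall[[length(ins_tall) + 1L]] <- tibble(
            chrom = chrom, pos = bl$gend[b - 1L],
            ins = seq_along(ins_bases), line = line, allele = ins_bases,
            read = alignments$read_id[i])
        }
      }
    }
    pos_l[[i]] <- pos
    base_l[[i]] <- base
    n_per[i] <- length(pos)
  }
  tall_df <- tibble(
    chrom = rep(alignments$chrom, n_per),
    pos = unlist(pos_l, use.names = FALSE),
    ins = 0L,
    line = rep(alignments$library, n_per),
    allele = unlist(base_l, use.names = FALSE)
  )
  ins_df <- if (length(ins_tall)) bind_rows(ins_tall) else
    tibble(chrom = character(0), pos = integer(0), ins = integer(0),
           line = character(0), allele = character(0), read = character(0))
  # gap alleles at insertion columns for reads spanning the flank contiguously
  if (nrow(ins_df) > 0) {
    keys <- ins_df %>% distinct(.data$chrom, .data$pos) %>%
      left_join(ins_df %>% group_by(.data$chrom, .data$pos) %>%
                  summarise(max_ins = max(.data$ins), .groups = "drop"),
                by = c("chrom", "pos"))
    spans_df <- bind_rows(spans)
    gap_rows <- list()
    for (ki in seq_len(nrow(keys))) {
      kc <- keys$chrom[ki]; kp <- keys$pos[ki]; mi <- keys$max_ins[ki]
      cover <- spans_df %>% filter(.data$chrom == kc, .data$start <= kp,
                                   .data$end >= kp + 1L)
      for (ci in seq_len(nrow(cover))) {
        own <- ins_df %>% filter(.data$chrom == kc, .data$pos == kp,
                                 .data$read == cover$read[ci])
        miss <- setdiff(seq_len(mi), own$ins)
        if (length(miss) > 0) {
          gap_rows[[length(gap_rows) + 1L]] <- tibble(
            chrom = kc, pos = kp, ins = miss, line = cover$line[ci],
            allele = "-")
        }
      }
    }
    tall_df <- bind_rows(tall_df,
                         ins_df %>% select(-"read"),
                         bind_rows(gap_rows))
  }
  agg <- tall_df %>%
    group_by(.data$chrom, .data$pos, .data$ins, .data$line, .data$allele) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>%
    arrange(.data$chrom, .data$pos, .data$ins)
  key <- paste(agg$chrom, agg$pos, agg$ins, sep = "\r")
  grp <- split(seq_len(nrow(agg)), factor(key, levels = unique(key)))
  ng <- length(grp)
  first <- vapply(grp, `[`, integer(1), 1L)
  aG <- vector("list", ng); aH <- vector("list", ng)
  lines <- agg$line; alleles <- agg$allele; nn <- as.integer(agg$n)
  for (i in seq_len(ng)) {
    ix <- grp[[i]]
    gsel <- ix[lines[ix] == "G"]; hsel <- ix[lines[ix] == "H"]
    aG[[i]] <- stats::setNames(nn[gsel], alleles[gsel])
    aH[[i]] <- stats::setNames(nn[hsel], alleles[hsel])
  }
  cols <- tibble(
    chrom = agg$chrom[first], pos = agg$pos[first], ins = agg$ins[first],
    alleles_G = aG, alleles_H = aH
  )
  cols$consensus <- ifelse(
    cols$ins > 0L, "-",
    substring(genome[cols$chrom], cols$pos, cols$pos))
  cols$cov_G <- vapply(cols$alleles_G, function(a) sum(c(0L, a)), integer(1))
  cols$cov_H <- vapply(cols$alleles_H, function(a) sum(c(0L, a)), integer(1))
  cols %>% select("chrom", "pos", "ins", "consensus", "cov_G", "cov_H",
                  "alleles_G", "alleles_H")
}

#' Candidate variant sites
#'
#' Columns where the union of observed alleles across the two lines has at
#' least two members (within-line-only variation still qualifies here; it is
#' removed later by the disjointness filter).
#'
#' @param columns output of [pileup_columns()].
#' @return the candidate subset of `columns`.
#' @export
candidate_sites <- function(columns) {
  keep <- vapply(seq_len(nrow(columns)), function(i) {
    length(unique(c(names(columns$alleles_G[[i]]),
                    names(columns$alleles_H[[i]])))) >= 2L
  }, logical(1))
  columns[keep, , drop = FALSE]
}

#' Classify a variant by its allele set
#'
#' Indel if a gap allele is present; else transition iff the alleles are
#' within `{A,G}` or within `{C,T}`; else transversion.
#'
#' @param alleles character vector of alleles over `A,C,G,T,-`.
#' @return `"indel"`, `"transition"` or `"transversion"`.
#' @export
classify_variant <- function(alleles) {
  alleles <- unique(alleles)
  if ("-" %in% alleles) return("indel")
  if (all(alleles %in% c("A", "G")) || all(alleles %in% c("C", "T"))) {
    return("transition")
  }
  "transversion"
}

#' Apply the three inter-line SNP filters
#'
#' Candidate sites are kept only if they meet all of: (1) at least `min_cov`
#' reads at the site in each line; (2) if the site is an indel, no
#' homopolymer run of length >= 3 in the consensus overlaps the window
#' `[pos-1, pos+1]`; (3) the allele sets of the two lines are disjoint
#' (optionally also fixed within each line). Non-indel sites with more than
#' two alleles are additionally rejected, since transition/transversion
#' classes are defined for biallelic sites. All three criterion outcomes are
#' recorded per site.
#'
#' @param candidates output of [candidate_sites()].
#' @param genome named character vector or `DNAStringSet` providing the
#'   consensus sequence for the homopolymer check.
#' @param min_cov per-line coverage threshold (default 2).
#' @param require_within_line_fixation stricter criterion-3 mode: each line
#'   must show a single allele (off by default).
#' @return tibble: site keys, per-line allele strings, coverages, `class`,
#'   logical `pass_coverage`, `pass_homopolymer`, `pass_disjoint`,
#'   `biallelic`, and the final `pass`.
#' @export
apply_filters <- function(candidates, genome, min_cov = 2L,
                          require_within_line_fixation = FALSE) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  n <- nrow(candidates)
  out <- tibble(
    chrom = candidates$chrom, pos = candidates$pos, ins = candidates$ins,
    consensus = candidates$consensus,
    alleles_G = vapply(candidates$alleles_G,
                       function(a) paste(sort(names(a)), collapse = ","),
                       character(1)),
    alleles_H = vapply(candidates$alleles_H,
                       function(a) paste(sort(names(a)), collapse = ","),
                       character(1)),
    cov_G = candidates$cov_G, cov_H = candidates$cov_H
  )
  pass1 <- pass2 <- pass3 <- biall <- logical(n)
  cls <- character(n)
  for (i in seq_len(n)) {
    aG <- names(candidates$alleles_G[[i]])
    aH <- names(candidates$alleles_H[[i]])
    uni <- unique(c(aG, aH))
    is_indel <- "-" %in% uni || candidates$ins[i] > 0L
    cls[i] <- classify_variant(uni)
    pass1[i] <- candidates$cov_G[i] >= min_cov && candidates$cov_H[i] >= min_cov
    pass2[i] <- if (is_indel) {
      !has_run3_near(genome[[candidates$chrom[i]]], candidates$pos[i])
    } else TRUE
    pass3[i] <- length(intersect(aG, aH)) == 0L &&
      (!require_within_line_fixation ||
         (length(aG) == 1L && length(aH) == 1L))
    biall[i] <- length(uni) == 2L
  }
  out$class <- cls
  out$pass_coverage <- pass1
  out$pass_homopolymer <- pass2
  out$pass_disjoint <- pass3
  out$biallelic <- biall
  out$pass <- pass1 & pass2 & pass3 & (cls == "indel" | biall)
  out
}

#' End-to-end inter-line SNP calling on mapped reads
#'
#' Convenience pipeline: [pileup_columns()] then [candidate_sites()] then
#' [apply_filters()].
#'
#' @inheritParams pileup_columns
#' @inheritParams apply_filters
#' @return the [apply_filters()] table.
#' @export
call_snps <- function(alignments, reads, genome, min_cov = 2L,
                      min_intron = 40L,
                      require_within_line_fixation = FALSE) {
  cols <- pileup_columns(alignments, reads, genome, min_intron = min_intron)
  cand <- candidate_sites(cols)
  apply_filters(cand, genome, min_cov = min_cov,
                require_within_line_fixation = require_within_line_fixation)
}
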