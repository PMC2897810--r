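#' Flanked gene regions
#'
#' Extends each gene by up to `flank` nt on both sides, anchored at the
#' translation start/stop when CDS bounds are annotated (else at the gene
#' bounds), truncated at chromosome ends and — when the full flanks of two
#' neighbouring genes would overlap — at the midpoint of the intergenic gap.
#' Overlapping gene bodies are truncated at the bodies with a warning.
#'
#' @param models a [gene_models] object.
#' @param flank maximum flank (nt), default 1000.
#' @param chrom_lengths named integer vector of chromosome lengths; regions
#'   are clipped to `[1, length]`. If `NULL`, only the lower bound is clipped.
#' @return tibble `gene_id`, `chrom`, `strand`, `start`, `end` (1-based
#'   inclusive), sorted by chromosome and start. Construction is idempotent
#'   and independent of the input row order.
#' @export
define_gene_regions <- function(models, flank = 1000L, chrom_lengths = NULL) {
  g <- models$genes %>% arrange(.data$chrom, .data$start)
  cds_l <- pmin(g$cds_start %||% g$start, g$cds_end %||% g$end)
  cds_r <- pmax(g$cds_start %||% g$start, g$cds_end %||% g$end)
  left <- pmin(g$start, cds_l - flank)
  right <- pmax(g$end, cds_r + flank)
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    if (length(idx) > 1) {
      for (j in seq_len(length(idx) - 1L)) {
        a <- idx[j]; b <- idx[j + 1L]
        if (g$end[a] >= g$start[b]) {
          warning("gene bodies overlap: ", g$gene_id[a], " / ", g$gene_id[b],
                  "; regions truncated at the bodies")
          right[a] <- g$end[a]
          left[b] <- g$start[b]
        } else if (right[a] >= left[b]) {
          gap <- g$start[b] - g$end[a] - 1L
          cut <- g$end[a] + gap %/% 2L
          right[a] <- min(right[a], cut)
          left[b] <- max(left[b], cut + 1L)
        }
      }
    }
  }
  left <- pmax(left, 1L)
  if (!is.null(chrom_lengths)) {
    right <- pmin(right, unname(chrom_lengths[g$chrom]))
  }
  tibble(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
         start = as.integer(left), end = as.integer(right))
}

#' Alignment parameters for the splice-aware EST aligner
#'
#' @param k exact-anchor k-mer size.
#' @param stride read k-mers are sampled every `stride` positions (the genome
#'   index is dense, so strided query seeding loses no hits).
#' @param min_intron,max_intron genomic gap range (nt) interpreted as an
#'   intron; smaller gaps are treated as indels.
#' @param shift_window junction boundaries may shift this many nt to prefer
#'   canonical GT..AG (or CT..AC on the reverse strand) dinucleotides.
#' @param min_identity,min_coverage acceptance rule: alignments below 95%
#'   identity or 80% query coverage are rejected.
#' @param merge_gap same-diagonal anchor runs separated by at most this many
#'   nt merge into one block (bridges isolated substitutions).
#' @param max_kmer_hits k-mers with more genomic hits than this are skipped
#'   as repeats.
#' @return list of class `align_params`.
#' @export
align_params <- function(k = 15L, stride = 3L, min_intron = 40L,
                         max_intron = 10000L, shift_window = 10L,
                         min_identity = 0.95, min_coverage = 0.80,
                         merge_gap = 30L, max_kmer_hits = 20L) {
  structure(list(k = as.integer(k), stride = as.integer(stride),
                 min_intron = as.integer(min_intron),
                 max_intron = as.integer(max_intron),
                 shift_window = as.integer(shift_window),
                 min_identity = min_identity, min_coverage = min_coverage,
                 merge_gap = as.integer(merge_gap),
                 max_kmer_hits = as.integer(max_kmer_hits)),
            class = "align_params")
}

# Dense k-mer index of a set of sequences: an environment mapping each k-mer
# to its (global, concatenated-coordinate) start positions.
build_kmer_index <- function(seqs, k) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  lens <- nchar(seqs)
  offsets <- c(0L, cumsum(lens))[seq_along(seqs)]
  all_km <- character(0); all_pos <- integer(0)
  for (i in seq_along(seqs)) {
    km <- kmers_of(seqs[[i]], k)
    all_km <- c(all_km, km)
    all_pos <- c(all_pos, offsets[i] + seq_along(km))
  }
  env <- list2env(split(all_pos, all_km), hash = TRUE,
                  size = length(all_pos))
  list(env = env, k = k,
       chroms = tibble(chrom = names(seqs), offset = offsets, len = lens),
       seqs = seqs)
}

seqi <- function(from, to) if (from > to) integer(0) else from:to

# Core chain aligner: exact k-mer anchors (qpos on the oriented read, gpos on
# the target), merged into same-diagonal segments, chained collinearly, with
# junction/indel refinement and terminal extension. Returns NULL or a list
# with blocks (qstart/qend/gstart/gend), introns, identity, coverage.
chain_core <- function(read, target, qpos, gpos, params) {
  k <- params$k
  if (length(qpos) == 0) return(NULL)
  diag <- gpos - qpos
  ord <- order(diag, qpos)
  qpos <- qpos[ord]; gpos <- gpos[ord]; diag <- diag[ord]
  brk <- c(TRUE, diff(diag) != 0L | diff(qpos) > params$merge_gap)
  first <- which(brk)
  last <- c(first[-1] - 1L, length(qpos))
  qs <- qpos[first]; qe <- qpos[last] + k - 1L; dg <- diag[first]
  o <- order(qs, qs + dg)
  segs <- quick_df(qs = qs[o], qe = qe[o], gs = (qs + dg)[o],
                   ge = (qe + dg)[o], diag = dg[o])
  n <- nrow(segs)
  # DP over segments: maximise aligned query length
  score <- segs$qe - segs$qs + 1L
  best <- as.numeric(score); prev <- rep(0L, n)
  if (n > 1) {
    for (b in 2:n) {
      for (a in 1:(b - 1)) {
        ddiff <- segs$diag[b] - segs$diag[a]
        qgap <- segs$qs[b] - segs$qe[a] - 1L
        if (segs$qs[b] <= segs$qs[a] || segs$gs[b] <= segs$gs[a]) next
        if (qgap < -(k - 1L)) next
        ok <- (abs(ddiff) <= 15L && qgap <= 50L) ||
          (ddiff >= params$min_intron && ddiff <= params$max_intron &&
             qgap <= 10L)
        if (!ok) next
        contrib <- segs$qe[b] - max(segs$qs[b], segs$qe[a] + 1L) + 1L
        if (contrib <= 0) next
        cand <- best[a] + contrib
        if (cand > best[b]) { best[b] <- cand; prev[b] <- a }
      }
    }
  }
  end <- which.max(best)
  chain <- end
  while (prev[chain[1]] != 0L) chain <- c(prev[chain[1]], chain)
  segs <- segs[chain, , drop = FALSE]
  # trim query overlaps between consecutive segments
  if (nrow(segs) > 1) {
    for (b in 2:nrow(segs)) {
      ov <- segs$qe[b - 1L] - segs$qs[b] + 1L
      if (ov > 0) {
        segs$qs[b] <- segs$qs[b] + ov
        segs$gs[b] <- segs$gs[b] + ov
      }
    }
  }
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  tlen <- nchar(target)
  # character access restricted to a window around the chained segments
  lo <- max(1L, min(segs$gs) - 80L)
  hi <- min(tlen, max(segs$ge) + 80L)
  toff <- lo - 1L
  tch <- strsplit(substr(target, lo, hi), "", fixed = TRUE)[[1]]

  blocks <- segs[, c("qs", "qe", "gs", "ge")]
  indel_cols <- 0L
  if (nrow(blocks) > 1) {
    i <- 1L
    while (i < nrow(blocks)) {
      a <- blocks[i, ]; b <- blocks[i + 1L, ]
      dA <- a$gs - a$qs; dB <- b$gs - b$qs
      ddiff <- dB - dA
      ins <- max(0L, -ddiff)
      g_at_A <- function(q) q + dA
      is_intron <- ddiff >= params$min_intron
      if (ddiff == 0L) {
        # same diagonal: merge into one block (mismatch stretch inside)
        blocks$qe[i] <- b$qe; blocks$ge[i] <- b$ge
        blocks <- blocks[-(i + 1L), , drop = FALSE]
        next
      }
      w <- params$shift_window
      jmin <- max(a$qs, a$qe - w)
      jmax <- min(b$qe - 1L, b$qs - 1L + w)
      js <- seqi(jmin, jmax)
      stats_j <- vapply(js, function(j) {
        qa <- seqi(a$qe + 1L, j)
        qb <- seqi(j + ins + 1L, b$qs - 1L)
        ga <- qa + dA; gb <- qb + dB
        okA <- if (length(qa)) ga <= hi & ga >= lo else logical(0)
        okB <- if (length(qb)) gb <= hi & gb >= lo else logical(0)
        mis <- sum(!okA) + sum(!okB) +
          sum(rch[qa[okA]] != tch[ga[okA] - toff]) +
          sum(rch[qb[okB]] != tch[gb[okB] - toff])
        canon <- 0L
        if (is_intron) {
          is_ <- j + dA + 1L; ie_ <- j + ins + dB  # intron bounds on target
          if (is_ >= lo && is_ + 1L <= hi && ie_ - 1L >= lo && ie_ <= hi) {
            d2 <- paste0(tch[is_ - toff], tch[is_ + 1L - toff])
            a2 <- paste0(tch[ie_ - 1L - toff], tch[ie_ - toff])
            canon <- as.integer((d2 == "GT" && a2 == "AG") ||
                                  (d2 == "CT" && a2 == "AC"))
          }
        }
        c(mis, canon)
      }, numeric(2))
      if (length(js) == 0) { i <- i + 1L; next }
      if (is_intron) {
        o <- order(stats_j[1, ], -stats_j[2, ], abs(js - a$qe), js)
      } else {
        o <- order(stats_j[1, ], js)
      }
      j <- js[o[1]]
      blocks$qe[i] <- j
      blocks$ge[i] <- j + dA
      blocks$qs[i + 1L] <- j + ins + 1L
      blocks$gs[i + 1L] <- j + ins + 1L + dB
      if (!is_intron) indel_cols <- indel_cols + abs(ddiff)
      i <- i + 1L
    }
  }
  # drop degenerate blocks
  keep <- blocks$qe >= blocks$qs
  blocks <- blocks[keep, , drop = FALSE]
  if (nrow(blocks) == 0) return(NULL)
  # terminal extension with exact matches
  while (blocks$qs[1] > 1L && blocks$gs[1] > lo &&
         rch[blocks$qs[1] - 1L] == tch[blocks$gs[1] - 1L - toff]) {
    blocks$qs[1] <- blocks$qs[1] - 1L
    blocks$gs[1] <- blocks$gs[1] - 1L
  }
  nb <- nrow(blocks)
  while (blocks$qe[nb] < length(rch) && blocks$ge[nb] < hi &&
         rch[blocks$qe[nb] + 1L] == tch[blocks$ge[nb] + 1L - toff]) {
    blocks$qe[nb] <- blocks$qe[nb] + 1L
    blocks$ge[nb] <- blocks$ge[nb] + 1L
  }
  matched <- 0L; cols <- indel_cols
  for (i in seq_len(nrow(blocks))) {
    qi <- blocks$qs[i]:blocks$qe[i]
    gi <- blocks$gs[i]:blocks$ge[i]
    matched <- matched + sum(rch[qi] == tch[gi - toff])
    cols <- cols + length(qi)
  }
  aligned_len <- sum(blocks$qe - blocks$qs + 1L)
  # introns recomputed from the final blocks so both stay consistent
  introns_df <- quick_df(start = integer(0), end = integer(0))
  if (nrow(blocks) > 1) {
    gap_s <- head(blocks$ge, -1) + 1L
    gap_e <- tail(blocks$gs, -1) - 1L
    big <- (gap_e - gap_s + 1L) >= params$min_intron
    introns_df <- quick_df(start = gap_s[big], end = gap_e[big])
  }
  list(blocks = blocks, introns = introns_df,
       identity = matched / cols, coverage = aligned_len / length(rch),
       aligned_len = aligned_len, matched = matched)
}

anchors_for <- function(read, env, k, stride, max_hits) {
  L <- nchar(read)
  if (L < k) return(list(q = integer(0), g = integer(0)))
  starts <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
  km <- substring(read, starts, starts + k - 1L)
  hits <- mget(km, envir = env, ifnotfound = list(NULL))
  nh <- lengths(hits)
  use <- nh > 0L & nh <= max_hits
  list(q = rep(starts[use], nh[use]), g = unlist(hits[use], use.names = FALSE))
}

#' Align one EST read to a gene-region sequence
#'
#' Splice-aware alignment by exact k-mer anchor chaining: same-diagonal
#' anchors merge into blocks, collinear blocks are chained, genomic gaps of
#' at least `min_intron` nt become introns with boundaries shifted within
#' `shift_window` nt to prefer canonical splice dinucleotides, and smaller
#' gaps become indels. Both read orientations are tried. The alignment is
#' rejected unless identity >= `min_identity` and query coverage >=
#' `min_coverage`.
#'
#' @param read character scalar (the EST sequence); its name, if any, is used
#'   as the read id.
#' @param region_seq character scalar: the gene-region sequence (forward
#'   genomic orientation).
#' @param params [align_params()].
#' @return a one-row tibble (`read_id`, `strand`, `identity`, `coverage`,
#'   `aligned_len`, `n_blocks`, list-columns `blocks` and `introns`, all
#'   coordinates relative to `region_seq`), or `NULL` if rejected.
#' @export
align_est <- function(read, region_seq, params = align_params()) {
  stopifnot(length(read) == 1, nchar(read) >= params$k)
  idx <- build_kmer_index(c(region = unname(region_seq)), params$k)
  res <- align_to_index(read, idx, params)
  if (is.null(res)) return(NULL)
  tibble(read_id = names(read) %||% NA_character_,
         strand = res$strand, identity = res$identity,
         coverage = res$coverage, aligned_len = res$aligned_len,
         n_blocks = nrow(res$blocks),
         blocks = list(quick_df(qstart = res$blocks$qs, qend = res$blocks$qe,
                                gstart = res$blocks$gs,
                                gend = res$blocks$ge)),
         introns = list(as_tibble(res$introns)))
}

# Align a read against an indexed target (single concatenated space); tries
# both orientations, returns best accepted chain or NULL.
align_to_index <- function(read, idx, params, target_window = NULL) {
  cand <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") read else revcomp(read)
    an <- anchors_for(oriented, idx$env, idx$k, params$stride,
                      params$max_kmer_hits)
    if (!is.null(target_window)) {
      keep <- an$g >= target_window[1] & an$g <= target_window[2]
      an$q <- an$q[keep]; an$g <- an$g[keep]
    }
    if (length(an$q) == 0) next
    target <- idx$seqs[[1]]
    res <- chain_core(oriented, target, an$q, an$g, params)
    if (is.null(res)) next
    res$strand <- strand
    cand[[strand]] <- res
  }
  if (length(cand) == 0) return(NULL)
  scores <- vapply(cand, function(r) r$identity * r$coverage, numeric(1))
  res <- cand[[order(-scores, names(cand))[1]]]
  if (res$identity < params$min_identity ||
      res$coverage < params$min_coverage) return(NULL)
  res
}

#' Map an EST library to gene regions genome-wide
#'
#' Builds a dense k-mer index of the genome once, seeds each read to its
#' candidate gene regions, runs the chain aligner in both orientations, and
#' keeps per read the best accepted alignment (see [assign_to_gene()] for the
#' tie-breaks). Reads whose id carries a `LIB|` prefix get that library tag.
#'
#' @param reads named character vector of read sequences.
#' @param genome named character vector or `DNAStringSet`.
#' @param models [gene_models].
#' @param regions optional precomputed [define_gene_regions()] output.
#' @param params [align_params()].
#' @param index optional prebuilt genome k-mer index (from an earlier
#'   `map_reads()` call, attribute `index` of the result) to avoid re-indexing
#'   when mapping several libraries against one genome.
#' @return list with `alignments` (tibble, one row per mapped read:
#'   `read_id`, `library`, `gene_id`, `chrom`, `strand`, `identity`,
#'   `coverage`, `aligned_len`, `n_blocks`, list-columns `blocks`, `introns`
#'   — genomic coordinates) and `unmapped` (character vector of read ids).
#' @export
map_reads <- function(reads, genome, models, regions = NULL,
                      params = align_params(), index = NULL) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (is.null(regions)) {
    regions <- define_gene_regions(models,
                                   chrom_lengths = nchar(genome))
  }
  idx <- index %||% build_kmer_index(genome, params$k)
  offs <- stats::setNames(idx$chroms$offset, idx$chroms$chrom)
  regions <- regions %>% arrange(.data$chrom, .data$start)
  rg_start <- unname(offs[regions$chrom]) + regions$start
  rg_end <- unname(offs[regions$chrom]) + regions$end
  ord <- order(rg_start)
  rg_start <- rg_start[ord]; rg_end <- rg_end[ord]
  rg_gene <- regions$gene_id[ord]; rg_chrom <- regions$chrom[ord]
  rg_gstart <- regions$start[ord]
  nr <- length(reads)
  o_gene <- o_chrom <- o_strand <- character(nr)
  o_id <- o_cov <- o_al <- o_nb <- numeric(nr)
  o_blocks <- vector("list", nr); o_introns <- vector("list", nr)
  hit <- logical(nr)
  unmapped <- character(0)
  for (ri in seq_along(reads)) {
    read <- reads[[ri]]
    rid <- names(reads)[ri]
    best <- NULL
    if (nchar(read) >= params$k) {
      for (strand in c("+", "-")) {
        oriented <- if (strand == "+") read else revcomp(read)
        an <- anchors_for(oriented, idx$env, idx$k, params$stride,
                          params$max_kmer_hits)
        if (length(an$q) == 0) next
        hit_r <- findInterval(an$g, rg_start)
        inside <- hit_r >= 1L & an$g <= rg_end[pmax(hit_r, 1L)]
        if (!any(inside)) next
        hr <- hit_r[inside]
        u <- unique(hr)
        cnt <- vapply(u, function(z) sum(hr == z), integer(1))
        top <- u[order(-cnt)][seq_len(min(2L, length(u)))]
        for (r in top) {
          sel <- inside & hit_r == r
          qv <- an$q[sel]
          gv <- an$g[sel] - rg_start[r] + 1L  # region-local coordinates
          target <- substr(genome[[rg_chrom[r]]], rg_gstart[r],
                           rg_gstart[r] + (rg_end[r] - rg_start[r]))
          res <- chain_core(oriented, target, qv, gv, params)
          if (is.null(res)) next
          if (res$identity < params$min_identity ||
              res$coverage < params$min_coverage) next
          res$strand <- strand
          res$gene_id <- rg_gene[r]
          res$chrom <- rg_chrom[r]
          shift <- rg_gstart[r] - 1L
          res$blocks$gstart <- res$blocks$gs + shift
          res$blocks$gend <- res$blocks$ge + shift
          res$introns$start <- res$introns$start + shift
          res$introns$end <- res$introns$end + shift
          score <- res$identity * res$coverage
          if (is.null(best) || score > best$score ||
              (score == best$score &&
                 (res$aligned_len > best$res$aligned_len ||
                    (res$aligned_len == best$res$aligned_len &&
                       res$gene_id < best$res$gene_id)))) {
            best <- list(score = score, res = res)
          }
        }
      }
    }
    if (is.null(best)) {
      unmapped <- c(unmapped, rid)
    } else {
      res <- best$res
      hit[ri] <- TRUE
      o_gene[ri] <- res$gene_id; o_chrom[ri] <- res$chrom
      o_strand[ri] <- res$strand
      o_id[ri] <- res$identity; o_cov[ri] <- res$coverage
      o_al[ri] <- res$aligned_len; o_nb[ri] <- nrow(res$blocks)
      o_blocks[[ri]] <- quick_df(qstart = res$blocks$qs,
                                 qend = res$blocks$qe,
                                 gstart = res$blocks$gstart,
                                 gend = res$blocks$gend)
      o_introns[[ri]] <- quick_df(start = res$introns$start,
                                  end = res$introns$end)
    }
  }
  ids <- names(reads) %||% as.character(seq_along(reads))
  alignments <- tibble(
    read_id = ids[hit],
    library = sub("\\|.*$", "", ids[hit]),
    gene_id = o_gene[hit], chrom = o_chrom[hit], strand = o_strand[hit],
    identity = o_id[hit], coverage = o_cov[hit],
    aligned_len = as.integer(o_al[hit]), n_blocks = as.integer(o_nb[hit]),
    blocks = o_blocks[hit], introns = o_introns[hit]
  )
  out <- list(alignments = alignments, unmapped = unmapped)
  attr(out, "index") <- idx
  out
}

#' Pick the best gene per read from candidate alignments
#'
#' Highest identity x coverage wins; ties broken by longer aligned length,
#' then lexicographically smaller gene id (deterministic).
#'
#' @param candidates tibble of accepted alignments with at least `read_id`,
#'   `gene_id`, `identity`, `coverage`, `aligned_len`.
#' @return the input filtered to one row per read.
#' @export
assign_to_gene <- function(candidates) {
  candidates %>%
    mutate(.score = .data$identity * .data$coverage) %>%
    group_by(.data$read_id) %>%
    arrange(dplyr::desc(.data$.score), dplyr::desc(.data$aligned_len),
            .data$gene_id, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select(-".score")
}
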