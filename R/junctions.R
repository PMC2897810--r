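#' Extract intron-exon junctions from spliced alignments
#'
#' One junction per distinct (gene, intron interval); support counts distinct
#' ESTs. A junction is kept only if the alignment has at least `min_overhang`
#' contiguously aligned nt on both sides of the intron (small indel gaps
#' within an exonic stretch do not break contiguity). Donor and acceptor
#' coordinates follow the gene's transcription strand.
#'
#' @param alignments tibble from [map_reads()] / [read_alignments()].
#' @param models [gene_models] (for strand and the annotated flag).
#' @param min_overhang minimum aligned nt flanking the intron (default 8).
#' @param min_support minimum number of distinct supporting ESTs (default 1;
#'   raising it to 2 suppresses junctions created by isolated sequencing
#'   errors on error-containing libraries).
#' @return tibble `gene_id`, `chrom`, `strand`, `start`, `end`, `donor`,
#'   `acceptor`, `support`, `annotated`, plus list-column `read_ids`.
#' @export
extract_junctions <- function(alignments, models, min_overhang = 8L,
                              min_support = 1L) {
  ann <- gene_introns(models)
  rows <- list()
  for (i in seq_len(nrow(alignments))) {
    intr <- alignments$introns[[i]]
    if (nrow(intr) == 0) next
    bl <- alignments$blocks[[i]]
    # exonic chunks: blocks between introns (indel gaps do not split chunks)
    chunk_of <- cumsum(c(0L, (head(bl$gend, -1) + 1L) %in% intr$start)) + 1L
    chunk_w <- tapply(bl$gend - bl$gstart + 1L,
                      factor(chunk_of, levels = unique(chunk_of)), sum)
    for (j in seq_len(nrow(intr))) {
      if (chunk_w[j] < min_overhang || chunk_w[j + 1L] < min_overhang) next
      rows[[length(rows) + 1L]] <- tibble(
        gene_id = alignments$gene_id[i], chrom = alignments$chrom[i],
        start = intr$start[j], end = intr$end[j],
        read_id = alignments$read_id[i]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(gene_id = character(0), chrom = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  donor = integer(0), acceptor = integer(0),
                  support = integer(0), annotated = logical(0),
                  read_ids = list()))
  }
  strand_of <- stats::setNames(models$genes$strand, models$genes$gene_id)
  jc <- bind_rows(rows) %>%
    group_by(.data$gene_id, .data$chrom, .data$start, .data$end) %>%
    summarise(support = n_distinct(.data$read_id),
              read_ids = list(unique(.data$read_id)), .groups = "drop") %>%
    mutate(strand = unname(strand_of[.data$gene_id]),
           donor = ifelse(.data$strand == "+", .data$start, .data$end),
           acceptor = ifelse(.data$strand == "+", .data$end, .data$start)) %>%
    left_join(ann %>% mutate(annotated = TRUE) %>%
                select("gene_id", "start", "end", "annotated"),
              by = c("gene_id", "start", "end")) %>%
    mutate(annotated = !is.na(.data$annotated)) %>%
    select("gene_id", "chrom", "strand", "start", "end", "donor", "acceptor",
           "support", "annotated", "read_ids") %>%
    filter(.data$support >= min_support) %>%
    arrange(.data$gene_id, .data$start, .data$end)
  jc
}

#' Fraction of observed junctions consistent with the annotation
#'
#' Exact intron-interval matches over all observed junctions.
#'
#' @param junctions output of [extract_junctions()].
#' @param models [gene_models], or `NULL` to use the `annotated` flag already
#'   present on the junctions.
#' @return a single fraction in `[0, 1]` (`NaN` for an empty junction set).
#' @export
junction_concordance <- function(junctions, models = NULL) {
  if (!is.null(models)) {
    ann <- gene_introns(models)
    key <- paste(junctions$gene_id, junctions$start, junctions$end)
    akey <- paste(ann$gene_id, ann$start, ann$end)
    return(mean(key %in% akey))
  }
  mean(junctions$annotated)
}

# union of annotated introns and observed junctions for one classification run
intron_union <- function(junctions, models) {
  ann <- gene_introns(models) %>%
    mutate(annotated = TRUE, support = 0L, read_ids = list(character(0)))
  obs <- junctions %>%
    select("gene_id", "chrom", "strand", "start", "end", "support",
           "read_ids") %>%
    mutate(annotated = FALSE)
  bind_rows(
    obs,
    ann %>% dplyr::anti_join(obs, by = c("gene_id", "start", "end"))
  ) %>%
    # observed junctions that match annotation keep their support but are
    # flagged annotated
    left_join(gene_introns(models) %>% mutate(.ann = TRUE) %>%
                select("gene_id", "start", "end", ".ann"),
              by = c("gene_id", "start", "end")) %>%
    mutate(annotated = !is.na(.data$.ann)) %>%
    select(-".ann") %>%
    # strand is a property of the gene, not of the junction evidence
    mutate(strand = stats::setNames(models$genes$strand,
                                    models$genes$gene_id)[.data$gene_id]) %>%
    arrange(.data$gene_id, .data$start, .data$end)
}

#' Classify alternative-splicing events
#'
#' Works on the union of annotated introns and EST-derived junctions of each
#' gene. For every unordered intron pair and retained-intron configuration at
#' most one event type is assigned, with this precedence:
#'
#' * **ExonS** — introns `j1`, `j2` (disjoint, `j1` before `j2`) and a third
#'   intron `i` with `i.start == j1.start` and `i.end == j2.end`; the skipped
#'   exon is the interval between `j1` and `j2`. The pairs `(i, j1)` and
#'   `(i, j2)` are consumed by the triple and not reported again.
#' * **AltD / AltA** — overlapping introns sharing the acceptor but not the
#'   donor (AltD), or the donor but not the acceptor (AltA); donor/acceptor
#'   follow the gene strand.
#' * **AltP** — overlapping introns sharing neither boundary and not part of
#'   an ExonS triple.
#' * **IntronR** (independent of the pair logic) — an intron exists and some
#'   EST's contiguous aligned stretch covers it plus `retention_overhang` nt
#'   beyond both boundaries.
#'
#' Duplicate events collapse to one record.
#'
#' @param junctions output of [extract_junctions()].
#' @param alignments the alignments the junctions came from (needed for
#'   intron-retention evidence).
#' @param models [gene_models].
#' @param retention_overhang contiguous aligned nt required beyond both intron
#'   boundaries to call retention (default 8; distinguishes retention from
#'   alignment truncation).
#' @return tibble `gene_id`, `type`, `chrom`, `strand`, intron coordinates
#'   (`intron1_*` = first/retained/long intron, `intron2_*`, `intron3_*` for
#'   the ExonS flanking pair), `skipped_start`/`skipped_end`, `n_support` and
#'   list-column `read_ids`.
#' @export
classify_events <- function(junctions, alignments, models,
                            retention_overhang = 8L) {
  unknown <- setdiff(junctions$gene_id, models$genes$gene_id)
  if (length(unknown) > 0) {
    stop("junction(s) on unknown gene(s): ", paste(unknown, collapse = ", "))
  }
  uni <- intron_union(junctions, models)
  ev <- list()
  add <- function(type, gene, chrom, strand, i1, i2 = c(NA, NA),
                  i3 = c(NA, NA), skip = c(NA, NA), reads = character(0)) {
    ev[[length(ev) + 1L]] <<- tibble(
      gene_id = gene, type = type, chrom = chrom, strand = strand,
      intron1_start = as.integer(i1[1]), intron1_end = as.integer(i1[2]),
      intron2_start = as.integer(i2[1]), intron2_end = as.integer(i2[2]),
      intron3_start = as.integer(i3[1]), intron3_end = as.integer(i3[2]),
      skipped_start = as.integer(skip[1]), skipped_end = as.integer(skip[2]),
      n_support = length(unique(reads)), read_ids = list(unique(reads))
    )
  }
  # contiguous aligned chunks per gene for retention evidence
  chunks <- alignment_chunks(alignments)
  for (gid in unique(uni$gene_id)) {
    gi <- uni %>% filter(.data$gene_id == gid)
    strand <- gi$strand[1]; chrom <- gi$chrom[1]
    n <- nrow(gi)
    consumed <- matrix(FALSE, n, n)
    # ExonS triples
    if (n >= 3) {
      for (ii in seq_len(n)) {
        j1s <- which(gi$start == gi$start[ii] & gi$end < gi$end[ii])
        for (j1 in j1s) {
          j2s <- which(gi$end == gi$end[ii] & gi$start > gi$end[j1])
          for (j2 in j2s) {
            add("ExonS", gid, chrom, strand,
                c(gi$start[ii], gi$end[ii]),
                c(gi$start[j1], gi$end[j1]),
                c(gi$start[j2], gi$end[j2]),
                c(gi$end[j1] + 1L, gi$start[j2] - 1L),
                unlist(gi$read_ids[c(ii, j1, j2)]))
            consumed[ii, j1] <- consumed[j1, ii] <- TRUE
            consumed[ii, j2] <- consumed[j2, ii] <- TRUE
          }
        }
      }
    }
    # pairwise AltD / AltA / AltP among overlapping introns
    if (n >= 2) {
      for (a in seq_len(n - 1L)) {
        for (b in (a + 1L):n) {
          if (consumed[a, b]) next
          if (gi$start[b] > gi$end[a] || gi$start[a] > gi$end[b]) next
          same_start <- gi$start[a] == gi$start[b]
          same_end <- gi$end[a] == gi$end[b]
          if (same_start && same_end) next
          reads <- unlist(gi$read_ids[c(a, b)])
          i1 <- c(gi$start[a], gi$end[a]); i2 <- c(gi$start[b], gi$end[b])
          if (same_start) {
            # shared 5' coordinate: donor on '+', acceptor on '-'
            type <- if (strand == "+") "AltA" else "AltD"
          } else if (same_end) {
            type <- if (strand == "+") "AltD" else "AltA"
          } else {
            type <- "AltP"
          }
          add(type, gid, chrom, strand, i1, i2, reads = reads)
        }
      }
    }
    # intron retention
    ch <- chunks[chunks$gene_id == gid, , drop = FALSE]
    if (nrow(ch) > 0) {
      for (ii in seq_len(n)) {
        cover <- ch$start <= gi$start[ii] - retention_overhang &
          ch$end >= gi$end[ii] + retention_overhang
        if (any(cover)) {
          add("IntronR", gid, chrom, strand, c(gi$start[ii], gi$end[ii]),
              reads = ch$read_id[cover])
        }
      }
    }
  }
  if (length(ev) == 0) {
    return(tibble(gene_id = character(0), type = character(0),
                  chrom = character(0), strand = character(0),
                  intron1_start = integer(0), intron1_end = integer(0),
                  intron2_start = integer(0), intron2_end = integer(0),
                  intron3_start = integer(0), intron3_end = integer(0),
                  skipped_start = integer(0), skipped_end = integer(0),
                  n_support = integer(0), read_ids = list()))
  }
  bind_rows(ev) %>%
    distinct(.data$gene_id, .data$type, .data$intron1_start,
             .data$intron1_end, .data$intron2_start, .data$intron2_end,
             .data$intron3_start, .data$intron3_end, .keep_all = TRUE) %>%
    arrange(.data$gene_id, .data$type, .data$intron1_start)
}

# contiguous aligned genomic stretches (indel gaps bridged, introns split)
alignment_chunks <- function(alignments) {
  rows <- list()
  for (i in seq_len(nrow(alignments))) {
    bl <- alignments$blocks[[i]]
    intr <- alignments$introns[[i]]
    chunk_of <- cumsum(c(0L, (head(bl$gend, -1) + 1L) %in% intr$start)) + 1L
    f <- factor(chunk_of, levels = unique(chunk_of))
    rows[[i]] <- tibble(
      gene_id = alignments$gene_id[i],
      read_id = alignments$read_id[i],
      start = as.integer(tapply(bl$gstart, f, min)),
      end = as.integer(tapply(bl$gend, f, max))
    )
  }
  if (length(rows) == 0) {
    return(tibble(gene_id = character(0), read_id = character(0),
                  start = integer(0), end = integer(0)))
  }
  bind_rows(rows)
}

#' Tabulate alternative-splicing events by type
#'
#' @param events output of [classify_events()].
#' @return tibble with one row per type (all five always present, in the
#'   order AltD, AltA, AltP, IntronR, ExonS): event counts, distinct gene
#'   counts, and their percentages of the totals.
#' @export
summarize_as <- function(events) {
  types <- c("AltD", "AltA", "AltP", "IntronR", "ExonS")
  out <- tibble(type = types) %>%
    left_join(
      events %>% group_by(.data$type) %>%
        summarise(n_events = n(), n_genes = n_distinct(.data$gene_id),
                  .groups = "drop"),
      by = "type"
    ) %>%
    mutate(n_events = ifelse(is.na(.data$n_events), 0L, .data$n_events),
           n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes))
  tot_e <- sum(out$n_events)
  tot_g <- length(unique(events$gene_id))
  out %>% mutate(
    pct_events = if (tot_e > 0) 100 * .data$n_events / tot_e else 0,
    pct_genes = if (tot_g > 0) 100 * .data$n_genes / tot_g else 0
  )
}
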