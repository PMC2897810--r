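#' Canonical motif class of a microsatellite motif
#'
#' The lexicographically smallest string among all cyclic rotations of the
#' motif and of its reverse complement — the standard motif-class notation
#' (e.g. `CTT` and `TCT` both report as `AAG`, the "AAG/CTT" class).
#' Idempotent and invariant under reverse-complementing the source sequence.
#'
#' @param motif character vector of motifs over `A`/`C`/`G`/`T`.
#' @return character vector of canonical classes.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    u <- nchar(m)
    rots <- function(s) {
      vapply(seq_len(u), function(i) {
        paste0(substr(s, i, u), substr(s, 1, i - 1L))
      }, character(1))
    }
    min(c(rots(m), rots(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

# TRUE if the motif is not a repetition of a shorter motif
primitive_motif <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && strrep(substr(motif, 1, d), u %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Find perfect microsatellites (SSRs)
#'
#' MISA-style scan for maximal perfect tandem repeats of primitive 2-6 nt
#' motifs. Default minimum repeat numbers are 6 for dinucleotides and 5 for
#' tri- to hexanucleotides; mononucleotide repeats are never reported (they
#' are indistinguishable from the homopolymer errors of pyrosequencing
#' reads). `N` breaks a repeat. Where a stretch satisfies two motif lengths,
#' the shorter primitive motif wins (an `(AT)10` run is a dinucleotide SSR,
#' never a tetranucleotide `ATAT` one).
#'
#' @param seqs named character vector (or `DNAStringSet`) of sequences —
#'   typically the unigene/transcript set.
#' @param thresholds named integer vector: minimum repeat number per motif
#'   length `"2"`..`"6"`.
#' @return tibble `seq_id`, `motif` (as found), `canonical`, `unit_len`,
#'   `n_repeats`, `start`, `end` (1-based inclusive,
#'   `end - start + 1 == unit_len * n_repeats`), sorted by sequence and
#'   position.
#' @export
find_ssrs <- function(seqs, thresholds = c(`2` = 6L, `3` = 5L, `4` = 5L,
                                           `5` = 5L, `6` = 5L)) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  rows <- list()
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    for (u in 2:6) {
      thr <- thresholds[[as.character(u)]]
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thr - 1L)
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      lens <- attr(m, "match.length")
      for (i in seq_along(m)) {
        start <- m[i]
        reps <- lens[i] %/% u
        len <- reps * u  # greedy match length is a multiple of u by pattern
        motif <- substr(s, start, start + u - 1L)
        if (!primitive_motif(motif)) next
        rows[[length(rows) + 1L]] <- tibble(
          seq_id = sid, motif = motif, canonical = canonical_motif(motif),
          unit_len = u, n_repeats = as.integer(reps),
          start = as.integer(start), end = as.integer(start + len - 1L)
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(seq_id = character(0), motif = character(0),
                  canonical = character(0), unit_len = integer(0),
                  n_repeats = integer(0), start = integer(0),
                  end = integer(0)))
  }
  bind_rows(rows) %>% arrange(.data$seq_id, .data$start, .data$unit_len)
}

#' Group SSRs into compound microsatellites
#'
#' SSRs on the same sequence whose interruption (the gap between the end of
#' one repeat and the start of the next) is at most `max_gap` nt share a
#' compound id, with transitive chaining; adjacent repeats (gap 0) compound.
#'
#' @param ssrs output of [find_ssrs()].
#' @param max_gap maximal interrupting distance (nt), default 100.
#' @return the input with an added `compound_id` column (`NA` for solitary
#'   SSRs) and `compound_size`.
#' @export
merge_compound <- function(ssrs, max_gap = 100L) {
  if (nrow(ssrs) == 0) {
    ssrs$compound_id <- character(0)
    ssrs$compound_size <- integer(0)
    return(ssrs)
  }
  ssrs <- ssrs %>% arrange(.data$seq_id, .data$start)
  out <- ssrs %>%
    group_by(.data$seq_id) %>%
    mutate(
      .gap = .data$start - dplyr::lag(cummax(.data$end), default = -1e9) - 1L,
      .grp = cumsum(.data$.gap > max_gap)
    ) %>%
    ungroup() %>%
    group_by(.data$seq_id, .data$.grp) %>%
    mutate(compound_size = n(),
           compound_id = ifelse(n() > 1,
                                paste0(.data$seq_id, ".c", .data$.grp), NA)) %>%
    ungroup() %>%
    select(-".gap", -".grp")
  out
}

#' Flanking-sequence sufficiency for primer design
#'
#' TRUE iff the SSR has at least `min_flank` non-`N` nucleotides on both
#' sides within its source sequence.
#'
#' @param ssrs output of [find_ssrs()] (or [merge_compound()]).
#' @param seqs the sequences the SSRs were found in.
#' @param min_flank required flank length (nt), default 50.
#' @return the input with an added logical `flanking_ok` column.
#' @export
flanking_ok <- function(ssrs, seqs, min_flank = 50L) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  ok <- vapply(seq_len(nrow(ssrs)), function(i) {
    s <- seqs[[ssrs$seq_id[i]]]
    ls <- ssrs$start[i] - min_flank
    re <- ssrs$end[i] + min_flank
    if (ls < 1L || re > nchar(s)) return(FALSE)
    left <- substr(s, ls, ssrs$start[i] - 1L)
    right <- substr(s, ssrs$end[i] + 1L, re)
    !grepl("N", left, fixed = TRUE) && !grepl("N", right, fixed = TRUE)
  }, logical(1))
  ssrs$flanking_ok <- ok
  ssrs
}
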