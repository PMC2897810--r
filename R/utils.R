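#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n n_distinct pull rename select summarise ungroup
#' @importFrom rlang .data
#' @importFrom stats optimize p.adjust pchisq phyper rgamma rnorm rpois runif
#' @importFrom utils head read.delim tail write.table
NULL

# Reverse complement of plain character DNA (keeps N).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# All k-mers of a string starting at positions 1..(n-k+1).
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# Homopolymer runs of a sequence: tibble(base, start, end, length), 1-based.
homopolymer_runs <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(ch)
  end <- cumsum(r$lengths)
  tibble(
    base = r$values,
    start = end - r$lengths + 1L,
    end = end,
    length = r$lengths
  )
}

# Random DNA string of length n using the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast data.frame constructor for hot paths (no checks, no name repair)
quick_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = .set_row_names(length(x[[1]])))
}
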