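# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Likelihood-ratio oracle for the tag-count R statistic: numerically maximise
# the separate-rate and pooled-rate Poisson log-likelihoods.
oracle_r_loglik <- function(x, N) {
  ll <- function(lambda, xj, Nj) sum(stats::dpois(xj, lambda * Nj, log = TRUE))
  sep <- sum(vapply(seq_along(x), function(j) {
    # x_j = 0: the supremum is the lambda -> 0 limit, exactly 0
    if (x[j] == 0) return(0)
    stats::optimize(ll, c(1e-12, 10 * (x[j] / N[j]) + 1), xj = x[j],
                    Nj = N[j], maximum = TRUE, tol = 1e-12)$objective
  }, numeric(1)))
  f <- sum(x) / sum(N)
  pooled <- stats::optimize(function(l) sum(stats::dpois(x, l * N, log = TRUE)),
                            c(max(1e-12, f / 10), 10 * f + 1),
                            maximum = TRUE, tol = 1e-12)$objective
  sep - pooled
}

# Brute-force maximal perfect tandem repeat enumerator (vector-scan, an
# algorithm independent of the package's regex scanner).
oracle_ssrs <- function(seq, thresholds = c(`2` = 6L, `3` = 5L, `4` = 5L,
                                            `5` = 5L, `6` = 5L)) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  is_primitive <- function(m) {
    u <- nchar(m)
    for (d in seq_len(u - 1L)) {
      if (u %% d == 0L && strrep(substr(m, 1, d), u %/% d) == m) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  for (u in 2:6) {
    thr <- thresholds[[as.character(u)]]
    if (n < u * thr) next
    eq <- x[seq_len(n - u)] == x[seq_len(n - u) + u]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      a <- starts[j]
      L <- r$lengths[j] + u      # length of the periodic region from a
      k <- L %/% u
      if (k < thr) next
      motif <- paste(x[a:(a + u - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      if (!is_primitive(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motif, unit_len = u, n_repeats = k,
        start = a, end = a + k * u - 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(motif = character(0), unit_len = integer(0),
                      n_repeats = integer(0), start = integer(0),
                      end = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_len), , drop = FALSE]
}

# Exact hypergeometric upper tail by direct enumeration of the tail terms.
oracle_hyper_tail <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# All minimal slim ancestors of a term by exhaustive path enumeration on a
# small DAG given as a child->parents edge list.
oracle_min_slim <- function(term, edges, slim) {
  if (term %in% slim) return(term)
  paths <- list(term)
  found <- character(0)
  while (length(paths) > 0) {
    p <- paths[[1]]; paths <- paths[-1]
    tip <- p[length(p)]
    for (par in edges[[tip]] %||% character(0)) {
      if (par %in% p) next
      if (par %in% slim) {
        if (!any(p[-1] %in% slim)) found <- c(found, par)
      } else {
        paths[[length(paths) + 1L]] <- c(p, par)
      }
    }
  }
  sort(unique(found))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random DNA of length n (uses the caller's RNG stream)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# random 2 kb test sequences for the SSR oracle comparison: random background
# with planted tandem repeats of random motifs and repeat counts straddling
# the thresholds
rand_ssr_seq <- function(len = 2000L) {
  s <- rand_dna(len)
  n_plant <- sample(0:4, 1)
  for (i in seq_len(n_plant)) {
    u <- sample(2:6, 1)
    k <- sample(3:9, 1)
    motif <- rand_dna(u)
    run <- strrep(motif, k)
    pos <- sample(len - nchar(run) - 1L, 1)
    substr(s, pos, pos + nchar(run) - 1L) <- run
  }
  s
}

rc <- function(x) chartr("ACGTN", "TGCAN", vapply(x, function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}, character(1), USE.NAMES = FALSE))
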