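#' Count tags per gene and library
#'
#' Tabulates assigned reads into a per-gene count table. Library sizes are
#' the totals of assigned reads per library (unassigned reads are excluded
#' from both the counts and the library sizes).
#'
#' @param assignments tibble with `read_id`, `library`, `gene_id` — one row
#'   per assigned read (e.g. `map_reads()$alignments`, already one best gene
#'   per read).
#' @param libraries library tags, default `c("G", "H")`; tags found in the
#'   data but not listed are an error.
#' @return tibble of class `tag_counts`: `gene_id` plus one integer column
#'   per library, with attribute `lib_sizes`.
#' @export
count_tags <- function(assignments, libraries = c("G", "H")) {
  extra <- setdiff(unique(assignments$library), libraries)
  if (length(extra) > 0) {
    stop("unexpected library tag(s): ", paste(extra, collapse = ", "))
  }
  wide <- assignments %>%
    group_by(.data$gene_id, .data$library) %>%
    summarise(n = n(), .groups = "drop")
  out <- tibble(gene_id = sort(unique(wide$gene_id)))
  for (lib in libraries) {
    cnt <- wide %>% filter(.data$library == lib)
    v <- stats::setNames(cnt$n, cnt$gene_id)[out$gene_id]
    out[[lib]] <- as.integer(ifelse(is.na(v), 0L, v))
  }
  attr(out, "lib_sizes") <- stats::setNames(
    vapply(libraries, function(l) sum(out[[l]]), integer(1)), libraries)
  class(out) <- c("tag_counts", class(out))
  out
}

#' The Stekel-Falciani-Brazma R statistic for tag counts
#'
#' For one gene with counts \eqn{x_j} in libraries of sizes \eqn{N_j},
#' \deqn{R = \sum_j x_j \ln\left(\frac{x_j}{N_j f}\right), \qquad
#'       f = \frac{\sum_j x_j}{\sum_j N_j},}
#' with \eqn{0 \cdot \ln(0/\cdot) = 0}. This is the log-likelihood ratio of
#' library-specific Poisson rates against a single pooled rate, so
#' \eqn{R \ge 0}, with equality iff the proportions \eqn{x_j/N_j} are equal.
#'
#' @param x integer vector of counts (one gene), or a matrix with one row per
#'   gene and one column per library.
#' @param N integer vector of library sizes (all `> 0`).
#' @return numeric: one R value per gene. Genes with all-zero counts get
#'   `NA` (no evidence; they are excluded from testing).
#' @export
r_statistic <- function(x, N) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == length(N), all(N > 0), all(x >= 0))
  tot <- rowSums(x)
  f <- tot / sum(N)
  expd <- outer(f, N)
  term <- x * log(x / expd)
  term[x == 0] <- 0
  r <- rowSums(term)
  r[tot == 0] <- NA_real_
  r
}

#' Convert R statistics to p-values
#'
#' `chisq`: upper tail of a chi-square with `m - 1` degrees of freedom at
#' `2R` (the asymptotic null of the likelihood-ratio statistic).
#' `montecarlo`: for each gene, the total count is redistributed across
#' libraries in proportion to the library sizes (multinomial null), the R
#' statistic recomputed, and p estimated as `(r + 1) / (reps + 1)` where `r`
#' counts resampled statistics at least as large as the observed one; this
#' uses the current RNG stream.
#'
#' @param R numeric vector of R statistics.
#' @param m number of libraries.
#' @param method `"chisq"` or `"montecarlo"`.
#' @param x,N count matrix and library sizes — required for `montecarlo`.
#' @param reps Monte-Carlo replicates.
#' @return numeric vector of p-values (`NA` where `R` is `NA`).
#' @export
r_pvalue <- function(R, m = 2L, method = c("chisq", "montecarlo"),
                     x = NULL, N = NULL, reps = 1000L) {
  method <- match.arg(method)
  if (method == "chisq") {
    p <- pchisq(2 * R, df = m - 1L, lower.tail = FALSE)
    p[!is.na(R) & R <= 0] <- 1
    return(p)
  }
  stopifnot(!is.null(x), !is.null(N))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  prob <- N / sum(N)
  vapply(seq_along(R), function(i) {
    if (is.na(R[i])) return(NA_real_)
    tot <- sum(x[i, ])
    null_x <- t(stats::rmultinom(reps, tot, prob))
    r_null <- r_statistic(null_x, N)
    (sum(r_null >= R[i] - 1e-12) + 1) / (reps + 1)
  }, numeric(1))
}

#' Convert p-values to q-values
#'
#' `BH` is the Benjamini-Hochberg step-up FDR. `storey` multiplies the BH
#' values by the estimated null proportion
#' \eqn{\hat\pi_0 = \min(1, \#\{p > \lambda\} / ((1-\lambda) m))} with a
#' fixed \eqn{\lambda} (no smoother), so `storey` equals `BH` when
#' \eqn{\hat\pi_0 = 1}.
#'
#' @param p numeric vector of p-values (`NA` allowed, propagated).
#' @param method `"BH"` or `"storey"`.
#' @param lambda tuning constant for the Storey null-proportion estimate.
#' @return numeric vector of q-values, monotone in the p-value ranks.
#' @export
qvalues <- function(p, method = c("BH", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    ok <- !is.na(p)
    pi0 <- min(1, sum(p[ok] > lambda) / ((1 - lambda) * sum(ok)))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Call differentially expressed genes between two libraries
#'
#' Computes per-gene R statistics, p- and q-values, and the normalized fold
#' change on pseudocounted rates \eqn{((x_j + 1)/N_j)}; a gene is called DE
#' iff its fold change exceeds `fold_threshold` and its q-value is below
#' `q_threshold`. Genes with zero counts in both libraries carry no evidence
#' and are excluded.
#'
#' @param counts a `tag_counts` from [count_tags()], or a tibble with
#'   `gene_id` and two count columns plus a `lib_sizes` attribute (or
#'   supplied via `lib_sizes`).
#' @param fold_threshold fold-change threshold (exclusive), default 2.
#' @param q_threshold q-value threshold (exclusive), default 0.05.
#' @param p_method,q_method see [r_pvalue()] and [qvalues()].
#' @param lib_sizes optional named library sizes overriding the attribute.
#' @param reps Monte-Carlo replicates if `p_method = "montecarlo"`.
#' @return tibble: `gene_id`, counts `x_1`/`x_2`, sizes `N_1`/`N_2`, pooled
#'   rate `f`, `R`, `p`, `q`, `fold` (always >= 1), `direction` (library with
#'   the higher normalized rate) and logical `de`.
#' @export
call_de <- function(counts, fold_threshold = 2, q_threshold = 0.05,
                    p_method = "chisq", q_method = "BH", lib_sizes = NULL,
                    reps = 1000L) {
  libs <- setdiff(names(counts), "gene_id")[1:2]
  N <- lib_sizes %||% attr(counts, "lib_sizes")
  if (is.null(N)) stop("library sizes missing: supply `lib_sizes`")
  N <- unname(N[libs])
  x <- as.matrix(counts[, libs])
  keep <- rowSums(x) > 0
  counts <- counts[keep, ]; x <- x[keep, , drop = FALSE]
  R <- r_statistic(x, N)
  p <- r_pvalue(R, m = 2L, method = p_method, x = x, N = N, reps = reps)
  q <- qvalues(p, method = q_method)
  rate1 <- (x[, 1] + 1) / N[1]
  rate2 <- (x[, 2] + 1) / N[2]
  fold <- pmax(rate1 / rate2, rate2 / rate1)
  # ties (fold exactly 1) resolve to the lexicographically smaller tag so the
  # label does not depend on column order
  direction <- ifelse(rate1 > rate2, libs[1],
                      ifelse(rate2 > rate1, libs[2], min(libs)))
  tibble(
    gene_id = counts$gene_id,
    x_1 = x[, 1], x_2 = x[, 2], N_1 = N[1], N_2 = N[2],
    f = rowSums(x) / sum(N),
    R = R, p = p, q = q, fold = fold, direction = direction,
    de = fold > fold_threshold & q < q_threshold
  )
}

#' Simulate a two-library tag-count table
#'
#' Count-level companion to the read-level simulator, for statistical
#' validation of the DE caller at scale: per-gene rates are gamma around
#' `base_expression`, a chosen fraction of genes carries a true fold change
#' (half up in each library), and counts are multinomial given the fixed
#' library sizes.
#'
#' @param n_genes number of genes.
#' @param lib_sizes two library sizes (named `G`, `H` if unnamed).
#' @param de_fraction fraction of DE genes (0 for a null simulation).
#' @param de_fold true fold change of DE genes.
#' @param shape gamma shape of the per-gene rate distribution (mean fixed).
#' @return list: `counts` (a `tag_counts`) and `truth` (gene, true fold).
#' @export
simulate_counts <- function(n_genes, lib_sizes = c(G = 20000L, H = 20000L),
                            de_fraction = 0, de_fold = 4, shape = 2) {
  if (is.null(names(lib_sizes))) names(lib_sizes) <- c("G", "H")
  w <- rgamma(n_genes, shape = shape, rate = shape)
  fold <- rep(1, n_genes)
  n_de <- round(de_fraction * n_genes)
  if (n_de > 0) {
    idx <- sample(n_genes, n_de)
    half <- ceiling(n_de / 2)
    fold[idx[seq_len(half)]] <- de_fold
    if (n_de > half) fold[idx[(half + 1):n_de]] <- 1 / de_fold
  }
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  w1 <- w * ifelse(fold > 1, fold, 1)
  w2 <- w * ifelse(fold < 1, 1 / fold, 1)
  x1 <- as.integer(stats::rmultinom(1, lib_sizes[[1]], w1))
  x2 <- as.integer(stats::rmultinom(1, lib_sizes[[2]], w2))
  counts <- tibble(gene_id = gene_id)
  counts[[names(lib_sizes)[1]]] <- x1
  counts[[names(lib_sizes)[2]]] <- x2
  attr(counts, "lib_sizes") <- stats::setNames(as.integer(lib_sizes),
                                               names(lib_sizes))
  class(counts) <- c("tag_counts", class(counts))
  list(counts = counts, truth = tibble(gene_id = gene_id, fold = fold))
}
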