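#' Read a Gene Ontology OBO file
#'
#' Minimal OBO 1.2 parser covering what slim mapping and enrichment need:
#' `[Term]` stanzas with `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` edges, and `is_obsolete`. Obsolete terms are
#' dropped (with a message giving the count), as are edges touching them.
#'
#' @param path OBO file path.
#' @return object of class `ontology`: list with `terms` (tibble `id`,
#'   `name`, `namespace`) and `parents` (tibble `id`, `parent`, `rel` with
#'   `rel` in `is_a`/`part_of`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  term_rows <- list(); edge_rows <- list()
  n_obsolete <- 0L
  for (si in seq_along(stanza_starts)) {
    s <- stanza_starts[si]
    if (lines[s] != "[Term]") next
    e <- if (si < length(stanza_starts)) stanza_starts[si + 1L] - 1L else length(lines)
    chunk <- lines[(s + 1L):e]
    get1 <- function(tag) {
      v <- sub(paste0("^", tag, ": "), "", grep(paste0("^", tag, ": "), chunk,
                                                value = TRUE))
      if (length(v) == 0) NA_character_ else sub(" *!.*$", "", v[1])
    }
    id <- get1("id")
    if (is.na(id)) next
    if (any(grepl("^is_obsolete: true", chunk))) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    term_rows[[length(term_rows) + 1L]] <- tibble(
      id = id, name = get1("name"), namespace = get1("namespace"))
    isa <- sub(" *!.*$", "", sub("^is_a: ", "",
                                 grep("^is_a: ", chunk, value = TRUE)))
    po <- grep("^relationship: part_of ", chunk, value = TRUE)
    po <- sub(" *!.*$", "", sub("^relationship: part_of ", "", po))
    if (length(isa) + length(po) > 0) {
      edge_rows[[length(edge_rows) + 1L]] <- tibble(
        id = id, parent = c(isa, po),
        rel = c(rep("is_a", length(isa)), rep("part_of", length(po))))
    }
  }
  terms <- bind_rows(term_rows)
  parents <- if (length(edge_rows)) bind_rows(edge_rows) else
    tibble(id = character(0), parent = character(0), rel = character(0))
  parents <- parents %>% filter(.data$parent %in% terms$id)
  if (n_obsolete > 0) message(n_obsolete, " obsolete term(s) dropped")
  structure(list(terms = terms, parents = parents), class = "ontology")
}

#' Read gene-to-GO annotations
#'
#' Accepts either a two-column TSV (`gene_id`, `term`, header optional) or a
#' GAF 2.x file (comment lines `!`, object id in column 2, GO id in column
#' 5).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gaf"`.
#' @return tibble with `gene_id` and `term`, distinct rows.
#' @export
read_gene2go <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "gaf") {
    lines <- grep("^!", readLines(path, warn = FALSE), value = TRUE,
                  invert = TRUE)
    f <- strsplit(lines, "\t", fixed = TRUE)
    out <- tibble(gene_id = vapply(f, `[`, character(1), 2),
                  term = vapply(f, `[`, character(1), 5))
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(df[1, 1]), "gene_id")) df <- df[-1, , drop = FALSE]
    out <- tibble(gene_id = as.character(df[[1]]), term = as.character(df[[2]]))
  }
  distinct(out)
}

#' Construct an ontology from term and edge tables
#'
#' @param terms tibble with `id` (and optionally `name`, `namespace`).
#' @param parents tibble with `id`, `parent` (and optionally `rel`);
#'   child-to-parent edges over `is_a`/`part_of`.
#' @return an `ontology` object; cycles are an error.
#' @export
ontology <- function(terms, parents) {
  terms <- as_tibble(terms)
  parents <- as_tibble(parents)
  if (!"name" %in% names(terms)) terms$name <- terms$id
  if (!"namespace" %in% names(terms)) terms$namespace <- NA_character_
  if (!"rel" %in% names(parents)) parents$rel <- "is_a"
  missing <- setdiff(c(parents$id, parents$parent), terms$id)
  if (length(missing) > 0) {
    stop("edge endpoint(s) not in term table: ", paste(missing, collapse = ", "))
  }
  ont <- structure(list(terms = terms, parents = parents), class = "ontology")
  # acyclicity: every term must have a finite ancestor closure
  for (id in terms$id) term_ancestors(ont, id)
  ont
}

# All ancestors of a term (is_a + part_of closure), excluding itself.
term_ancestors <- function(ont, id) {
  seen <- character(0)
  frontier <- ont$parents$parent[ont$parents$id == id]
  steps <- 0L
  while (length(frontier) > 0) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- ont$parents$parent[ont$parents$id %in% frontier]
    steps <- steps + 1L
    if (steps > nrow(ont$terms) + 1L) stop("cycle detected in ontology at ", id)
  }
  seen
}

#' Map a term to its minimal slim ancestors
#'
#' Returns the slim terms that are ancestors-or-self of `term` and reachable
#' from it by at least one path containing no other slim term (the map2slim
#' rule). A term that is itself in the slim maps to itself. A term with two
#' slim ancestors on independent paths returns both.
#'
#' @param term a term id (scalar).
#' @param ont an [ontology].
#' @param slim character vector of slim term ids.
#' @return character vector of slim term ids (possibly empty).
#' @export
map_to_slim <- function(term, ont, slim) {
  if (!term %in% ont$terms$id) return(character(0))
  if (term %in% slim) return(term)
  hit <- character(0)
  seen <- term
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- unique(ont$parents$parent[ont$parents$id %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    hit <- c(hit, intersect(nxt, slim))
    frontier <- setdiff(nxt, slim)  # slim nodes block further traversal
  }
  sort(unique(hit))
}

#' Classify genes into slim functional groups
#'
#' Each gene counts once per slim term, regardless of how many of its
#' annotations map there.
#'
#' @param annotations tibble with `gene_id`, `term`.
#' @param ont an [ontology].
#' @param slim character vector of slim term ids.
#' @return tibble `term`, `n_genes`, one row per slim term (zeros included),
#'   in the order of `slim`.
#' @export
classify_by_slim <- function(annotations, ont, slim) {
  counts <- stats::setNames(integer(length(slim)), slim)
  for (g in unique(annotations$gene_id)) {
    terms <- unique(annotations$term[annotations$gene_id == g])
    hits <- unique(unlist(lapply(terms, map_to_slim, ont = ont, slim = slim)))
    counts[hits] <- counts[hits] + 1L
  }
  tibble(term = slim, n_genes = unname(counts))
}

#' Propagate gene annotations to ancestor terms
#'
#' A gene annotated to a term is annotated to every ancestor of that term
#' (the true-path rule), so term counts are monotone non-decreasing toward
#' the root.
#'
#' @param annotations tibble with `gene_id`, `term`.
#' @param ont an [ontology]; annotations to unknown terms are dropped.
#' @return tibble `gene_id`, `term`, distinct rows.
#' @export
propagate_annotations <- function(annotations, ont) {
  annotations <- annotations %>% filter(.data$term %in% ont$terms$id)
  anc_cache <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    a <- term_ancestors(ont, t)
    anc_cache[[t]] <- a
    a
  }
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    tibble(gene_id = annotations$gene_id[i],
           term = c(annotations$term[i], anc(annotations$term[i])))
  })
  bind_rows(rows) %>% distinct()
}

#' Hypergeometric GO term enrichment
#'
#' Tests each annotated term for over-representation in a study gene set
#' against a population (background) set, using the upper tail of the
#' hypergeometric distribution: with `N` population genes of which `K` carry
#' the term, and `n` study genes of which `k` carry it, the raw p-value is
#' `P(X >= k)`. Annotations are propagated to ancestors first when an
#' ontology is given. A term is flagged enriched iff its adjusted p-value is
#' below `alpha`.
#'
#' @param study,population character vectors of gene ids; `study` must be a
#'   subset of `population`.
#' @param annotations tibble `gene_id`, `term`.
#' @param ont optional [ontology] for true-path propagation.
#' @param adjust `"BH"` or `"bonferroni"`.
#' @param alpha enrichment threshold on the adjusted p (default 0.05).
#' @return tibble: `term`, `k` (study count), `n` (study size), `K`
#'   (population count), `N` (population size), `p`, `p_adj`, `enriched`,
#'   sorted by `p`.
#' @export
enrich <- function(study, population, annotations, ont = NULL,
                   adjust = c("BH", "bonferroni"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  study <- unique(study); population <- unique(population)
  bad <- setdiff(study, population)
  if (length(bad) > 0) {
    stop("study gene(s) absent from population: ", paste(bad, collapse = ", "))
  }
  ann <- annotations %>% filter(.data$gene_id %in% population) %>% distinct()
  if (!is.null(ont)) ann <- propagate_annotations(ann, ont)
  N <- length(population); n <- length(study)
  per_term <- ann %>%
    group_by(.data$term) %>%
    summarise(K = n_distinct(.data$gene_id),
              k = n_distinct(intersect(.data$gene_id, study)),
              .groups = "drop")
  p <- phyper(per_term$k - 1L, per_term$K, N - per_term$K, n,
              lower.tail = FALSE)
  out <- per_term %>%
    mutate(n = n, N = N, p = p,
           p_adj = p.adjust(p, method = if (adjust == "BH") "BH" else
             "bonferroni"),
           enriched = .data$p_adj < alpha) %>%
    select("term", "k", "n", "K", "N", "p", "p_adj", "enriched") %>%
    arrange(.data$p, .data$term)
  out
}
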