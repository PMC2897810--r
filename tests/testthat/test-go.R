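write_toy_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]", "id: GO:0000001", "name: root process",
    "namespace: biological_process",
    "",
    "[Term]", "id: GO:0000002", "name: branch A",
    "namespace: biological_process", "is_a: GO:0000001 ! root process",
    "",
    "[Term]", "id: GO:0000003", "name: branch B",
    "namespace: biological_process",
    "relationship: part_of GO:0000001 ! root process",
    "",
    "[Term]", "id: GO:0000004", "name: leaf",
    "namespace: biological_process", "is_a: GO:0000002 ! branch A",
    "is_a: GO:0000003 ! branch B",
    "",
    "[Term]", "id: GO:0000099", "name: gone", "is_obsolete: true",
    "",
    "[Typedef]", "id: part_of", "name: part of"
  ), path)
  path
}

test_that("the OBO reader keeps is_a and part_of edges and drops obsoletes", {
  obo <- write_toy_obo(file.path(withr::local_tempdir(), "toy.obo"))
  expect_message(ont <- read_obo(obo), "1 obsolete")
  expect_equal(sort(ont$terms$id), paste0("GO:000000", 1:4))
  expect_equal(nrow(ont$parents), 4L)
  expect_setequal(ont$parents$rel, c("is_a", "part_of"))
  expect_setequal(ont$parents$parent[ont$parents$id == "GO:0000004"],
                  c("GO:0000002", "GO:0000003"))
})

test_that("annotation tables read from two-column TSV and GAF", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "ann.tsv")
  writeLines(c("gene_id\tterm", "g1\tGO:0000001", "g1\tGO:0000001",
               "g2\tGO:0000002"), tsv)
  ann <- read_gene2go(tsv)
  expect_equal(nrow(ann), 2L)   # duplicates collapse
  expect_equal(ann$term[ann$gene_id == "g2"], "GO:0000002")
  gaf <- file.path(d, "ann.gaf")
  writeLines(c("!gaf-version: 2.2",
               paste("DB", "g1", "sym", "", "GO:0000003", "ref", "IEA",
                     "", "P", "", "", "protein", "taxon:1", "20200101",
                     "DB", sep = "\t")), gaf)
  ag <- read_gene2go(gaf, "gaf")
  expect_equal(ag$gene_id, "g1")
  expect_equal(ag$term, "GO:0000003")
})

test_that("slim mapping returns the nearest slim ancestors", {
  dag <- toy_dag()
  # chain t02 -> t04 -> t06 -> t07 with slim {t04, t07}: the nearer slim
  # term screens the root
  expect_equal(map_to_slim("t02", dag$ont, c("t04", "t07")), "t04")
  # a slim term maps to itself
  expect_equal(map_to_slim("t04", dag$ont, c("t04", "t07")), "t04")
  # two slim ancestors on independent paths are both returned
  expect_equal(map_to_slim("t08", dag$ont, c("t04", "t09")),
               c("t04", "t09"))
})

test_that("slim mapping matches exhaustive path enumeration on the toy DAG", {
  dag <- toy_dag()
  set.seed(55)
  ids <- names(dag$edges)
  for (i in 1:30) {
    slim <- sample(ids, sample(2:5, 1))
    for (term in ids) {
      expect_equal(map_to_slim(term, dag$ont, slim),
                   oracle_min_slim(term, dag$edges, slim),
                   label = paste(term, "slim:", paste(slim, collapse = ",")))
    }
  }
})

test_that("slim classification counts each gene once per slim term", {
  dag <- toy_dag()
  ann <- tibble::tibble(gene_id = c("a", "a", "b"),
                        term = c("t01", "t02", "t10"))
  slim <- c("t04", "t09")
  res <- classify_by_slim(ann, dag$ont, slim)
  expect_equal(res$n_genes[res$term == "t04"], 2L)  # both via t02/t01 and t10
  expect_equal(res$n_genes[res$term == "t09"], 1L)
  expect_equal(classify_by_slim(ann[0, ], dag$ont, slim)$n_genes, c(0L, 0L))
})

test_that("annotation propagation is monotone toward the root", {
  dag <- toy_dag()
  ann <- tibble::tibble(gene_id = c("a", "b", "c"),
                        term = c("t01", "t08", "t05"))
  prop <- propagate_annotations(ann, dag$ont)
  counts <- table(prop$term)
  for (i in seq_len(nrow(dag$ont$parents))) {
    child <- dag$ont$parents$id[i]; par <- dag$ont$parents$parent[i]
    kc <- if (child %in% names(counts)) counts[[child]] else 0L
    kp <- if (par %in% names(counts)) counts[[par]] else 0L
    expect_gte(kp, kc)
  }
})

test_that("hypergeometric p-values are exact and thresholds apply to adjusted p", {
  genes <- paste0("g", 1:20)
  ann <- tibble::tibble(gene_id = genes[1:5], term = "T1")
  study <- c(genes[1:4], genes[20])   # k = 4 of n = 5, K = 5, N = 20
  res <- enrich(study, genes, ann)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$k, 4L)
  # k = 0 -> p = 1
  res0 <- enrich(genes[19:20], genes, ann)
  expect_equal(res0$p, 1)
  # enriched iff adjusted p < 0.05
  expect_equal(res$enriched, res$p_adj < 0.05)
  expect_error(enrich(c("nope"), genes, ann), "absent")
})

test_that("enrichment p-values match exact enumeration on small cases", {
  set.seed(66)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    genes <- paste0("g", seq_len(N))
    ann <- if (K > 0) {
      tibble::tibble(gene_id = genes[seq_len(K)], term = "T")
    } else tibble::tibble(gene_id = character(0), term = character(0))
    study <- sample(genes, n)
    res <- enrich(study, genes, ann)
    if (K == 0) { expect_equal(nrow(res), 0L); next }
    k <- length(intersect(study, genes[seq_len(K)]))
    expect_equal(res$p, oracle_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("bonferroni adjustment is available and never below BH", {
  genes <- paste0("g", 1:30)
  set.seed(77)
  ann <- tibble::tibble(
    gene_id = sample(genes, 40, replace = TRUE),
    term = sample(paste0("T", 1:6), 40, replace = TRUE))
  study <- genes[1:8]
  bh <- enrich(study, genes, ann, adjust = "BH")
  bf <- enrich(study, genes, ann, adjust = "bonferroni")
  expect_true(all(bf$p_adj >= bh$p_adj - 1e-12))
  expect_true(all(bh$p_adj >= bh$p))
})
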