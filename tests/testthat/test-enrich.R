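test_that("annotation tables load with counts, flags and validation", {
  p <- write_toy_annotations()
  cat <- load_annotations(p$snp_gene, p$gene_pathway, p$reference)
  expect_s3_class(cat, "annotation_catalog")
  expect_equal(nrow(cat$snp_to_genes), 4L)          # snp5 maps to "-"
  expect_equal(cat$unmapped_snps, "snp5")
  expect_equal(nrow(cat$pathways), 2L)
  expect_equal(cat$reference_total, 50L)
  expect_setequal(query_genes_for_snps(c("snp1", "snp3", "snp5"), cat),
                  c("geneA", "geneB"))

  # reference without a TOTAL row is rejected
  bad <- readLines(p$reference)
  writeLines(bad[!grepl("TOTAL", bad)], p$reference)
  expect_error(load_annotations(p$snp_gene, p$gene_pathway, p$reference),
               "TOTAL")
})

test_that("an empty pathway table gives an empty enrichment result", {
  p <- write_toy_annotations()
  gp0 <- file.path(dirname(p$gene_pathway), "gp0.tsv")
  writeLines("gene\tpathway_id\tpathway_name", gp0)
  ref0 <- file.path(dirname(p$reference), "ref0.tsv")
  writeLines(c("pathway_id\tref_gene_count", "TOTAL\t50"), ref0)
  cat0 <- load_annotations(p$snp_gene, gp0, ref0)
  expect_equal(nrow(cat0$pathways), 0L)
  res <- overrepresentation_test(c("geneA", "geneB"), cat0)
  expect_equal(nrow(res), 0L)
})

test_that("expected counts and fold enrichment follow the reference share", {
  # a pathway of 100 reference genes, a 265-gene query with 9 hits, and a
  # 20,589-gene reference universe: expected ~1.29 genes, ~7-fold excess
  dir <- local_fixture_dir()
  n_total <- 20589L; k <- 100L; n_query <- 265L; obs <- 9L
  genes <- paste0("g", seq_len(n_query + k))
  in_pw <- c(genes[seq_len(obs)], paste0("x", seq_len(k - obs)))
  sg <- data.frame(snp_id = paste0("s", seq_len(n_query)), gene = genes[seq_len(n_query)])
  gp <- data.frame(gene = in_pw, pathway_id = "pwA", pathway_name = "growth factor signalling")
  ref <- data.frame(pathway_id = c("pwA", "TOTAL"), ref_gene_count = c(k, n_total))
  fp <- c(sg = file.path(dir, "sg.tsv"), gp = file.path(dir, "gp.tsv"),
          ref = file.path(dir, "ref.tsv"))
  write.table(sg, fp["sg"], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(gp, fp["gp"], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(ref, fp["ref"], sep = "\t", row.names = FALSE, quote = FALSE)
  cat <- load_annotations(fp["sg"], fp["gp"], fp["ref"])
  res <- overrepresentation_test(genes[seq_len(n_query)], cat)
  expect_equal(round(res$expected, 2), 1.29)
  expect_equal(signif(res$fold, 3), 6.99)
  expect_equal(res$fold * res$expected, res$observed, tolerance = 1e-12)
  expect_identical(res$direction, "+")
  expect_lt(res$p_raw, 1e-5)
})

test_that("Fisher p-values equal brute-force hypergeometric enumeration", {
  grid <- expand.grid(n_total = c(20L, 47L, 100L), k = c(3L, 5L, 12L),
                      n_query = c(4L, 10L))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cat <- hypergeom_catalog(g$n_total, g$k)
    genes <- paste0("g", seq_len(g$n_total))
    obs_min <- max(0L, g$n_query - (g$n_total - g$k))
    for (obs in obs_min:min(g$k, g$n_query)) {
      query <- c(genes[seq_len(obs)],
                 genes[g$k + seq_len(g$n_query - obs)])
      res <- overrepresentation_test(query, cat)
      expect_equal(res$p_raw,
                   hypergeom_tail(obs, g$n_total, g$k, g$n_query),
                   tolerance = 1e-10)
      expect_equal(res$observed, obs)
    }
  }
})

test_that("the exact tail matches a hand-enumerated tail probability", {
  cat <- hypergeom_catalog(20L, 5L)
  genes <- paste0("g", 1:20)
  query <- c(genes[1:3], genes[6])              # 3 of 4 query genes in pathway
  res <- overrepresentation_test(query, cat)
  hand <- sum(choose(5, 3:4) * choose(15, 1:0)) / choose(20, 4)
  expect_equal(res$p_raw, hand, tolerance = 1e-12)
})

test_that("BH adjustment matches its step-up definition", {
  expect_equal(adjust_fdr(tibble::tibble(p_raw = 0.01))$fdr, 0.01)
  expect_equal(adjust_fdr(tibble::tibble(p_raw = c(0.01, 0.02, 0.03)))$fdr,
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(tibble::tibble(p_raw = rep(1, 4)))$fdr, rep(1, 4))
  set.seed(77)
  p <- runif(25)
  q <- adjust_fdr(tibble::tibble(p_raw = p))$fdr
  # brute force: q_(i) = min over j >= i of p_(j) * m / j
  ord <- order(p)
  m <- length(p)
  q_brute <- numeric(m)
  for (i in seq_len(m)) {
    q_brute[ord[i]] <- min(pmin(p[ord][i:m] * m / (i:m), 1))
  }
  expect_equal(q, q_brute, tolerance = 1e-12)
})

test_that("SNP sets respect multi-pathway membership, unions and 'other'", {
  p <- write_toy_annotations()
  cat <- load_annotations(p$snp_gene, p$gene_pathway, p$reference)
  snps <- paste0("snp", 1:5)
  sets <- build_snp_sets(snps, cat, pathways = c("pw1", "pw2"),
                         combine = list(both = c("pw1", "pw2")))
  expect_true("snp3" %in% sets$pw1 && "snp3" %in% sets$pw2)  # geneB in both
  expect_setequal(sets$pw1, c("snp1", "snp2", "snp3"))
  expect_setequal(sets$pw2, c("snp3", "snp4"))
  expect_setequal(sets$both, union(sets$pw1, sets$pw2))
  expect_setequal(sets$other, "snp5")                         # unmapped
  # subset combine: union with a contained pathway equals the larger one
  sets2 <- build_snp_sets(snps, cat, pathways = "pw1",
                          combine = list(just1 = "pw1"))
  expect_setequal(sets2$just1, sets2$pw1)
  expect_error(build_snp_sets(snps, cat, pathways = "missing"), "Unknown")
})
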