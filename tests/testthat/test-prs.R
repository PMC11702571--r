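prs_cohort <- function(seed = 61) {
  spec <- small_spec(n_snps = 40L, q_causal = 5L, q_gxe = 0L,
                     overlap = c(0L, 0L, 0L),
                     n_cases = 1500L, n_controls = 1500L)
  simulate_cohort(spec, effect_config(spec, deltaG = 0.3), seed = seed)
}

test_that("a single-SNP weight equals the univariate logistic coefficient", {
  cohort <- prs_cohort()
  w <- estimate_weights(cohort, "snp_0001")
  oracle <- glm(D ~ snp_0001, family = binomial(), data = cohort)
  expect_equal(w$weight, unname(coef(oracle)[2]), tolerance = 1e-6)
})

test_that("joint weights on independent SNPs track the marginal estimates", {
  cohort <- prs_cohort()
  ids <- sprintf("snp_%04d", 1:5)
  w <- estimate_weights(cohort, ids)
  for (i in seq_along(ids)) {
    oracle <- glm(stats::reformulate(ids[i], "D"), family = binomial(),
                  data = cohort)
    se <- sqrt(diag(vcov(oracle)))[2]
    expect_lt(abs(w$weight[i] - coef(oracle)[2]), 2 * se)
  }
  expect_identical(attr(w, "provenance"), "insample_discovered")
})

test_that("unit weights reduce the PRS to an allele-count sum", {
  cohort <- prs_cohort()
  ids <- sprintf("snp_%04d", 1:6)
  w <- manual_weights(ids, rep(1, 6))
  sc <- compute_scores(cohort, w)
  expect_equal(sc$prs, rowSums(as.data.frame(cohort)[ids]), ignore_attr = TRUE)
})

test_that("pathway scores partition the PRS exactly", {
  cohort <- prs_cohort()
  ids <- sprintf("snp_%04d", 1:8)
  set.seed(5)
  w <- manual_weights(ids, rnorm(8))
  sets <- list(a = ids[1:3], b = ids[4:5])
  sc <- compute_scores(cohort, w, snp_sets = sets)
  expect_equal(sc$pprs_a + sc$pprs_b + sc$npprs, sc$prs, tolerance = 1e-12)
  # overlapping sets break the partition but each subset is still exact
  sets2 <- list(a = ids[1:4], b = ids[3:6])
  sc2 <- compute_scores(cohort, w, snp_sets = sets2)
  g <- as.matrix(as.data.frame(cohort)[ids[3:6]])
  expect_equal(sc2$pprs_b, drop(g %*% w$weight[3:6]), tolerance = 1e-12)
})

test_that("standardization yields exact zero mean and unit sd", {
  cohort <- prs_cohort()
  ids <- sprintf("snp_%04d", 1:5)
  w <- manual_weights(ids, c(0.2, -0.1, 0.4, 0.3, -0.2))
  sc <- compute_scores(cohort, w, snp_sets = list(a = ids[1:2]),
                       standardize = TRUE)
  for (col in c("prs", "pprs_a", "npprs")) {
    expect_lt(abs(mean(sc[[col]])), 1e-12)
    expect_equal(sd(sc[[col]]), 1, tolerance = 1e-12)
  }
  expect_true(all(attr(sc, "sd_scale") > 0))
})

test_that("scores are linear in the weights and order-invariant", {
  cohort <- prs_cohort()
  ids <- sprintf("snp_%04d", 1:5)
  set.seed(8)
  w1 <- rnorm(5); w2 <- rnorm(5)
  s1 <- compute_scores(cohort, manual_weights(ids, w1))$prs
  s2 <- compute_scores(cohort, manual_weights(ids, w2))$prs
  s12 <- compute_scores(cohort, manual_weights(ids, w1 + w2))$prs
  expect_equal(s12, s1 + s2, tolerance = 1e-10)
  perm <- c(3, 1, 5, 2, 4)
  s_perm <- compute_scores(cohort, manual_weights(ids[perm], w1[perm]))$prs
  expect_equal(s_perm, s1, tolerance = 1e-12)
})

test_that("missing weight SNPs and unknown subset SNPs error clearly", {
  cohort <- prs_cohort()
  w <- manual_weights(c("snp_0001", "absent_snp"), c(1, 1))
  expect_error(compute_scores(cohort, w), "absent_snp")
  w2 <- manual_weights("snp_0001", 1)
  expect_error(compute_scores(cohort, w2, snp_sets = list(a = "snp_0002")),
               "snp_0002")
  expect_error(estimate_weights(cohort, character(0)), "At least one")
})

test_that("separation triggers the ridge fallback with a warning", {
  set.seed(13)
  n <- 80
  d <- rep(c(0L, 1L), each = n / 2)
  cohort <- tibble::tibble(id = 1:n, D = d, E = rbinom(n, 1, 0.5),
                           snp_0001 = d,            # perfect separator
                           snp_0002 = rbinom(n, 1, 0.4))
  expect_warning(w <- estimate_weights(cohort, c("snp_0001", "snp_0002")),
                 "ridge")
  expect_true(attr(w, "ridged"))
  expect_true(all(is.finite(w$weight)))
})

test_that("PGS scoring files round-trip and enforce uniqueness", {
  w <- manual_weights(c("rs1", "rs2", "rs3"), c(0.123456789012, -0.5, 1e-4),
                      effect_allele = c("A", "C", "T"))
  path <- tempfile(fileext = ".txt")
  write_pgs_scorefile(w, path)
  w2 <- read_pgs_scorefile(path)
  expect_equal(nrow(w2), 3L)
  expect_equal(w2$weight, w$weight, tolerance = 1e-12)
  expect_identical(attr(w2, "provenance"), "catalog")

  lines <- readLines(path)
  dup <- sub("rs2", "rs1", lines)
  path2 <- tempfile(fileext = ".txt")
  writeLines(dup, path2)
  expect_error(read_pgs_scorefile(path2), "duplicated")

  nohead <- lines[!grepl("^rsID|^#", lines)]
  path3 <- tempfile(fileext = ".txt")
  writeLines(c("rsID\tother\tcolumns", nohead[0]), path3)
  expect_error(read_pgs_scorefile(path3), "mandatory")
})
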