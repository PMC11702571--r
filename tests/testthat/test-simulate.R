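test_that("quota sampling returns the exact design at full scale", {
  spec <- scenario_spec()
  cohort <- simulate_cohort(spec, calibrated_effects(spec), seed = 101)
  expect_equal(nrow(cohort), 10000L)
  expect_equal(sum(cohort$D), 5000L)
  expect_equal(sum(cohort$D == 0), 5000L)
  expect_length(setdiff(names(cohort), c("id", "D", "E")), 1000L)
  truth <- cohort_truth(cohort)
  expect_equal(sum(truth$role == "gxe"), 5L)
  expect_equal(sum(truth$role == "gonly"), 15L)
  expect_equal(sum(truth$in_pathway), 5L)
})

test_that("simulation is bit-identical under a fixed seed", {
  spec <- small_spec()
  eff <- effect_config(spec, deltaG = 0.3, deltaGxE = 0.2)
  a <- simulate_cohort(spec, eff, seed = 7)
  b <- simulate_cohort(spec, eff, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_cohort(spec, eff, seed = 8)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("under all-null effects genotypes and exposure are undistorted", {
  spec <- small_spec(n_snps = 120L, n_cases = 1500L, n_controls = 1500L)
  eff <- effect_config(spec, deltaG = 0, deltaGxE = 0, deltaE = 0)
  cohort <- simulate_cohort(spec, eff, seed = 31)
  G <- cohort_genotypes(cohort)
  # per-SNP case-control log odds ratios scatter around zero
  p_case <- colMeans(G[cohort$D == 1, ])
  p_ctrl <- colMeans(G[cohort$D == 0, ])
  log_or <- qlogis(p_case) - qlogis(p_ctrl)
  expect_lt(abs(mean(log_or)), 0.02)
  expect_lt(max(abs(log_or)), 0.35)
  expect_lt(abs(mean(cohort$E[cohort$D == 1]) - spec$e_prev), 0.03)
})

test_that("a single causal SNP reproduces its closed-form case-control OR", {
  # Oracle: enumerate the four (G, D) cells of the single-SNP population
  # model; the case-control odds ratio equals the generative one.
  spec <- small_spec(n_snps = 5L, q_causal = 1L, q_gxe = 0L,
                     overlap = c(0L, 0L, 0L),
                     n_cases = 2500L, n_controls = 2500L)
  delta <- log(2)
  eff <- effect_config(spec, deltaG = delta, deltaE = 0)
  f <- spec$g_freq
  b0 <- eff$delta0
  pd <- plogis(b0 + delta * c(0, 1))
  cell <- c(g0 = (1 - f) * pd[1], g1 = f * pd[2])      # P(G, D=1)
  prev <- sum(cell)
  p1 <- cell["g1"] / prev
  p0 <- f * (1 - pd[2]) / (1 - prev)
  oracle_or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  expect_equal(unname(oracle_or), 2, tolerance = 1e-10)

  cohort <- simulate_cohort(spec, eff, seed = 55)
  g <- cohort$snp_0001
  emp_or <- (mean(g[cohort$D == 1]) / (1 - mean(g[cohort$D == 1]))) /
    (mean(g[cohort$D == 0]) / (1 - mean(g[cohort$D == 0])))
  expect_lt(abs(log(emp_or) - log(2)), 3 * sqrt(4 / 2500))
})

test_that("an unattainable prevalence hits the quota-sampling draw cap", {
  spec <- small_spec(n_snps = 3L, q_causal = 1L, q_gxe = 0L,
                     overlap = c(0L, 0L, 0L),
                     n_cases = 200L, n_controls = 200L)
  eff <- effect_config(spec, deltaG = 0, deltaE = 0, delta0 = -20)
  expect_error(simulate_cohort(spec, eff, seed = 1), "draw cap")
})

test_that("pathway truth labels follow the scenario overlap layout", {
  spec <- make_scenario(6)  # 4 GxE + 1 null SNP in the pathway
  eff <- effect_config(spec, deltaG = 0.2, deltaGxE = 0.1)
  spec_small <- small_spec(n_snps = 30L, q_causal = 6L, q_gxe = 3L,
                           overlap = c(2L, 0L, 1L),
                           n_cases = 100L, n_controls = 100L)
  ch <- simulate_cohort(spec_small, effect_config(spec_small, deltaG = 0.2,
                                                  deltaGxE = 0.1), seed = 3)
  truth <- cohort_truth(ch)
  expect_setequal(truth$snp_id[truth$in_pathway],
                  c("snp_0001", "snp_0002", "snp_0007"))
  expect_equal(pathway_snp_ids(spec_small),
               c("snp_0001", "snp_0002", "snp_0007"))
  expect_equal(length(pathway_snp_ids(spec)), 5L)
})
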