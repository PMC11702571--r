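test_that("centering leaves the interaction estimate and test unchanged", {
  set.seed(301)
  dat <- sim_gxe_data(4000, bge = 0.2)
  f_c <- fit_interaction(dat, "score", "E", center = TRUE)
  f_u <- fit_interaction(dat, "score", "E", center = FALSE)
  expect_equal(f_c$coefficients[["score:exposure"]],
               f_u$coefficients[["score:exposure"]], tolerance = 1e-8)
  expect_equal(f_c$p_lrt, f_u$p_lrt, tolerance = 1e-8)
  expect_equal(f_c$p_wald, f_u$p_wald, tolerance = 1e-8)
})

test_that("affine rescaling of the score rescales the estimate, not the p-value", {
  set.seed(302)
  dat <- sim_gxe_data(4000, bge = 0.2)
  dat2 <- dplyr::mutate(dat, score = 3.5 * score + 2)
  f1 <- fit_interaction(dat, "score", "E")
  f2 <- fit_interaction(dat2, "score", "E")
  expect_equal(f2$coefficients[["score:exposure"]],
               f1$coefficients[["score:exposure"]] / 3.5, tolerance = 1e-6)
  expect_equal(f2$p_lrt, f1$p_lrt, tolerance = 1e-6)
})

test_that("the interaction LRT holds its size under the null", {
  set.seed(303)
  rej <- vapply(1:300, function(i) {
    dat <- sim_gxe_data(600, bge = 0)
    fit_interaction(dat, "score", "E")$p_lrt < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("the interaction coefficient is recovered with nominal coverage", {
  set.seed(304)
  bge <- 0.25
  hits <- vapply(1:300, function(i) {
    dat <- sim_gxe_data(1500, bge = bge)
    td <- tidy(fit_interaction(dat, "score", "E"))
    row <- td[td$term == "score:exposure", ]
    row$conf.low <= exp(bge) && exp(bge) <= row$conf.high
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("LRT and Wald p-values agree at large n", {
  set.seed(305)
  dat <- sim_gxe_data(10000, bge = 0.12)
  fit <- fit_interaction(dat, "score", "E")
  expect_lt(abs(fit$p_lrt - fit$p_wald) / fit$p_lrt, 0.20)
})

test_that("the reported log-likelihood matches a direct evaluation", {
  set.seed(306)
  dat <- sim_gxe_data(2000, bge = 0.2)
  fit <- fit_interaction(dat, "score", "E", center = FALSE)
  co <- fit$coefficients
  eta <- co[1] + co["score"] * dat$score + co["exposure"] * dat$E +
    co["score:exposure"] * dat$score * dat$E
  ll <- sum(dat$D * eta - log1p(exp(eta)))
  expect_equal(fit$logLik, ll, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with diagnostics", {
  set.seed(307)
  dat <- sim_gxe_data(200)
  dat$E <- 1
  expect_error(fit_interaction(dat, "score", "E"), "degenerate")
  dat2 <- sim_gxe_data(200)
  dat2$D[dat2$E == 1] <- 1
  expect_error(fit_interaction(dat2, "score", "E"), "at least one case")
})

test_that("the joint pathway-score model nests the single-score fit", {
  set.seed(308)
  dat <- sim_gxe_data(3000, bge = 0.15)
  single <- fit_interaction(dat, "score", "E")
  joint <- fit_joint_pprs(dat, pprs_cols = "score", exposure = "E")
  expect_equal(joint$coefficients[["score:exposure"]],
               single$coefficients[["score:exposure"]], tolerance = 1e-7)
  expect_equal(joint$p_lrt, single$p_lrt, tolerance = 1e-6)
  expect_error(fit_joint_pprs(dat, c("score", "score"), "E"), "Duplicated")
  dat$score2 <- dat$score
  expect_error(fit_joint_pprs(dat, c("score", "score2"), "E"),
               "rank deficient|collinear")
})

test_that("the joint model localises the interacting score", {
  set.seed(309)
  n_rej_active <- 0; n_rej_nuisance <- 0
  n_reps <- 60
  for (i in seq_len(n_reps)) {
    n <- 2500
    s1 <- rnorm(n); s0 <- rnorm(n); e <- rbinom(n, 1, 0.5)
    d <- rbinom(n, 1, plogis(-0.4 + 0.2 * s1 + 0.1 * s0 + 0.2 * e + 0.35 * s1 * e))
    dat <- tibble::tibble(D = d, pw = s1, np = s0, E = e)
    fit <- fit_joint_pprs(dat, c("pw", "np"), "E")
    n_rej_active <- n_rej_active + (fit$p_wald[["pw:exposure"]] < 0.05)
    n_rej_nuisance <- n_rej_nuisance + (fit$p_wald[["np:exposure"]] < 0.05)
  }
  expect_gt(n_rej_active / n_reps, 0.5)
  expect_lt(n_rej_nuisance / n_reps, 0.05 + 3 * sqrt(0.05 * 0.95 / n_reps))
})

test_that("the exposure OR profile matches its closed form", {
  prof <- exposure_or_profile(beta_e = log(0.76), beta_ge = log(0.94),
                              percentiles = c(0.05, 0.5, 0.95))
  expect_equal(round(prof$or[1], 2), 0.84)
  expect_equal(prof$or[2], 0.76, tolerance = 1e-12)
  expect_true(all(diff(prof$or) < 0))                   # protective interaction
  flat <- exposure_or_profile(beta_e = log(0.8), beta_ge = 0,
                              percentiles = c(0.1, 0.5, 0.9))
  expect_equal(flat$or, rep(0.8, 3), tolerance = 1e-12)
  expect_error(exposure_or_profile(beta_e = 0, beta_ge = 0, percentiles = 1.2),
               "inside")
})

test_that("profiles from a fitted model use its covariance for the CI", {
  set.seed(310)
  dat <- sim_gxe_data(6000, bge = -0.15)
  fit <- fit_interaction(dat, "score", "E")
  prof <- exposure_or_profile(fit, percentiles = 0.05)
  s <- qnorm(0.05)
  be <- fit$coefficients[["exposure"]]
  bge <- fit$coefficients[["score:exposure"]]
  v <- fit$cov["exposure", "exposure"] + s^2 * fit$cov["score:exposure", "score:exposure"] +
    2 * s * fit$cov["exposure", "score:exposure"]
  expect_equal(prof$or, exp(be + bge * s), tolerance = 1e-10)
  expect_equal(prof$conf.high, exp(be + bge * s + 1.96 * sqrt(v)), tolerance = 1e-3)
  # empirical-quantile evaluation uses the supplied score distribution
  prof_emp <- exposure_or_profile(fit, percentiles = 0.25, scores = dat$score)
  expect_equal(prof_emp$score_value, unname(quantile(dat$score, 0.25)),
               tolerance = 1e-12)
})

test_that("confounder-level interactions can be added to the model", {
  set.seed(311)
  dat <- sim_gxe_data(2000, bge = 0.2)
  dat$z <- rnorm(2000) + 0.3 * dat$E
  fit <- fit_interaction(dat, "score", "E", covariates = "z",
                         extra_confounder_interactions = TRUE)
  expect_true(all(c("z", "score:z", "exposure:z", "score:exposure") %in% fit$terms))
  # the interaction of interest is still a 1-df LRT
  expect_equal(fit$lrt_df, 1L)
  plain <- fit_interaction(dat, "score", "E", covariates = "z")
  expect_false("score:z" %in% plain$terms)
})
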