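#' Analytic power of the per-SNP marginal association test
#'
#' Computes the asymptotic power of the two-sided Wald test of a single
#' binary SNP's marginal log odds ratio in a case-control sample, using
#' expected cell counts under the generative disease model. The intercept
#' of the single-SNP population model is solved so that the population
#' disease prevalence matches `spec$prevalence`; the case-control genotype
#' frequencies then follow from Bayes' rule and the test's noncentrality is
#' `delta^2` over the expected-information variance of the 2x2 log odds
#' ratio.
#'
#' @param delta Marginal log odds ratio of the SNP.
#' @param alpha Two-sided significance level of the test.
#' @param spec A [scenario_spec()]; supplies case/control quotas, the SNP
#'   frequency and the target prevalence.
#' @return Power as a probability.
#' @export
power_main_effect <- function(delta, alpha, spec) {
  check_prob(alpha, "alpha")
  f <- spec$g_freq
  b0 <- uniroot(function(b) {
    (1 - f) * expit(b) + f * expit(b + delta) - spec$prevalence
  }, c(-30, 30), tol = 1e-12)$root
  pd <- c(expit(b0), expit(b0 + delta))          # P(D=1 | G = 0, 1)
  pg <- c(1 - f, f)
  prev <- sum(pg * pd)
  p1 <- pg[2] * pd[2] / prev                     # P(G=1 | case)
  p0 <- pg[2] * (1 - pd[2]) / (1 - prev)         # P(G=1 | control)
  v <- 1 / (spec$n_cases * p1) + 1 / (spec$n_cases * (1 - p1)) +
    1 / (spec$n_controls * p0) + 1 / (spec$n_controls * (1 - p0))
  ncp <- delta^2 / v
  pchisq(qchisq(1 - alpha, 1), df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Analytic power of the single-SNP gene-environment interaction test
#'
#' Power of the two-sided Wald test of the interaction log odds ratio in
#' the saturated logistic model of disease on a binary SNP, a binary
#' exposure and their product, fitted to a case-control sample. Expected
#' counts in the eight genotype-by-exposure-by-disease cells are derived
#' from the generative model with the intercept solved for the target
#' prevalence.
#'
#' @param delta_gxe Interaction log odds ratio.
#' @param alpha Significance level.
#' @param spec A [scenario_spec()].
#' @param deltaG Main-effect log odds ratio of the SNP.
#' @param deltaE Main-effect log odds ratio of the exposure.
#' @param sided `"one"` for directional power (rejection in the direction
#'   of the simulated interaction), `"two"` for two-sided. Sidedness
#'   matters greatly for detection targets far below 50% power: the
#'   directional convention is the package default because it reproduces
#'   the reference simulation design (see the methods vignette).
#' @return Power as a probability.
#' @export
power_gxe_effect <- function(delta_gxe, alpha, spec, deltaG, deltaE = log(1.5),
                             sided = c("one", "two")) {
  sided <- match.arg(sided)
  check_prob(alpha, "alpha")
  f <- spec$g_freq; pe <- spec$e_prev
  cells <- expand.grid(g = 0:1, e = 0:1)
  pge <- (f^cells$g * (1 - f)^(1 - cells$g)) * (pe^cells$e * (1 - pe)^(1 - cells$e))
  lp_slope <- deltaE * cells$e + deltaG * cells$g + delta_gxe * cells$g * cells$e
  b0 <- uniroot(function(b) sum(pge * expit(b + lp_slope)) - spec$prevalence,
                c(-30, 30), tol = 1e-12)$root
  pd <- expit(b0 + lp_slope)
  prev <- sum(pge * pd)
  p_case <- pge * pd / prev
  p_ctrl <- pge * (1 - pd) / (1 - prev)
  v <- sum(1 / (spec$n_cases * p_case)) + sum(1 / (spec$n_controls * p_ctrl))
  if (sided == "two") {
    pchisq(qchisq(1 - alpha, 1), df = 1, ncp = delta_gxe^2 / v, lower.tail = FALSE)
  } else {
    pnorm(abs(delta_gxe) / sqrt(v) - qnorm(1 - alpha))
  }
}

solve_effect <- function(power_fn, alpha, power_target, upper = 10) {
  check_prob(alpha, "alpha")
  check_prob(power_target, "power_target")
  if (power_target < alpha) {
    abort("`power_target` must be at least `alpha` (the power of the null test).")
  }
  if (power_target == alpha) return(0)
  f <- function(d) power_fn(d) - power_target
  if (f(upper) < 0) {
    abort(sprintf("Effect-size calibration did not bracket the target in [0, %g].", upper))
  }
  uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Calibrate the per-SNP main effect to a target marginal power
#'
#' Solves for the main-effect log odds ratio at which the per-SNP marginal
#' association test attains a stated power. This plays the role of an
#' external sample-size/power calculator: the returned value is used as
#' the generative `deltaG` for every causal SNP. The solution is found by
#' root-finding on the analytic noncentrality of [power_main_effect()] and
#' is strictly monotone in `power_target`.
#'
#' @param alpha Per-SNP two-sided significance level (e.g. `0.05 / 1000`
#'   for a Bonferroni-corrected scan of 1,000 SNPs).
#' @param power_target Desired power.
#' @param spec A [scenario_spec()].
#' @return The calibrated log odds ratio (non-negative).
#' @export
#' @examples
#' spec <- scenario_spec()
#' exp(calibrate_main_effect(0.05 / 1000, 0.90, spec)) # per-SNP odds ratio
calibrate_main_effect <- function(alpha, power_target, spec) {
  solve_effect(function(d) power_main_effect(d, alpha, spec), alpha, power_target)
}

#' Calibrate the per-SNP interaction effect to a target interaction power
#'
#' Solves for the interaction log odds ratio at which the single-SNP
#' gene-environment interaction test attains a stated power, holding the
#' SNP's main effect and the exposure effect fixed. In the reference
#' design the interaction SNPs are calibrated to roughly 10% power at
#' `alpha = 0.05 / 20`, i.e. Bonferroni-adjusted for interaction testing
#' of 20 GWAS-discovered SNPs.
#'
#' @inheritParams calibrate_main_effect
#' @inheritParams power_gxe_effect
#' @param deltaG Main-effect log odds ratio of the SNP; defaults to the
#'   main effect calibrated to 90% marginal power at `0.05 / n_snps`.
#' @param deltaE Exposure log odds ratio.
#' @return The calibrated interaction log odds ratio (non-negative).
#' @export
calibrate_gxe_effect <- function(alpha, power_target, spec,
                                 deltaE = log(1.5),
                                 deltaG = calibrate_main_effect(0.05 / spec$n_snps, 0.90, spec),
                                 sided = c("one", "two")) {
  sided <- match.arg(sided)
  solve_effect(function(d) power_gxe_effect(d, alpha, spec, deltaG, deltaE, sided),
               alpha, power_target)
}

#' Marginal (collapsed over E) log odds ratio of an interaction SNP
#'
#' For a SNP with main effect `deltaG` and interaction `delta_gxe` under a
#' binary exposure, the exposure-collapsed case-control log odds ratio —
#' the quantity a GWAS scan detects — exceeds `deltaG`. Computed exactly
#' from the four genotype-by-exposure cells of the population model with
#' the intercept solved for the target prevalence.
#'
#' @inheritParams power_gxe_effect
#' @return The marginal log odds ratio.
#' @export
marginal_logor_gxe <- function(deltaG, delta_gxe, spec, deltaE = log(1.5)) {
  f <- spec$g_freq; pe <- spec$e_prev
  cells <- expand.grid(g = 0:1, e = 0:1)
  pge <- (f^cells$g * (1 - f)^(1 - cells$g)) * (pe^cells$e * (1 - pe)^(1 - cells$e))
  lp_slope <- deltaE * cells$e + deltaG * cells$g + delta_gxe * cells$g * cells$e
  b0 <- uniroot(function(b) sum(pge * expit(b + lp_slope)) - spec$prevalence,
                c(-30, 30), tol = 1e-12)$root
  pd <- expit(b0 + lp_slope)
  prev <- sum(pge * pd)
  p1 <- sum(pge * pd * cells$g) / prev
  p0 <- sum(pge * (1 - pd) * cells$g) / (1 - prev)
  qlogis(p1) - qlogis(p0)
}

#' Build the calibrated effect configuration for the reference design
#'
#' Convenience wrapper producing the [effect_config()] used throughout the
#' power study: every causal SNP gets the main effect calibrated to
#' `power_main` at `alpha_main`, and every interaction SNP additionally
#' gets the interaction effect calibrated to `power_gxe` at `alpha_gxe`.
#'
#' The `gxe_main_effect` argument settles how interaction SNPs are made
#' detectable. With the default `"shared"`, interaction SNPs carry the
#' same main-effect coefficient as main-effect-only SNPs, and their
#' interaction raises their exposure-collapsed marginal effect — they are
#' then somewhat easier to discover than the nominal target. The
#' `"marginal"` alternative instead shrinks their main effect until every
#' causal SNP's marginal (detectable) effect meets the same target,
#' iterating the interaction and main-effect solutions to a joint fixed
#' point; see the methods vignette for the trade-off.
#'
#' @param spec A [scenario_spec()].
#' @param alpha_main,power_main Level and target for the marginal test;
#'   defaults `0.05 / n_snps` and 0.90.
#' @param alpha_gxe,power_gxe Level and target for the interaction test;
#'   defaults `0.05 / 20` and 0.10.
#' @param sided_gxe Sidedness convention of the interaction calibration
#'   (see [power_gxe_effect()]).
#' @param gxe_main_effect `"shared"` (default) gives interaction SNPs the
#'   same main-effect coefficient as main-effect-only SNPs; `"marginal"`
#'   equalises the marginal detectable effect of all causal SNPs.
#' @param deltaE Exposure log odds ratio.
#' @return An [effect_config()].
#' @export
calibrated_effects <- function(spec,
                               alpha_main = 0.05 / spec$n_snps, power_main = 0.90,
                               alpha_gxe = 0.05 / 20, power_gxe = 0.10,
                               deltaE = log(1.5), sided_gxe = c("one", "two"),
                               gxe_main_effect = c("shared", "marginal")) {
  sided_gxe <- match.arg(sided_gxe)
  gxe_main_effect <- match.arg(gxe_main_effect)
  dG_target <- calibrate_main_effect(alpha_main, power_main, spec)
  if (spec$q_gxe == 0) {
    return(effect_config(spec, deltaG = dG_target, deltaGxE = numeric(0),
                         deltaE = deltaE))
  }
  dG_gxe <- dG_target
  dGxE <- calibrate_gxe_effect(alpha_gxe, power_gxe, spec, deltaE = deltaE,
                               deltaG = dG_gxe, sided = sided_gxe)
  if (gxe_main_effect == "marginal") {
    # fixed point: the interaction boosts the marginal effect, so shrink
    # the interaction SNPs' main effect until their marginal effect
    # matches the common detection target, re-solving the interaction at
    # the updated main effect
    for (it in 1:4) {
      dG_gxe <- uniroot(function(d) {
        marginal_logor_gxe(d, dGxE, spec, deltaE) - dG_target
      }, c(-1, dG_target + 1), tol = 1e-10)$root
      dGxE_new <- calibrate_gxe_effect(alpha_gxe, power_gxe, spec,
                                       deltaE = deltaE, deltaG = dG_gxe,
                                       sided = sided_gxe)
      if (abs(dGxE_new - dGxE) < 1e-10) { dGxE <- dGxE_new; break }
      dGxE <- dGxE_new
    }
  }
  deltaG <- rep(dG_target, spec$q_causal)
  deltaG[seq_len(spec$q_gxe)] <- dG_gxe
  effect_config(spec, deltaG = deltaG, deltaGxE = dGxE, deltaE = deltaE)
}

#' Monte-Carlo verification of a calibrated effect size
#'
#' Simulates single-SNP case-control cohorts at the supplied effect sizes
#' and reports the empirical rejection rate of the corresponding test,
#' providing an independent check on the analytic calibration.
#'
#' @param spec A [scenario_spec()] (only sample sizes, `g_freq`, `e_prev`
#'   and `prevalence` are used).
#' @param deltaG Main-effect log odds ratio.
#' @param deltaGxE Interaction log odds ratio (used when `type = "gxe"`).
#' @param type `"main"` tests the marginal SNP effect; `"gxe"` tests the
#'   SNP-by-exposure interaction.
#' @param alpha Test level.
#' @param n_reps Number of simulated cohorts.
#' @param seed Master seed.
#' @param deltaE Exposure log odds ratio.
#' @param sided Rejection convention for the interaction test, matching
#'   the calibration being verified: `"one"` counts directional Wald
#'   rejections, `"two"` likelihood-ratio rejections. The marginal test
#'   is always two-sided.
#' @return A tibble with the rejection proportion and its binomial SE.
#' @export
verify_power <- function(spec, deltaG, deltaGxE = 0,
                         type = c("main", "gxe"),
                         alpha, n_reps = 1000L, seed = 1L,
                         deltaE = log(1.5), sided = c("one", "two")) {
  type <- match.arg(type)
  sided <- match.arg(sided)
  spec1 <- scenario_spec(
    n_snps = 1L, q_causal = 1L, q_gxe = if (type == "gxe") 1L else 0L,
    q_pathway = 0L, pathway_overlap_gxe = 0L, pathway_overlap_gonly = 0L,
    pathway_overlap_null = 0L,
    n_cases = spec$n_cases, n_controls = spec$n_controls,
    g_freq = spec$g_freq, e_prev = spec$e_prev, prevalence = spec$prevalence
  )
  eff <- effect_config(spec1, deltaG = deltaG,
                       deltaGxE = if (type == "gxe") deltaGxE else numeric(0),
                       deltaE = deltaE)
  reject <- vapply(seq_len(n_reps), function(i) {
    ch <- simulate_cohort(spec1, eff, seed = substream_seed(seed, i))
    if (type == "main") {
      marginal_scan(ch)$p.value[1] < alpha
    } else {
      fit <- fit_interaction(ch, score = "snp_0001", exposure = "E")
      if (sided == "one") {
        tm <- fit$interaction_terms
        z <- fit$coefficients[[tm]] / sqrt(fit$cov[tm, tm])
        sign(deltaGxE) * z > qnorm(1 - alpha)
      } else {
        fit$p_lrt < alpha
      }
    }
  }, logical(1))
  p <- mean(reject)
  tibble(type = type, n_reps = n_reps, rejection_rate = p,
         se = sqrt(p * (1 - p) / n_reps))
}
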