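#' Per-SNP marginal disease association scan
#'
#' Tests each SNP's marginal association with disease using the efficient
#' score test against the covariate-only null model (logistic regression
#' of disease on the intercept and any adjustment covariates). A single
#' null fit serves all SNPs, so the scan is a handful of matrix products
#' and scales to thousands of SNPs per replicate; at case-control sample
#' sizes in the thousands the score test is asymptotically equivalent to
#' the per-SNP Wald or likelihood-ratio test.
#'
#' The reported `estimate` is the one-step score/information update from
#' the null (a consistent approximation to the per-SNP log odds ratio);
#' [snp_assoc_refit()] provides the exact maximum-likelihood refit for
#' individual SNPs.
#'
#' @param cohort A cohort tibble with columns `D` and `E`, SNP columns,
#'   and optionally covariate columns.
#' @param covariates Character vector of covariate column names to adjust
#'   for (the scan model never includes the exposure).
#' @return A tibble with one row per SNP: `snp_id`, `estimate`, `se`,
#'   `statistic` (1-df chi-square), `p.value`, and `monomorphic`.
#'   Monomorphic SNPs get `p.value = 1` and an `NA` estimate.
#' @export
marginal_scan <- function(cohort, covariates = character(0)) {
  d <- cohort$D
  if (is.null(d)) abort("`cohort` must contain a disease column `D`.")
  if (sum(d == 1) < 2 || sum(d == 0) < 2) {
    abort("The scan needs at least 2 cases and 2 controls.")
  }
  meta <- c("id", "D", "E", covariates)
  G <- cohort_genotypes(cohort, meta_cols = meta)
  Z <- cbind(`(Intercept)` = rep(1, length(d)))
  if (length(covariates)) {
    Z <- cbind(Z, as.matrix(as.data.frame(cohort)[covariates]))
  }
  if (length(covariates) == 0L) {
    # intercept-only null: the null fit is the case fraction and the
    # information weight is a scalar, so the scan is two column sums
    mu <- mean(d)
    w <- mu * (1 - mu)
    U <- drop(crossprod(G, d - mu))
    S1 <- colSums(G)
    rng <- range(G)
    S2 <- if (is.integer(G) && rng[1] >= 0 && rng[2] <= 1) S1 else colSums(G * G)
    V <- w * (S2 - S1^2 / length(d))
  } else {
    null_fit <- glm.fit(Z, d, family = binomial())
    mu <- null_fit$fitted.values
    w <- mu * (1 - mu)
    U <- drop(crossprod(G, d - mu))
    GW_Z <- crossprod(G * w, Z)                     # S x p
    ZWZ_inv <- solve(crossprod(Z * w, Z))
    V <- colSums(w * G^2) - rowSums((GW_Z %*% ZWZ_inv) * GW_Z)
  }

  mono <- V <= 1e-12 | !is.finite(V)
  stat <- ifelse(mono, 0, U^2 / V)
  p <- ifelse(mono, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  est <- ifelse(mono, NA_real_, U / V)
  se <- ifelse(mono, NA_real_, 1 / sqrt(V))

  tibble(snp_id = colnames(G), estimate = unname(est), se = unname(se),
         statistic = unname(stat), p.value = unname(p),
         monomorphic = unname(mono))
}

#' Exact per-SNP logistic refit
#'
#' Maximum-likelihood logistic regression of disease on a single SNP plus
#' covariates, with Wald estimate/SE and the likelihood-ratio p-value
#' against the covariate-only null.
#'
#' @inheritParams marginal_scan
#' @param snp_id Name of the SNP column to refit.
#' @return A one-row tibble: `snp_id`, `estimate`, `se`, `statistic`
#'   (LRT), `p.value`.
#' @export
snp_assoc_refit <- function(cohort, snp_id, covariates = character(0)) {
  d <- cohort$D
  x <- as.data.frame(cohort)[[snp_id]]
  if (is.null(x)) abort(sprintf("SNP `%s` not found in the cohort.", snp_id))
  Z <- matrix(1, length(d), 1L)
  if (length(covariates)) Z <- cbind(Z, as.matrix(as.data.frame(cohort)[covariates]))
  full <- glm.fit(cbind(Z, x), d, family = binomial())
  null <- glm.fit(Z, d, family = binomial())
  lrt <- max(null$deviance - full$deviance, 0)
  k <- ncol(Z) + 1L
  se <- sqrt(diag(chol2inv(chol(crossprod(
    cbind(Z, x) * sqrt(full$weights))))))[k]
  tibble(snp_id = snp_id, estimate = unname(full$coefficients[k]),
         se = unname(se), statistic = lrt,
         p.value = pchisq(lrt, 1, lower.tail = FALSE))
}

#' Bonferroni discovery of scan hits
#'
#' Returns the SNPs whose scan p-value falls below `alpha_total / n_tests`
#' — by default 0.05 over the declared panel size, i.e. the conventional
#' `5e-5` threshold for a 1,000-SNP panel.
#'
#' @param scan A tibble from [marginal_scan()].
#' @param alpha_total Family-wise significance level.
#' @param n_tests Bonferroni denominator; defaults to the number of
#'   scanned SNPs.
#' @return Character vector of discovered SNP ids, in scan order.
#' @export
discover_snps <- function(scan, alpha_total = 0.05, n_tests = nrow(scan)) {
  check_prob(alpha_total, "alpha_total")
  n_tests <- check_count(n_tests, "n_tests", 1L)
  scan$snp_id[scan$p.value < alpha_total / n_tests]
}
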