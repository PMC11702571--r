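#' Fit the logistic score-by-exposure interaction model
#'
#' Maximum-likelihood logistic regression of disease on a risk score G, an
#' exposure E, their product and optional covariates:
#' `logit P(D=1) = b0 + bg*G + be*E + bge*G:E + bz*Z`. The interaction null
#' `H0: bge = 0` is tested by the likelihood-ratio test against the
#' no-interaction nested model (the package default); the Wald test is
#' reported alongside and backs the confidence intervals.
#'
#' When `center = TRUE` (default) the score and exposure are mean-centered
#' before the product is formed, so the main-effect coefficients read as
#' effects at the sample mean of the other variable (approximately the
#' marginal effects). Centering is a reparameterisation: the interaction
#' estimate, its SE and both p-values are unchanged.
#'
#' @param data A data frame holding all model columns.
#' @param score,exposure,response Column names of the risk score, the
#'   exposure, and the binary disease indicator.
#' @param covariates Covariate column names (entered linearly).
#' @param center Mean-center score and exposure before forming the
#'   product.
#' @param extra_confounder_interactions Also include score-by-covariate
#'   and exposure-by-covariate products, guarding the interaction of
#'   interest against confounding at the interaction level.
#' @return An object of class `gxe_fit`; see [tidy.gxe_fit()] and
#'   [glance.gxe_fit()].
#' @export
#' @examples
#' spec <- scenario_spec(n_snps = 10, q_causal = 2, q_gxe = 1, q_pathway = 1,
#'                       pathway_overlap_gxe = 1, n_cases = 300, n_controls = 300)
#' ch <- simulate_cohort(spec, effect_config(spec, deltaG = 0.4, deltaGxE = 0.3),
#'                       seed = 3)
#' w <- estimate_weights(ch, c("snp_0001", "snp_0002"))
#' sc <- compute_scores(ch, w)
#' fit <- fit_interaction(dplyr::bind_cols(sc, ch[c("D", "E")]),
#'                        score = "prs", exposure = "E")
#' tidy(fit)
fit_interaction <- function(data, score, exposure, response = "D",
                            covariates = character(0), center = TRUE,
                            extra_confounder_interactions = FALSE) {
  d <- data[[response]]
  g <- as.double(data[[score]])
  e <- as.double(data[[exposure]])
  if (is.null(d) || is.null(g) || is.null(e)) {
    abort("`response`, `score` and `exposure` must name columns of `data`.")
  }
  keep <- stats::complete.cases(d, g, e)
  Z <- if (length(covariates)) as.matrix(as.data.frame(data)[covariates]) else NULL
  if (!is.null(Z)) keep <- keep & stats::complete.cases(Z)
  d <- d[keep]; g <- g[keep]; e <- e[keep]
  if (!is.null(Z)) Z <- Z[keep, , drop = FALSE]
  n <- length(d)
  if (length(unique(e)) < 2L) abort("The exposure is degenerate (constant).")
  if (all(e %in% c(0, 1)) &&
      (min(tapply(d, e, function(x) sum(x == 1))) < 1 ||
       min(tapply(d, e, function(x) sum(x == 0))) < 1)) {
    abort("Each exposure level needs at least one case and one control.")
  }
  centering <- c(score_mean = if (center) mean(g) else 0,
                 exposure_mean = if (center) mean(e) else 0)
  gc_ <- g - centering[["score_mean"]]
  ec_ <- e - centering[["exposure_mean"]]

  X_red <- cbind(`(Intercept)` = 1, score = gc_, exposure = ec_)
  if (!is.null(Z)) X_red <- cbind(X_red, Z)
  if (extra_confounder_interactions && !is.null(Z)) {
    gz <- Z * gc_; colnames(gz) <- paste0("score:", colnames(Z))
    ez <- Z * ec_; colnames(ez) <- paste0("exposure:", colnames(Z))
    X_red <- cbind(X_red, gz, ez)
  }
  X_full <- cbind(X_red, `score:exposure` = gc_ * ec_)

  full <- fit_logistic_checked(X_full, d, "interaction model")
  red <- fit_logistic_checked(X_red, d, "no-interaction model")

  lrt <- max(red$deviance - full$deviance, 0)
  p_lrt <- pchisq(lrt, 1, lower.tail = FALSE)
  k <- ncol(X_full)
  wald_z <- full$coefficients[k] / sqrt(full$cov[k, k])
  structure(
    list(coefficients = full$coefficients, cov = full$cov,
         terms = colnames(X_full),
         lrt_stat = lrt, lrt_df = 1L, p_lrt = p_lrt,
         p_wald = 2 * pnorm(-abs(wald_z)),
         centering = centering, n_used = n,
         deviance = full$deviance, null_deviance = red$deviance,
         logLik = -full$deviance / 2,
         score = score, exposure = exposure,
         interaction_terms = "score:exposure"),
    class = "gxe_fit"
  )
}

fit_logistic_checked <- function(X, y, what) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(sprintf("Design matrix of the %s is rank deficient; collinear term(s): %s",
                  what, paste(dropped, collapse = ", ")))
  }
  # Newton-Raphson IRLS with step halving; equivalent to glm.fit but lean
  # enough for the replicate loops, which fit tens of these per dataset.
  beta <- numeric(ncol(X))
  dev <- -2 * sum(y * log(0.5) + (1 - y) * log(0.5))
  converged <- FALSE
  for (it in seq_len(60L)) {
    mu <- expit(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X * w, X)
    g <- crossprod(X, y - mu)
    step <- tryCatch(drop(solve(H, g)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    halve <- 0L
    repeat {
      beta_new <- beta + step
      mu_new <- expit(drop(X %*% beta_new))
      dev_new <- -2 * sum(y * log(pmax(mu_new, 1e-300)) +
                            (1 - y) * log(pmax(1 - mu_new, 1e-300)))
      if (is.finite(dev_new) && dev_new <= dev + 1e-8) break
      step <- step / 2
      halve <- halve + 1L
      if (halve > 20L) break
    }
    improvement <- dev - dev_new
    beta <- beta_new
    dev <- dev_new
    if (abs(improvement) < 1e-9 * (abs(dev) + 0.1)) { converged <- TRUE; break }
  }
  if (!converged || any(!is.finite(beta))) {
    abort(sprintf("Logistic fit of the %s did not converge (deviance %.3f after %d iterations).",
                  what, dev, it))
  }
  mu <- expit(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  cov <- chol2inv(chol(crossprod(X * sqrt(w))))
  dimnames(cov) <- list(colnames(X), colnames(X))
  list(coefficients = setNames(beta, colnames(X)), cov = cov, deviance = dev)
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf("<gxe_fit> %s x %s interaction (n = %d)\n", x$score, x$exposure, x$n_used))
  int <- x$interaction_terms
  for (tm in int) {
    est <- x$coefficients[tm]
    cat(sprintf("  %s: OR %.3f, LRT p = %.3g (Wald p = %.3g)\n",
                tm, exp(est), x$p_lrt, x$p_wald[[min(which(int == tm), length(x$p_wald))]]))
  }
  invisible(x)
}

#' Tidy a fitted interaction model
#'
#' @param x A `gxe_fit`.
#' @param conf.level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `or`, `conf.low`, `conf.high` (the latter three on the
#'   odds-ratio scale).
#' @export
tidy.gxe_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$cov))
  z <- x$coefficients / se
  q <- qnorm(1 - (1 - conf.level) / 2)
  tibble(term = x$terms, estimate = unname(x$coefficients),
         std.error = unname(se), statistic = unname(z),
         p.value = 2 * pnorm(-abs(unname(z))),
         or = exp(unname(x$coefficients)),
         conf.low = exp(unname(x$coefficients - q * se)),
         conf.high = exp(unname(x$coefficients + q * se)))
}

#' One-row summary of a fitted interaction model
#'
#' @param x A `gxe_fit`.
#' @param ... Unused.
#' @return A tibble with sample size, log-likelihood, deviances, and the
#'   interaction LRT statistic with its p-value.
#' @export
glance.gxe_fit <- function(x, ...) {
  tibble(n = x$n_used, logLik = x$logLik, deviance = x$deviance,
         null_deviance = x$null_deviance,
         lrt_stat = x$lrt_stat, lrt_df = x$lrt_df,
         p_lrt = x$p_lrt, p_wald = x$p_wald[1])
}

#' Joint model over all pathway scores
#'
#' Fits one logistic model containing a main effect and an exposure
#' interaction for every supplied pathway score (conventionally including
#' the non-pathway score as the complement), plus the exposure and
#' covariates. Reports per-score Wald tests and a global likelihood-ratio
#' test of all interaction terms at once.
#'
#' @param data Data frame holding all model columns.
#' @param pprs_cols Character vector of score column names (e.g.
#'   `c("pprs_pw1", "npprs")`).
#' @param exposure,response,covariates As in [fit_interaction()].
#' @param center Mean-center scores and exposure before forming products.
#' @return A `gxe_fit` whose `interaction_terms` cover every score and
#'   whose `lrt_df` equals the number of scores.
#' @export
fit_joint_pprs <- function(data, pprs_cols, exposure, response = "D",
                           covariates = character(0), center = TRUE) {
  if (length(pprs_cols) < 1L) abort("Supply at least one score column.")
  if (anyDuplicated(pprs_cols)) {
    abort(sprintf("Duplicated score column(s): %s",
                  paste(unique(pprs_cols[duplicated(pprs_cols)]), collapse = ", ")))
  }
  d <- data[[response]]
  e <- as.double(data[[exposure]])
  S <- as.matrix(as.data.frame(data)[pprs_cols])
  if (length(unique(e)) < 2L) abort("The exposure is degenerate (constant).")
  if (center) {
    S <- scale(S, scale = FALSE)
    e <- e - mean(e)
  }
  Z <- if (length(covariates)) as.matrix(as.data.frame(data)[covariates]) else NULL
  main <- S; colnames(main) <- pprs_cols
  inter <- S * e; colnames(inter) <- paste0(pprs_cols, ":exposure")
  X_red <- cbind(`(Intercept)` = 1, exposure = e, main)
  if (!is.null(Z)) X_red <- cbind(X_red, Z)
  X_full <- cbind(X_red, inter)

  full <- fit_logistic_checked(X_full, d, "joint pathway-score model")
  red <- fit_logistic_checked(X_red, d, "joint main-effects model")

  lrt <- max(red$deviance - full$deviance, 0)
  idx <- match(colnames(inter), colnames(X_full))
  wald_z <- full$coefficients[idx] / sqrt(diag(full$cov)[idx])
  structure(
    list(coefficients = full$coefficients, cov = full$cov,
         terms = colnames(X_full),
         lrt_stat = lrt, lrt_df = length(pprs_cols),
         p_lrt = pchisq(lrt, length(pprs_cols), lower.tail = FALSE),
         p_wald = setNames(2 * pnorm(-abs(wald_z)), colnames(inter)),
         centering = c(score_mean = NA_real_, exposure_mean = if (center) mean(data[[exposure]]) else 0),
         n_used = length(d),
         deviance = full$deviance, null_deviance = red$deviance,
         logLik = -full$deviance / 2,
         score = paste(pprs_cols, collapse = "+"), exposure = exposure,
         interaction_terms = colnames(inter)),
    class = "gxe_fit"
  )
}

#' Exposure odds ratio across percentiles of a risk score
#'
#' Under the interaction model the exposure odds ratio at score value `s`
#' is `OR_E(s) = exp(beta_e + beta_ge * s)`. This evaluates the profile at
#' chosen percentiles of the score distribution — empirical quantiles when
#' scores are supplied, standard-normal quantiles otherwise (appropriate
#' for a standardized score) — with delta-method confidence intervals
#' `Var = Var(beta_e) + s^2 Var(beta_ge) + 2 s Cov`.
#'
#' Coefficients are taken from a fitted `gxe_fit`, or can be supplied
#' directly via `beta_e` / `beta_ge` (e.g. reported odds ratios on the log
#' scale) for closed-form profiling without the underlying data.
#'
#' @param fit A `gxe_fit`, or `NULL` when supplying coefficients.
#' @param percentiles Percentiles in (0, 1).
#' @param scores Optional numeric vector of subject-level scores; its
#'   empirical quantiles define the evaluation points.
#' @param beta_e,beta_ge Exposure and interaction log odds ratios
#'   (overriding `fit`).
#' @param vcov_ee,vcov_gege,vcov_ege Variance of `beta_e`, variance of
#'   `beta_ge`, and their covariance; `NA` intervals are returned when
#'   unavailable.
#' @param conf.level Confidence level.
#' @return A tibble of class `or_profile`: `percentile`, `score_value`,
#'   `or`, `conf.low`, `conf.high`.
#' @export
#' @examples
#' # profile implied by a protective exposure OR 0.76 and interaction OR
#' # 0.94 per SD of a standardized score
#' exposure_or_profile(beta_e = log(0.76), beta_ge = log(0.94),
#'                     percentiles = c(0.05, 0.5, 0.95))
exposure_or_profile <- function(fit = NULL,
                                percentiles = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                scores = NULL,
                                beta_e = NULL, beta_ge = NULL,
                                vcov_ee = NA_real_, vcov_gege = NA_real_,
                                vcov_ege = NA_real_,
                                conf.level = 0.95) {
  if (any(percentiles <= 0 | percentiles >= 1)) {
    abort("`percentiles` must lie strictly inside (0, 1).")
  }
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "gxe_fit"))
    if (length(fit$interaction_terms) != 1L) {
      abort("Profiling expects a single-score fit; use the per-pathway model.")
    }
    beta_e <- fit$coefficients[["exposure"]]
    beta_ge <- fit$coefficients[[fit$interaction_terms]]
    vcov_ee <- fit$cov["exposure", "exposure"]
    vcov_gege <- fit$cov[fit$interaction_terms, fit$interaction_terms]
    vcov_ege <- fit$cov["exposure", fit$interaction_terms]
  }
  if (is.null(beta_e) || is.null(beta_ge)) {
    abort("Supply either `fit` or both `beta_e` and `beta_ge`.")
  }
  s <- if (!is.null(scores)) {
    unname(quantile(scores, percentiles, type = 7))
  } else {
    qnorm(percentiles)
  }
  lp <- beta_e + beta_ge * s
  v <- vcov_ee + s^2 * vcov_gege + 2 * s * vcov_ege
  q <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble(percentile = percentiles, score_value = s,
                or = exp(lp),
                conf.low = exp(lp - q * sqrt(v)),
                conf.high = exp(lp + q * sqrt(v)))
  class(out) <- c("or_profile", class(out))
  out
}
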