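#' Estimate PRS weights from a single joint logistic model
#'
#' Fits one logistic regression of disease on all selected SNPs jointly
#' (plus optional covariates) and takes the fitted per-SNP coefficients as
#' the PRS weights. Mutual adjustment is the point: each weight is the
#' SNP's log odds ratio conditional on the other selected SNPs, and the
#' same weights are reused unchanged for every pathway-restricted score.
#'
#' Weights estimated on the analysis sample itself do not give valid PRS
#' *main-effect* inference on that sample, but remain valid for PRS-by-
#' exposure interaction testing because marginal SNP effects and
#' interaction effects are asymptotically independent.
#'
#' If the joint fit fails to converge or shows separation (unbounded
#' coefficients), it is refitted with a small ridge penalty and flagged
#' via the `ridged` attribute.
#'
#' @param cohort A cohort tibble with a `D` column and SNP columns.
#' @param snp_ids SNPs to include (M >= 1), all present in `cohort`.
#' @param covariates Covariate column names included in the joint model.
#' @param provenance Label recording how the weight SNPs were chosen:
#'   `"insample_discovered"` (GWAS on this sample), `"insample_fixed_snps"`
#'   (SNP list external, weights in-sample) or `"catalog"`.
#' @return A tibble of class `prs_weights` with columns `snp_id` and
#'   `weight`, plus attributes `provenance` and `ridged`.
#' @export
estimate_weights <- function(cohort, snp_ids, covariates = character(0),
                             provenance = c("insample_discovered",
                                            "insample_fixed_snps",
                                            "catalog")) {
  provenance <- match.arg(provenance)
  if (length(snp_ids) < 1L) abort("At least one SNP is required to estimate weights.")
  missing <- setdiff(snp_ids, names(cohort))
  if (length(missing)) {
    abort(sprintf("SNPs not present in the cohort: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  d <- cohort$D
  G <- as.matrix(as.data.frame(cohort)[snp_ids])
  storage.mode(G) <- "double"
  X <- cbind(1, if (length(covariates)) as.matrix(as.data.frame(cohort)[covariates]), G)
  k_snp <- ncol(X) - length(snp_ids) + seq_along(snp_ids)

  fit <- suppressWarnings(glm.fit(X, d, family = binomial()))
  bad <- !fit$converged || any(!is.finite(fit$coefficients)) ||
    any(abs(fit$coefficients[k_snp]) > 15)
  ridged <- FALSE
  if (bad) {
    co <- ridge_logistic(X, d, lambda = 1e-3)
    if (any(!is.finite(co))) abort("Joint weight model failed even with a ridge penalty.")
    fit$coefficients <- co
    ridged <- TRUE
    warn("Joint weight model showed separation/non-convergence; a small ridge penalty was applied.")
  }
  out <- tibble(snp_id = snp_ids, weight = unname(fit$coefficients[k_snp]))
  attr(out, "provenance") <- provenance
  attr(out, "ridged") <- ridged
  class(out) <- c("prs_weights", class(out))
  out
}

# Newton-iterated logistic regression with an L2 penalty on all slopes
# (intercept unpenalised); used only as a separation fallback.
ridge_logistic <- function(X, y, lambda, max_iter = 50, tol = 1e-9) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda * nrow(X), p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    mu <- expit(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Read a PGS-Catalog-style scoring file
#'
#' Scoring files carry `#`-prefixed header lines followed by a
#' tab-separated table with at least `rsID`, `effect_allele` and
#' `effect_weight` columns. Additional columns are preserved.
#'
#' @param path Path to the scoring file.
#' @return A `prs_weights` tibble (columns `snp_id`, `weight`,
#'   `effect_allele`, plus any extra columns), provenance `"catalog"`.
#' @export
read_pgs_scorefile <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("rsID", "effect_allele", "effect_weight")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(sprintf("Scoring file is missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tbl$rsID)) {
    abort(sprintf("Scoring file contains duplicated rsID(s): %s",
                  paste(unique(tbl$rsID[duplicated(tbl$rsID)]), collapse = ", ")))
  }
  out <- dplyr::rename(tbl, snp_id = "rsID", weight = "effect_weight")
  out$weight <- as.double(out$weight)
  if (any(!is.finite(out$weight))) abort("Scoring file contains non-finite weights.")
  attr(out, "provenance") <- "catalog"
  attr(out, "ridged") <- FALSE
  class(out) <- c("prs_weights", class(out))
  out
}

#' Write a weight set as a PGS-Catalog-style scoring file
#'
#' @param weights A `prs_weights` tibble (an `effect_allele` column is
#'   written as `N` if absent, as simulated SNPs carry no allele labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgs_scorefile <- function(weights, path) {
  tbl <- as_tibble(weights)
  if (!"effect_allele" %in% names(tbl)) tbl$effect_allele <- "N"
  tbl <- dplyr::rename(tbl, rsID = "snp_id", effect_weight = "weight")
  tbl <- dplyr::relocate(tbl, "rsID", "effect_allele", "effect_weight")
  header <- c("### PGS scoring file",
              sprintf("# provenance=%s", attr(weights, "provenance") %||% "unknown"),
              sprintf("# variants_number=%d", nrow(tbl)))
  writeLines(header, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
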