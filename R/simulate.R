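#' Simulate a case-control cohort under the generative disease model
#'
#' Subjects are drawn from the population model — independent binary SNPs
#' with frequency `g_freq`, an independent binary exposure with prevalence
#' `e_prev`, and Bernoulli disease with
#' `P(D=1) = expit(delta0 + deltaE*E + sum_k deltaG_k G_k +
#' sum_k deltaGxE_k G_k E)` — and retained by quota sampling until exactly
#' `n_cases` cases and `n_controls` controls are accumulated (in draw
#' order). Null SNPs do not enter the disease model, so they are generated
#' only for the retained subjects; the joint distribution of the returned
#' cohort is identical to generating all SNPs up front.
#'
#' SNP columns are laid out deterministically: the `q_gxe` interaction
#' SNPs first, then the main-effect-only SNPs, then the null SNPs. Every
#' downstream analysis is invariant to column order, and the `truth`
#' attribute records each SNP's generative role and pathway membership.
#'
#' @param spec A [scenario_spec()].
#' @param effects An [effect_config()]; defaults to [calibrated_effects()]
#'   for `spec`.
#' @param seed Integer seed; identical `(spec, effects, seed)` give a
#'   bit-identical cohort.
#' @return A tibble with columns `id`, `D`, `E` and one integer column per
#'   SNP (`snp_0001`, ...), carrying attributes `truth` (a tibble of
#'   `snp_id`, `role`, `in_pathway`) and `spec`.
#' @export
#' @examples
#' spec <- scenario_spec(n_snps = 50, q_causal = 4, q_gxe = 2,
#'                       q_pathway = 2, pathway_overlap_gxe = 2,
#'                       n_cases = 200, n_controls = 200)
#' cohort <- simulate_cohort(spec, effect_config(spec, deltaG = 0.3), seed = 1)
#' table(cohort$D)
simulate_cohort <- function(spec, effects = calibrated_effects(spec), seed) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(effects, "effect_config"))
  if (length(effects$deltaG) != spec$q_causal ||
      length(effects$deltaGxE) != spec$q_gxe) {
    abort("`effects` is inconsistent with `spec` (deltaG/deltaGxE lengths).")
  }
  seed <- check_count(seed, "seed")
  set.seed(seed)

  n_cases <- spec$n_cases; n_controls <- spec$n_controls
  q <- spec$q_causal
  prev <- spec$prevalence
  expected_draws <- max(n_cases / prev, n_controls / (1 - prev))
  max_draws <- 100 * expected_draws

  got_cases <- 0L; got_controls <- 0L; drawn <- 0
  keep_E <- list(); keep_D <- list(); keep_G <- list()
  gxe_idx <- seq_len(spec$q_gxe)

  while (got_cases < n_cases || got_controls < n_controls) {
    if (drawn > max_draws) {
      abort(sprintf(
        "Quota sampling exceeded the draw cap (%d draws) before filling %d cases / %d controls; the implied prevalence is too extreme.",
        as.integer(max_draws), n_cases, n_controls))
    }
    n_b <- as.integer(ceiling(1.2 * expected_draws *
                                max((n_cases - got_cases) / n_cases,
                                    (n_controls - got_controls) / n_controls,
                                    0.05)))
    drawn <- drawn + n_b
    E <- as.integer(runif(n_b) < spec$e_prev)
    G <- runif(n_b * q) < spec$g_freq
    dim(G) <- c(n_b, q)
    storage.mode(G) <- "integer"
    lp <- effects$delta0 + effects$deltaE * E + drop(G %*% effects$deltaG)
    if (spec$q_gxe > 0) {
      lp <- lp + (G[, gxe_idx, drop = FALSE] %*% effects$deltaGxE) * E
    }
    D <- as.integer(runif(n_b) < expit(drop(lp)))
    want_case <- which(D == 1L)[seq_len(min(sum(D == 1L), n_cases - got_cases))]
    want_ctrl <- which(D == 0L)[seq_len(min(sum(D == 0L), n_controls - got_controls))]
    keep <- sort(c(want_case, want_ctrl))
    if (length(keep)) {
      keep_E[[length(keep_E) + 1L]] <- E[keep]
      keep_D[[length(keep_D) + 1L]] <- D[keep]
      keep_G[[length(keep_G) + 1L]] <- G[keep, , drop = FALSE]
    }
    got_cases <- got_cases + length(want_case)
    got_controls <- got_controls + length(want_ctrl)
  }

  E <- unlist(keep_E); D <- unlist(keep_D)
  G_causal <- do.call(rbind, keep_G)
  n <- length(D)
  n_null <- spec$n_snps - q
  G_null <- if (n_null > 0) {
    g <- runif(n * n_null) < spec$g_freq
    dim(g) <- c(n, n_null)
    storage.mode(g) <- "integer"
    g
  } else {
    matrix(integer(0), n, 0)
  }

  snp_ids <- sprintf("snp_%04d", seq_len(spec$n_snps))
  geno <- cbind(G_causal, G_null)
  colnames(geno) <- snp_ids

  role <- rep("null", spec$n_snps)
  role[seq_len(q)] <- "gonly"
  if (spec$q_gxe > 0) role[gxe_idx] <- "gxe"
  in_pathway <- rep(FALSE, spec$n_snps)
  if (spec$pathway_overlap_gxe > 0) {
    in_pathway[seq_len(spec$pathway_overlap_gxe)] <- TRUE
  }
  if (spec$pathway_overlap_gonly > 0) {
    in_pathway[spec$q_gxe + seq_len(spec$pathway_overlap_gonly)] <- TRUE
  }
  if (spec$pathway_overlap_null > 0) {
    in_pathway[q + seq_len(spec$pathway_overlap_null)] <- TRUE
  }
  truth <- tibble(snp_id = snp_ids, role = role, in_pathway = in_pathway)

  cohort <- tibble(id = seq_len(n), D = D, E = E)
  cohort <- dplyr::bind_cols(cohort, as_tibble(geno))
  attr(cohort, "truth") <- truth
  attr(cohort, "spec") <- spec
  class(cohort) <- c("pprs_cohort", class(cohort))
  cohort
}

#' Extract the genotype matrix from a cohort tibble
#'
#' @param cohort A cohort tibble (any data frame whose SNP columns are
#'   those not named in `meta_cols`).
#' @param meta_cols Columns treated as metadata rather than genotypes.
#' @return A numeric matrix, subjects by SNPs.
#' @export
cohort_genotypes <- function(cohort, meta_cols = c("id", "D", "E")) {
  snp_cols <- setdiff(names(cohort), meta_cols)
  cols <- unclass(cohort)[snp_cols]
  g <- matrix(unlist(cols, recursive = FALSE, use.names = FALSE),
              nrow = nrow(cohort), ncol = length(snp_cols),
              dimnames = list(NULL, snp_cols))
  g
}

#' Per-SNP generative truth labels of a simulated cohort
#'
#' @param cohort A cohort produced by [simulate_cohort()].
#' @return A tibble with `snp_id`, `role` and `in_pathway`.
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) abort("This cohort carries no truth labels (not simulated).")
  truth
}
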