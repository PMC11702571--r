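#' Compute PRS and pathway-restricted scores
#'
#' The overall polygenic risk score for subject `i` is
#' `PRS_i = sum_k w_k G_ik` over all M weighted SNPs. Each pathway score
#' `pPRS` is the same weighted sum restricted to the SNPs in the pathway
#' subset — using the *same* joint-model weights, never refitted — and the
#' non-pathway score `npPRS` runs over the SNPs in none of the supplied
#' subsets. Because the weights are shared, the subset scores of any
#' partition of the M SNPs sum exactly to the overall PRS.
#'
#' @param cohort A data frame containing the SNP columns (a cohort tibble
#'   or a genotype table from [read_genotype_table()]).
#' @param weights A `prs_weights` tibble ([estimate_weights()] or
#'   [read_pgs_scorefile()]).
#' @param snp_sets Named list of SNP-id subsets (e.g. from
#'   [build_snp_sets()]); every subset must be covered by the weights.
#' @param standardize If `TRUE`, each score column is scaled to sample
#'   mean 0 and standard deviation 1 (the per-score SDs are kept in the
#'   `sd_scale` attribute). Interaction ORs on standardized scores read
#'   as "per 1 SD of the score". Power of the interaction test is
#'   scale-invariant, so simulation work typically leaves scores raw.
#' @param id_col Subject identifier column, carried through to the output.
#' @return A tibble of class `score_set`: `id`, `prs`, one `pprs_<label>`
#'   column per subset, and `npprs` (when subsets are given), with
#'   attributes `standardized` and `sd_scale`.
#' @export
#' @examples
#' spec <- scenario_spec(n_snps = 20, q_causal = 4, q_gxe = 2, q_pathway = 2,
#'                       pathway_overlap_gxe = 2, n_cases = 150, n_controls = 150)
#' ch <- simulate_cohort(spec, effect_config(spec, deltaG = 0.4), seed = 2)
#' w <- estimate_weights(ch, sprintf("snp_%04d", 1:4))
#' compute_scores(ch, w, snp_sets = list(pw = c("snp_0001", "snp_0002")))
compute_scores <- function(cohort, weights, snp_sets = list(),
                           standardize = FALSE, id_col = "id") {
  stopifnot(inherits(weights, "prs_weights"))
  snp_ids <- weights$snp_id
  missing_geno <- setdiff(snp_ids, names(cohort))
  if (length(missing_geno)) {
    abort(sprintf("Weighted SNP(s) absent from the genotype data: %s",
                  paste(utils::head(missing_geno, 5), collapse = ", ")))
  }
  if (length(snp_sets)) {
    if (is.null(names(snp_sets)) || any(names(snp_sets) == "")) {
      abort("`snp_sets` must be a named list.")
    }
    for (lab in names(snp_sets)) {
      extra <- setdiff(snp_sets[[lab]], snp_ids)
      if (length(extra)) {
        abort(sprintf("Subset `%s` contains SNP(s) without weights: %s",
                      lab, paste(utils::head(extra, 5), collapse = ", ")))
      }
    }
  }

  G <- as.matrix(as.data.frame(cohort)[snp_ids])
  storage.mode(G) <- "double"
  G <- align_effect_alleles(G, cohort, weights)
  w <- weights$weight

  out <- tibble(id = if (id_col %in% names(cohort)) cohort[[id_col]]
                else seq_len(nrow(cohort)))
  out$prs <- drop(G %*% w)
  if (length(snp_sets)) {
    for (lab in names(snp_sets)) {
      sel <- snp_ids %in% snp_sets[[lab]]
      out[[paste0("pprs_", lab)]] <- drop(G[, sel, drop = FALSE] %*% w[sel])
    }
    in_any <- snp_ids %in% unique(unlist(snp_sets))
    out$npprs <- drop(G[, !in_any, drop = FALSE] %*% w[!in_any])
  }

  score_cols <- setdiff(names(out), "id")
  sd_scale <- setNames(rep(1, length(score_cols)), score_cols)
  if (standardize) {
    for (sc in score_cols) {
      s <- sd(out[[sc]])
      if (!is.finite(s) || s == 0) {
        warn(sprintf("Score `%s` is constant; left unstandardized.", sc))
        next
      }
      sd_scale[[sc]] <- s
      out[[sc]] <- (out[[sc]] - mean(out[[sc]])) / s
    }
  }
  attr(out, "standardized") <- standardize
  attr(out, "sd_scale") <- sd_scale
  class(out) <- c("score_set", class(out))
  out
}

# Flip dosages (2 - g) where the counted allele of the genotype data
# disagrees with the scoring file's effect allele. Counted alleles come
# from the `counted_allele` attribute set by read_genotype_table() on
# PLINK-raw input; when either side lacks allele labels the dosages are
# used as-is. Strand-ambiguous (A/T, C/G) weight SNPs are rejected rather
# than guessed.
align_effect_alleles <- function(G, cohort, weights) {
  counted <- attr(cohort, "counted_allele")
  if (is.null(counted) || !"effect_allele" %in% names(weights)) return(G)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (j in seq_along(weights$snp_id)) {
    id <- weights$snp_id[j]
    if (!id %in% names(counted)) next
    eff <- toupper(weights$effect_allele[j])
    oth <- if ("other_allele" %in% names(weights)) toupper(weights$other_allele[j]) else NA
    cnt <- toupper(counted[[id]])
    if (!is.na(oth) && oth == comp[eff]) {
      abort(sprintf("SNP `%s` is strand-ambiguous (%s/%s); refusing to guess orientation.",
                    id, eff, oth))
    }
    if (cnt == eff || identical(cnt, unname(comp[eff]))) next
    if (is.na(oth) || cnt == oth || identical(cnt, unname(comp[oth]))) {
      G[, j] <- 2 - G[, j]
    } else {
      abort(sprintf("SNP `%s`: counted allele %s matches neither effect (%s) nor other (%s) allele.",
                    id, cnt, eff, oth))
    }
  }
  G
}
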