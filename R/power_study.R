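#' Pathway SNP ids implied by a scenario's overlap counts
#'
#' Simulated SNP columns are laid out deterministically (interaction SNPs
#' first, then main-effect-only, then null), so a scenario's pathway
#' membership is a fixed id set.
#'
#' @param spec A [scenario_spec()].
#' @return Character vector of pathway SNP ids.
#' @export
pathway_snp_ids <- function(spec) {
  ids <- sprintf("snp_%04d", seq_len(spec$n_snps))
  c(if (spec$pathway_overlap_gxe > 0) ids[seq_len(spec$pathway_overlap_gxe)],
    if (spec$pathway_overlap_gonly > 0)
      ids[spec$q_gxe + seq_len(spec$pathway_overlap_gonly)],
    if (spec$pathway_overlap_null > 0)
      ids[spec$q_causal + seq_len(spec$pathway_overlap_null)])
}

run_one_replicate <- function(spec, effects, rep_seed, scenario_sets,
                              alpha, discovery_alpha) {
  cohort <- simulate_cohort(spec, effects, seed = rep_seed)
  scan <- marginal_scan(cohort)
  discovered <- discover_snps(scan, discovery_alpha, spec$n_snps)
  truth <- cohort_truth(cohort)
  gxe_ids <- truth$snp_id[truth$role == "gxe"]
  n_disc <- length(discovered)
  n_gxe <- sum(discovered %in% gxe_ids)

  base <- tibble(n_discovered = n_disc, n_gxe_discovered = n_gxe,
                 reject_prs = FALSE)
  for (lab in names(scenario_sets)) {
    base[[paste0("reject_pprs_", lab)]] <- FALSE
    base[[paste0("reject_npprs_", lab)]] <- FALSE
  }
  if (n_disc == 0L) return(base)

  weights <- estimate_weights(cohort, discovered)
  sets <- lapply(scenario_sets, function(pw) intersect(discovered, pw))
  nonempty <- names(sets)[lengths(sets) > 0]
  scores <- compute_scores(
    cohort, weights,
    snp_sets = sets[nonempty],
    standardize = FALSE
  )
  dat <- dplyr::bind_cols(scores, cohort[c("D", "E")])

  test_one <- function(col) {
    x <- dat[[col]]
    if (is.null(x) || sd(x) == 0) return(FALSE)
    ok <- tryCatch(fit_interaction(dat, score = col, exposure = "E"),
                   error = function(e) NULL)
    !is.null(ok) && ok$p_lrt < alpha
  }
  base$reject_prs <- test_one("prs")
  for (lab in names(sets)) {
    pcol <- paste0("pprs_", lab)
    if (lab %in% nonempty) {
      base[[paste0("reject_pprs_", lab)]] <- test_one(pcol)
      # same weights, so the non-pathway score is the exact complement
      dat[[paste0("np_", lab)]] <- dat$prs - dat[[pcol]]
      base[[paste0("reject_npprs_", lab)]] <- test_one(paste0("np_", lab))
    } else {
      # empty pathway: the non-pathway score is the full PRS
      base[[paste0("reject_npprs_", lab)]] <- base$reject_prs
    }
  }
  base
}

#' Replicate power study of PRS x E versus pathway pPRS x E testing
#'
#' For each replicate: simulate a case-control cohort under the calibrated
#' generative model, scan all SNPs, discover at the Bonferroni threshold,
#' estimate joint-model weights on the discovered SNPs, form the overall
#' PRS plus each scenario's pathway and non-pathway scores, and run the
#' three interaction likelihood-ratio tests at level `alpha`. Power (or
#' type-I error, when no interaction effects are simulated) is the
#' rejection proportion across replicates.
#'
#' The nine standard scenarios share an identical generative model and
#' differ only in which SNPs count as the pathway, so one set of simulated
#' replicates is scored against every requested scenario — this keeps a
#' full nine-scenario study at the cost of a single-scenario one.
#' Replicates with zero discovered SNPs contribute non-rejections and are
#' tallied in `n_zero_discovery`.
#'
#' @param scenarios Integer vector of scenario ids (1..9).
#' @param n_reps Number of replicate datasets.
#' @param alpha Level of the interaction tests.
#' @param seed Master seed; each replicate uses an indexed substream, so
#'   results do not depend on evaluation order.
#' @param effects Optional [effect_config()]; defaults to
#'   [calibrated_effects()] (90% marginal power at `0.05/n_snps`, 10%
#'   per-SNP interaction power at `0.05/20`).
#' @param discovery_alpha Family-wise level of the discovery threshold.
#' @param progress Print a dot every 50 replicates.
#' @return A tibble of class `power_study`, one row per scenario:
#'   rejection proportions `power_prs`, `power_pprs`, `power_npprs` with
#'   binomial SEs, `mean_discovered`, `mean_gxe_discovered`,
#'   `n_zero_discovery`. The per-replicate table is attached as attribute
#'   `replicates`.
#' @export
run_power_study <- function(scenarios = 1:9, n_reps = 1000L, alpha = 0.05,
                            seed = 1L, effects = NULL,
                            discovery_alpha = 0.05, progress = FALSE) {
  scenarios <- vapply(scenarios, check_count, integer(1), name = "scenarios", min = 1L)
  if (any(scenarios > 9L)) abort("`scenarios` must be in 1..9.")
  n_reps <- check_count(n_reps, "n_reps", 1L)
  check_prob(alpha, "alpha")
  specs <- lapply(scenarios, make_scenario)
  names(specs) <- as.character(scenarios)
  base_spec <- specs[[1]]
  if (is.null(effects)) effects <- calibrated_effects(base_spec)
  scenario_sets <- lapply(specs, pathway_snp_ids)

  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    reps[[i]] <- run_one_replicate(base_spec, effects, substream_seed(seed, i),
                                   scenario_sets, alpha, discovery_alpha)
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  reps <- dplyr::bind_rows(reps)

  prop_se <- function(p) sqrt(p * (1 - p) / n_reps)
  out <- purrr::map_dfr(as.character(scenarios), function(lab) {
    pp <- mean(reps[[paste0("reject_pprs_", lab)]])
    np <- mean(reps[[paste0("reject_npprs_", lab)]])
    pr <- mean(reps$reject_prs)
    ov <- SCENARIO_OVERLAPS[[lab]]
    tibble(scenario_id = as.integer(lab),
           overlap_gxe = ov[1], overlap_gonly = ov[2], overlap_null = ov[3],
           n_reps = n_reps,
           power_prs = pr, se_prs = prop_se(pr),
           power_pprs = pp, se_pprs = prop_se(pp),
           power_npprs = np, se_npprs = prop_se(np),
           mean_discovered = mean(reps$n_discovered),
           mean_gxe_discovered = mean(reps$n_gxe_discovered),
           n_zero_discovery = sum(reps$n_discovered == 0L))
  })
  attr(out, "replicates") <- reps
  attr(out, "alpha") <- alpha
  attr(out, "effects") <- effects
  class(out) <- c("power_study", class(out))
  out
}

#' Power estimate for a single scenario
#'
#' @inheritParams run_power_study
#' @param scenario_id Scenario id in 1..9.
#' @return A one-row `power_study` tibble.
#' @export
run_power_scenario <- function(scenario_id, n_reps = 1000L, alpha = 0.05,
                               seed = 1L, effects = NULL,
                               discovery_alpha = 0.05) {
  run_power_study(scenarios = scenario_id, n_reps = n_reps, alpha = alpha,
                  seed = seed, effects = effects,
                  discovery_alpha = discovery_alpha)
}

#' Type-I-error study of same-data weight estimation
#'
#' Simulates cohorts with 20 causal SNPs and *no* interaction effects,
#' then — per replicate and per SNP-selection method — estimates joint
#' weights on the same cohort, forms the PRS, and tests PRS x E by LRT at
#' `alpha`. Valid type-I error despite the "double use" of the data rests
#' on the asymptotic independence of marginal SNP effects and interaction
#' effects.
#'
#' Selection methods: (1) scan `p < 0.05/n_snps`; (2) `p < 0.05/10`; (3)
#' `p < 0.05`; (4) the 20 causal SNPs by their true labels; (5) a random
#' 10 causal plus 10 null SNPs.
#'
#' @param selection_methods Subset of 1:5.
#' @inheritParams run_power_study
#' @return A tibble, one row per method: `method`, `type1_error`, `se`,
#'   `mean_selected`. Per-replicate rejections in attribute `replicates`.
#' @export
run_type1_study <- function(selection_methods = 1:5, n_reps = 1000L,
                            alpha = 0.05, seed = 1L, effects = NULL) {
  selection_methods <- vapply(selection_methods, check_count, integer(1),
                              name = "selection_methods", min = 1L)
  if (any(selection_methods > 5L)) abort("`selection_methods` must be in 1..5.")
  n_reps <- check_count(n_reps, "n_reps", 1L)
  spec <- scenario_spec(q_gxe = 0L, pathway_overlap_gxe = 0L,
                        pathway_overlap_gonly = 5L, pathway_overlap_null = 0L)
  if (is.null(effects)) {
    dG <- calibrate_main_effect(0.05 / spec$n_snps, 0.90, spec)
    effects <- effect_config(spec, deltaG = dG)
  }
  causal_ids <- sprintf("snp_%04d", seq_len(spec$q_causal))
  null_ids <- sprintf("snp_%04d", (spec$q_causal + 1L):spec$n_snps)

  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cohort <- simulate_cohort(spec, effects, seed = substream_seed(seed, i))
    scan <- marginal_scan(cohort)
    res <- list(rep = i)
    for (m in selection_methods) {
      sel <- switch(as.character(m),
        `1` = discover_snps(scan, 0.05, spec$n_snps),
        `2` = discover_snps(scan, 0.05, 10L),
        `3` = discover_snps(scan, 0.05, 1L),
        `4` = causal_ids,
        `5` = c(sample(causal_ids, 10L), sample(null_ids, 10L))
      )
      rej <- FALSE
      if (length(sel) > 0) {
        w <- estimate_weights(cohort, sel)
        sc <- compute_scores(cohort, w)
        dat <- dplyr::bind_cols(sc, cohort[c("D", "E")])
        rej <- tryCatch(
          fit_interaction(dat, score = "prs", exposure = "E")$p_lrt < alpha,
          error = function(e) FALSE)
      }
      res[[paste0("reject_m", m)]] <- rej
      res[[paste0("n_sel_m", m)]] <- length(sel)
    }
    rows[[i]] <- as_tibble(res)
  }
  reps <- dplyr::bind_rows(rows)
  out <- purrr::map_dfr(selection_methods, function(m) {
    p <- mean(reps[[paste0("reject_m", m)]])
    tibble(method = m, n_reps = n_reps, type1_error = p,
           se = sqrt(p * (1 - p) / n_reps),
           mean_selected = mean(reps[[paste0("n_sel_m", m)]]))
  })
  attr(out, "replicates") <- reps
  out
}

#' Cross-replicate discovery summaries
#'
#' @param replicates A per-replicate tibble with `n_discovered` and
#'   `n_gxe_discovered` columns (attribute `replicates` of a
#'   [run_power_study()] result).
#' @return A one-row tibble: `mean_discovered`, `mean_gxe_discovered`.
#' @export
summarize_discovery <- function(replicates) {
  if (nrow(replicates) < 1L) abort("At least one replicate is required.")
  tibble(mean_discovered = mean(replicates$n_discovered),
         mean_gxe_discovered = mean(replicates$n_gxe_discovered))
}
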