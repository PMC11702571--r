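#' Define a simulation scenario for the pPRS x E power study
#'
#' A scenario fixes the architecture of the simulated case-control study:
#' how many SNPs are generated, how many are disease-causing, how many of
#' those carry a gene-environment interaction, and how the five pathway
#' SNPs overlap the causal classes. Defaults correspond to the reference
#' simulation design: 1,000 independent binary SNPs with population
#' frequency 0.35, 20 causal SNPs of which 5 interact with a binary
#' exposure of prevalence 0.50, and quota sampling of 5,000 cases and
#' 5,000 controls.
#'
#' @param n_snps Total number of simulated SNPs.
#' @param q_causal Number of SNPs with a main effect on disease (includes
#'   the interaction SNPs).
#' @param q_gxe Number of causal SNPs that additionally interact with the
#'   exposure.
#' @param q_pathway Number of SNPs annotated to the pathway of interest.
#' @param pathway_overlap_gxe,pathway_overlap_gonly,pathway_overlap_null
#'   How the pathway SNPs are drawn from, respectively, the interaction
#'   SNPs, the main-effect-only SNPs, and the null SNPs. Must sum to
#'   `q_pathway`.
#' @param n_cases,n_controls Case and control quotas.
#' @param g_freq Population frequency of the binary risk genotype.
#' @param e_prev Population prevalence of the binary exposure.
#' @param prevalence Target population disease prevalence used to fix the
#'   intercept of the generative disease model.
#'
#' @return An object of class `scenario_spec` (a named list).
#' @export
#' @examples
#' scenario_spec()
#' make_scenario(1)
scenario_spec <- function(n_snps = 1000L,
                          q_causal = 20L,
                          q_gxe = 5L,
                          q_pathway = 5L,
                          pathway_overlap_gxe = 5L,
                          pathway_overlap_gonly = 0L,
                          pathway_overlap_null = 0L,
                          n_cases = 5000L,
                          n_controls = 5000L,
                          g_freq = 0.35,
                          e_prev = 0.50,
                          prevalence = 0.10) {
  spec <- list(
    n_snps = check_count(n_snps, "n_snps", 1L),
    q_causal = check_count(q_causal, "q_causal"),
    q_gxe = check_count(q_gxe, "q_gxe"),
    q_pathway = check_count(q_pathway, "q_pathway"),
    pathway_overlap_gxe = check_count(pathway_overlap_gxe, "pathway_overlap_gxe"),
    pathway_overlap_gonly = check_count(pathway_overlap_gonly, "pathway_overlap_gonly"),
    pathway_overlap_null = check_count(pathway_overlap_null, "pathway_overlap_null"),
    n_cases = check_count(n_cases, "n_cases", 1L),
    n_controls = check_count(n_controls, "n_controls", 1L),
    g_freq = check_prob(g_freq, "g_freq"),
    e_prev = check_prob(e_prev, "e_prev"),
    prevalence = check_prob(prevalence, "prevalence")
  )
  with(spec, {
    if (q_gxe > q_causal) abort("`q_gxe` cannot exceed `q_causal`.")
    if (q_causal > n_snps) abort("`q_causal` cannot exceed `n_snps`.")
    if (q_pathway > n_snps) abort("`q_pathway` cannot exceed `n_snps`.")
    if (pathway_overlap_gxe + pathway_overlap_gonly + pathway_overlap_null != q_pathway) {
      abort("Pathway overlap counts must sum to `q_pathway`.")
    }
    if (pathway_overlap_gxe > q_gxe) abort("`pathway_overlap_gxe` cannot exceed `q_gxe`.")
    if (pathway_overlap_gonly > q_causal - q_gxe) {
      abort("`pathway_overlap_gonly` cannot exceed the number of main-effect-only SNPs.")
    }
    if (pathway_overlap_null > n_snps - q_causal) {
      abort("`pathway_overlap_null` cannot exceed the number of null SNPs.")
    }
  })
  structure(spec, class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>\n")
  cat(sprintf("  SNPs: %d (%d causal, %d with GxE), pathway size %d\n",
              x$n_snps, x$q_causal, x$q_gxe, x$q_pathway))
  cat(sprintf("  pathway overlap (GxE / G-only / null): %d / %d / %d\n",
              x$pathway_overlap_gxe, x$pathway_overlap_gonly, x$pathway_overlap_null))
  cat(sprintf("  sample: %d cases / %d controls; G freq %.2f, E prev %.2f, prevalence %.2f\n",
              x$n_cases, x$n_controls, x$g_freq, x$e_prev, x$prevalence))
  invisible(x)
}

# (GxE, G-only, null) pathway-overlap triples for the nine study scenarios.
SCENARIO_OVERLAPS <- list(
  `1` = c(5L, 0L, 0L), `2` = c(4L, 1L, 0L), `3` = c(3L, 2L, 0L),
  `4` = c(2L, 3L, 0L), `5` = c(1L, 4L, 0L), `6` = c(4L, 0L, 1L),
  `7` = c(3L, 0L, 2L), `8` = c(2L, 0L, 3L), `9` = c(1L, 0L, 4L)
)

#' Retrieve one of the nine standard power-study scenarios
#'
#' Scenarios 1-5 move pathway membership from interaction SNPs to
#' main-effect-only SNPs; scenarios 6-9 move it to null SNPs instead.
#' All other design parameters stay at the [scenario_spec()] defaults.
#'
#' @param scenario_id Integer in 1..9.
#' @param ... Overrides passed to [scenario_spec()] (sample sizes,
#'   frequencies, prevalence).
#' @return A `scenario_spec`.
#' @export
make_scenario <- function(scenario_id, ...) {
  id <- check_count(scenario_id, "scenario_id", 1L)
  if (id > 9L) abort("`scenario_id` must be in 1..9.")
  ov <- SCENARIO_OVERLAPS[[as.character(id)]]
  spec <- scenario_spec(pathway_overlap_gxe = ov[1],
                        pathway_overlap_gonly = ov[2],
                        pathway_overlap_null = ov[3], ...)
  attr(spec, "scenario_id") <- id
  spec
}

#' Generative effect sizes for the disease model
#'
#' Bundles the log-odds coefficients of the Bernoulli disease model
#' `P(D=1 | G, E) = expit(delta0 + deltaE*E + sum(deltaG*G) +
#' sum(deltaGxE*G*E))`. When `delta0 = NULL` the intercept is solved so
#' that the population disease prevalence equals `spec$prevalence`.
#'
#' @param spec A [scenario_spec()].
#' @param deltaG Per-causal-SNP main-effect log odds ratios; recycled to
#'   length `q_causal`.
#' @param deltaGxE Per-interaction-SNP log odds ratios; recycled to length
#'   `q_gxe`.
#' @param deltaE Exposure main-effect log odds ratio. The default
#'   corresponds to an exposure odds ratio of 1.5.
#' @param delta0 Intercept; solved from `spec$prevalence` when `NULL`.
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(spec,
                          deltaG,
                          deltaGxE = numeric(spec$q_gxe),
                          deltaE = log(1.5),
                          delta0 = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  deltaG <- rep_len(as.double(deltaG), spec$q_causal)
  deltaGxE <- rep_len(as.double(deltaGxE), max(spec$q_gxe, 0L))
  if (!all(is.finite(deltaG)) || !all(is.finite(deltaGxE)) || !is.finite(deltaE)) {
    abort("All effect sizes must be finite.")
  }
  eff <- structure(
    list(delta0 = delta0, deltaE = as.double(deltaE),
         deltaG = deltaG, deltaGxE = deltaGxE),
    class = "effect_config"
  )
  if (is.null(delta0)) {
    eff$delta0 <- solve_intercept(spec, eff)
  }
  eff
}

#' @export
print.effect_config <- function(x, ...) {
  cat("<effect_config>\n")
  cat(sprintf("  delta0 = %.4f, deltaE = %.4f (OR %.3f)\n",
              x$delta0, x$deltaE, exp(x$deltaE)))
  cat(sprintf("  deltaG: %d coefficients, mean OR %.3f\n",
              length(x$deltaG), exp(mean(x$deltaG))))
  cat(sprintf("  deltaGxE: %d coefficients, mean OR %.3f\n",
              length(x$deltaGxE), if (length(x$deltaGxE)) exp(mean(x$deltaGxE)) else NA_real_))
  invisible(x)
}

# Exact distribution of the genetic part of the linear predictor.
# Causal SNPs are independent Bernoulli(g_freq); when the main (and
# interaction) effects are exchangeable within class the sums reduce to
# binomial counts, otherwise the atom set is built by direct convolution.
lp_distribution <- function(spec, eff) {
  f <- spec$g_freq
  conv <- function(deltas, extra = NULL) {
    # returns tibble-ish list: value, prob for sum(delta_k * G_k [ + extra_k * G_k])
    d <- if (is.null(extra)) deltas else deltas + extra
    if (length(d) == 0L) return(list(value = 0, prob = 1))
    if (length(unique(round(d, 12))) == 1L) {
      k <- 0:length(d)
      list(value = k * d[1], prob = stats::dbinom(k, length(d), f))
    } else {
      value <- 0; prob <- 1
      for (dk in d) {
        value <- c(value, value + dk)
        prob <- c(prob * (1 - f), prob * f)
      }
      agg <- tapply(prob, round(value, 12), sum)
      list(value = as.numeric(names(agg)), prob = as.numeric(agg))
    }
  }
  dG <- eff$deltaG
  q_gxe <- spec$q_gxe
  gxe_idx <- seq_len(q_gxe)
  gonly <- if (q_gxe < spec$q_causal) dG[-gxe_idx] else numeric(0)
  list(
    gonly = conv(gonly),
    gxe_e0 = conv(dG[gxe_idx]),
    gxe_e1 = conv(dG[gxe_idx], eff$deltaGxE)
  )
}

# Population disease prevalence under the generative model, as a function
# of the intercept; used to solve delta0 for the target prevalence.
population_prevalence <- function(spec, eff, delta0) {
  parts <- lp_distribution(spec, eff)
  prev <- 0
  for (e in 0:1) {
    pe <- if (e == 1) spec$e_prev else 1 - spec$e_prev
    gxe <- if (e == 1) parts$gxe_e1 else parts$gxe_e0
    lp <- outer(parts$gonly$value, gxe$value, `+`) + delta0 + e * eff$deltaE
    pr <- outer(parts$gonly$prob, gxe$prob)
    prev <- prev + pe * sum(pr * expit(lp))
  }
  prev
}

solve_intercept <- function(spec, eff) {
  f <- function(d0) population_prevalence(spec, eff, d0) - spec$prevalence
  uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
}
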