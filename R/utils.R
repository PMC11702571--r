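#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pchisq qchisq pnorm qnorm rbinom runif uniroot
#'   binomial glm glm.fit coef vcov anova p.adjust phyper dhyper
#'   fisher.test quantile sd setNames
NULL

expit <- function(x) stats::plogis(x)

#' @keywords internal
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single probability strictly inside (0, 1).", name))
  }
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

# Replicate-indexed substream: deterministic child seed for replicate `i`
# of master seed `seed`, kept inside the 32-bit signed range.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 69621) %% 2147483563) + 1L
}
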