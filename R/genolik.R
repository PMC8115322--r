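#' Sequencing-error and damage model for low-coverage reads
#'
#' Collapses base-calling error into a single mis-read probability
#' `epsilon` and post-mortem deamination into an extra flip probability
#' `delta` that acts only at damage-susceptible sites (the C->T / G->A
#' strand classes). The per-read alternate-allele probability for genotype
#' `g` (alt dosage) at a site with susceptibility flag `s` is
#' `a(0) = epsilon + delta*s`, `a(1) = 1/2`, `a(2) = 1 - epsilon - delta*s`.
#'
#' @param epsilon base mis-read probability, in `[0, 0.5)`.
#' @param delta damage flip probability, in `[0, 1)`; `epsilon + delta`
#'   must stay below 1.
#' @return An `error_model` list.
#' @export
error_model <- function(epsilon = 0.005, delta = 0.02) {
  if (epsilon < 0 || epsilon >= 0.5) stop_param("epsilon must lie in [0, 0.5)")
  if (delta < 0 || delta >= 1) stop_param("delta must lie in [0, 1)")
  if (epsilon + delta >= 1) stop_param("epsilon + delta must be < 1 at susceptible sites")
  structure(list(epsilon = epsilon, delta = delta), class = "error_model")
}

#' Genotype likelihoods from allele-count pileups
#'
#' For each individual and site, the three genotype likelihoods are the
#' binomial read-sampling probabilities under the [error_model()]:
#' `L(g) = a(g)^n_alt * (1 - a(g))^n_ref` up to a shared constant. They are
#' returned as natural logs, normalized so the per-site maximum is 0; at
#' zero coverage all three are 0 (uninformative).
#'
#' @param pileup a `pileup_table` from [simulate_pileups()] or
#'   [read_pileup_tsv()].
#' @param panel the matching frequency panel (provides damage flags).
#' @param model an [error_model()].
#' @return A `gl_set` list with matrices `ll0`, `ll1`, `ll2` (individuals x
#'   sites, natural-log likelihoods) and `coverage`.
#' @export
genotype_likelihoods <- function(pileup, panel, model = error_model()) {
  stopifnot(inherits(pileup, "pileup_table"), inherits(model, "error_model"))
  validate_panel(panel)
  nr <- pileup$n_ref; na <- pileup$n_alt
  if (any(nr < 0) || any(na < 0)) stop_data("read counts must be non-negative")
  n <- nrow(nr); S <- ncol(nr)
  stopifnot(S == nrow(panel))
  s <- matrix(rep(as.numeric(panel$damage), each = n), n, S)
  a0 <- model$epsilon + model$delta * s
  if (any(a0 >= 1)) stop_param("epsilon + delta must be < 1 at susceptible sites")
  ll_of <- function(a) {
    out <- matrix(0, n, S)
    pos <- na > 0
    out[pos] <- out[pos] + na[pos] * log(a[pos])
    pos <- nr > 0
    out[pos] <- out[pos] + nr[pos] * log(1 - a[pos])
    out
  }
  ll0 <- ll_of(a0)
  ll1 <- ll_of(matrix(0.5, n, S))
  ll2 <- ll_of(1 - a0)
  mx <- pmax(ll0, ll1, ll2)
  dn <- dimnames(nr)
  structure(list(ll0 = structure(ll0 - mx, dimnames = dn),
                 ll1 = structure(ll1 - mx, dimnames = dn),
                 ll2 = structure(ll2 - mx, dimnames = dn),
                 coverage = nr + na,
                 site_id = panel$site_id),
            class = "gl_set")
}

#' Majority-allele pseudo-haploid calls
#'
#' Represents each low-coverage diploid by the allele with the higher read
#' count per site; ties are broken by a fair coin and uncovered sites are
#' missing. This is the standard pseudo-haploid representation used by
#' mismatch-based relatedness methods.
#'
#' @param pileup a `pileup_table`.
#' @param seed integer seed for the tie-break coin.
#' @return Integer matrix (individuals x sites) of 0 (ref), 1 (alt) or `NA`.
#' @export
majority_allele_call <- function(pileup, seed = 1L) {
  stopifnot(inherits(pileup, "pileup_table"))
  nr <- pileup$n_ref; na <- pileup$n_alt
  with_seed(seed, {
    call <- matrix(NA_integer_, nrow(nr), ncol(nr), dimnames = dimnames(nr))
    call[nr > na] <- 0L
    call[na > nr] <- 1L
    tie <- nr == na & nr + na > 0
    call[tie] <- as.integer(runif(sum(tie)) < 0.5)
    call
  })
}

#' Bayesian allele-frequency estimate from genotype likelihoods
#'
#' The posterior over the population alternate-allele frequency `p` is
#' computed on a uniform grid, combining each covered individual's
#' likelihood `sum_g L(g) P(g | p)` under Hardy-Weinberg with a Beta prior.
#' The point estimate is the posterior mean and the interval the central
#' 95% posterior interval.
#'
#' @param ll0,ll1,ll2 per-individual natural-log genotype likelihoods at
#'   one site (numeric vectors of equal length).
#' @param prior Beta prior parameters `c(alpha, beta)` (default flat).
#' @param grid_points number of grid points on `[0, 1]`.
#' @param level interval coverage (default 0.95).
#' @return An `allele_freq_estimate` list: `estimate`, `lo`, `hi`,
#'   `n_effective` (covered individuals), `posterior` (grid + density).
#' @export
estimate_allele_frequency <- function(ll0, ll1, ll2, prior = c(1, 1),
                                      grid_points = 1001L, level = 0.95) {
  keep <- !(ll0 == 0 & ll1 == 0 & ll2 == 0)
  if (!any(keep)) stop_data("no covered individuals at this site")
  L <- exp(cbind(ll0, ll1, ll2)[keep, , drop = FALSE])
  p <- seq(0, 1, length.out = grid_points)
  G <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)      # 3 x grid HWE priors
  logpost <- (prior[1] - 1) * log(p) + (prior[2] - 1) * log(1 - p)
  if (all(prior == 1)) logpost <- rep(0, grid_points)
  M <- L %*% G                                      # individuals x grid
  logpost <- logpost + colSums(log(M))
  logpost <- logpost - max(logpost[is.finite(logpost)])
  w <- exp(logpost)
  w[!is.finite(w)] <- 0
  w <- w / sum(w)
  est <- sum(w * p)
  cdf <- cumsum(w)
  lo <- p[which(cdf >= (1 - level) / 2)[1]]
  hi <- p[which(cdf >= 1 - (1 - level) / 2)[1]]
  structure(list(estimate = est, lo = lo, hi = hi,
                 n_effective = sum(keep),
                 posterior = list(p = p, density = w)),
            class = "allele_freq_estimate")
}

#' Site filter on panel frequency and cohort coverage
#'
#' A site passes when its panel minor-allele frequency is at least
#' `maf_min` and at least `min_samples` individuals cover it at depth
#' `min_depth` or more (mirroring "covered at least twice in a minimum of
#' ten samples" style filters).
#'
#' @param panel frequency panel.
#' @param gls a `gl_set` (its `coverage` matrix is used).
#' @param maf_min minor-allele-frequency floor.
#' @param min_depth per-individual depth threshold.
#' @param min_samples minimum number of individuals at that depth.
#' @return Logical site mask (length = number of sites).
#' @export
site_filter <- function(panel, gls, maf_min = 0.05, min_depth = 2L,
                        min_samples = 10L) {
  if (maf_min < 0 || min_depth < 0 || min_samples < 0) {
    stop_param("thresholds must be non-negative")
  }
  maf <- pmin(panel$p, 1 - panel$p)
  n_ok <- colSums(gls$coverage >= min_depth)
  unname(maf >= maf_min & n_ok >= min_samples)
}
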