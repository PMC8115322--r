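#' Haplotype diversity with small-sample correction
#'
#' `h = n/(n-1) * (1 - sum(x_i^2))` where `x_i` are haplotype frequencies
#' among `n` individuals: the probability that two randomly drawn
#' individuals carry different haplotypes.
#'
#' @param labels character vector of haplotype labels (`NA` dropped).
#' @return Scalar diversity in `[0, 1]`.
#' @export
haplotype_diversity <- function(labels) {
  labels <- labels[!is.na(labels)]
  n <- length(labels)
  if (n < 2) stop_param("haplotype diversity needs at least 2 individuals")
  x <- as.numeric(table(labels)) / n
  n / (n - 1) * (1 - sum(x^2))
}

#' Hudson's F_ST estimator
#'
#' Per-site numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; the genome-wide estimate is the ratio
#' of summed numerators to summed denominators ("ratio of averages"), the
#' recommended way to combine sites.
#'
#' @param p1,p2 per-site sample allele frequencies in the two groups.
#' @param n1,n2 sample sizes (number of sampled allele copies), scalar or
#'   per-site; must exceed 1.
#' @return List with `fst` (genome-wide), `num`, `den` (per-site terms).
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1) || any(n2 <= 1)) stop_param("sample sizes must be > 1")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  list(fst = sum(num[ok]) / sum(den[ok]), num = num, den = den)
}

#' Hudson's F_ST between two genotype matrices
#'
#' Convenience wrapper computing sample allele frequencies (half the mean
#' alt dosage) and allele-copy counts from diploid genotype matrices.
#'
#' @param g1,g2 individuals x sites matrices of alt dosages (0/1/2).
#' @return As [hudson_fst()].
#' @export
hudson_fst_genotypes <- function(g1, g2) {
  hudson_fst(colMeans(g1) / 2, 2 * nrow(g1), colMeans(g2) / 2, 2 * nrow(g2))
}

#' Cohort inbreeding coefficient from genotype likelihoods (MCMC)
#'
#' Estimates a single cohort-level inbreeding coefficient `F` — the deficit
#' of heterozygotes relative to Hardy-Weinberg given the panel frequencies —
#' by random-walk Metropolis MCMC over the marginal likelihood
#' `prod_{ind,site} sum_g L(g) P(g | p, F)` with
#' `P(0) = q^2 + Fpq`, `P(1) = 2pq(1 - F)`, `P(2) = p^2 + Fpq`.
#'
#' Because the likelihood depends on the data only through per-entry linear
#' terms `A + F B`, the log-likelihood is pre-evaluated once on a fine grid
#' in `F` and interpolated by a cubic spline inside the chain; the
#' interpolation error is far below Monte-Carlo noise (see the methods
#' vignette). Frequencies near the domain edge can make `P(g | p, F)`
#' negative at strongly negative `F`; such values get likelihood zero, so
#' the effective domain adapts to the panel.
#'
#' @param gls a `gl_set`.
#' @param panel frequency panel.
#' @param sites optional logical site mask (e.g. from [site_filter()]).
#' @param restrict_nonneg if `TRUE`, constrain `F >= 0`.
#' @param iterations MCMC iterations (default 1e5).
#' @param burnin burn-in iterations discarded (default 5000).
#' @param step random-walk standard deviation (default 0.02).
#' @param seed integer seed.
#' @param f_min lower domain bound in unrestricted mode (default -0.2).
#' @return An `inbreeding_estimate` list: `F` (posterior mean), `lo`, `hi`
#'   (central 95% interval), `n_sites`, `acceptance`, `iterations`,
#'   `burnin`, `samples`.
#' @export
estimate_inbreeding <- function(gls, panel, sites = NULL,
                                restrict_nonneg = FALSE,
                                iterations = 1e5, burnin = 5000,
                                step = 0.02, seed = 1L, f_min = -0.2) {
  validate_panel(panel)
  keep <- rep(TRUE, length(panel$p))
  if (!is.null(sites)) keep <- sites
  p <- panel$p[keep]
  cov <- gls$coverage[, keep, drop = FALSE] > 0
  L0 <- exp(gls$ll0[, keep, drop = FALSE])
  L1 <- exp(gls$ll1[, keep, drop = FALSE])
  L2 <- exp(gls$ll2[, keep, drop = FALSE])
  q <- 1 - p
  pm <- matrix(rep(p, each = nrow(cov)), nrow(cov))
  qm <- 1 - pm
  # entry likelihood = A + F * B
  A <- (L0 * qm^2 + L1 * 2 * pm * qm + L2 * pm^2)[cov]
  B <- (pm * qm * (L0 - 2 * L1 + L2))[cov]
  n_entries <- length(A)
  if (n_entries == 0) stop_data("no covered entries after filtering")
  lo_dom <- if (restrict_nonneg) 0 else f_min
  grid <- seq(lo_dom, 1, length.out = 1201L)
  ll <- f_grid_loglik(A, B, grid)
  fin <- is.finite(ll)
  if (!any(fin)) stop_data("likelihood is degenerate over the whole F domain")
  ll_fun <- splinefun(grid[fin], ll[fin], method = "natural")
  f_lo <- min(grid[fin]); f_hi <- max(grid[fin])
  with_seed(seed, {
    draws <- numeric(iterations)
    f <- 0.01
    if (f < f_lo || f > f_hi) f <- (f_lo + f_hi) / 2
    cur <- ll_fun(f)
    acc <- 0L
    prop_all <- rnorm(iterations, 0, step)
    u_all <- log(runif(iterations))
    for (it in seq_len(iterations)) {
      fp <- f + prop_all[it]
      # reflect at the domain bounds
      if (fp < f_lo) fp <- 2 * f_lo - fp
      if (fp > f_hi) fp <- 2 * f_hi - fp
      if (fp >= f_lo && fp <= f_hi) {
        new <- ll_fun(fp)
        if (u_all[it] < new - cur) {
          f <- fp; cur <- new; acc <- acc + 1L
        }
      }
      draws[it] <- f
    }
    rate <- acc / iterations
    if (rate < 0.01 || rate > 0.99) {
      warning("inbreeding MCMC may not be mixing (acceptance rate ",
              signif(rate, 3), ")")
    }
    post <- draws[(burnin + 1L):iterations]
    structure(list(F = mean(post),
                   lo = unname(quantile(post, 0.025)),
                   hi = unname(quantile(post, 0.975)),
                   n_sites = sum(keep), n_entries = n_entries,
                   acceptance = rate, iterations = iterations,
                   burnin = burnin, samples = post),
              class = "inbreeding_estimate")
  })
}

#' Molecular sex from X- and Y-mapped read counts
#'
#' `Ry = nY / (nX + nY)` with a normal-approximation 95% confidence
#' interval; the call is XX when the interval lies entirely below 0.016
#' and XY when entirely above 0.075 (the standard shotgun-sexing
#' thresholds), otherwise inconclusive. Fewer than `min_reads` sex-linked
#' reads always yield an inconclusive, flagged call.
#'
#' @param n_x,n_y reads mapped to X and Y.
#' @param min_reads minimum total sex-linked reads for a call (default 100).
#' @return A `sex_call` list: `ry`, `lo`, `hi`, `call`, `n_x`, `n_y`,
#'   `insufficient`.
#' @export
molecular_sex <- function(n_x, n_y, min_reads = 100L) {
  if (n_x < 0 || n_y < 0) stop_param("read counts must be non-negative")
  tot <- n_x + n_y
  if (tot < min_reads) {
    return(structure(list(ry = if (tot > 0) n_y / tot else NA_real_,
                          lo = NA_real_, hi = NA_real_, call = "inconclusive",
                          n_x = n_x, n_y = n_y, insufficient = TRUE),
                     class = "sex_call"))
  }
  ry <- n_y / tot
  se <- sqrt(ry * (1 - ry) / tot)
  lo <- max(0, ry - 1.96 * se)
  hi <- min(1, ry + 1.96 * se)
  call <- if (hi < 0.016) "XX" else if (lo > 0.075) "XY" else "inconclusive"
  structure(list(ry = ry, lo = lo, hi = hi, call = call,
                 n_x = n_x, n_y = n_y, insufficient = FALSE),
            class = "sex_call")
}

#' Pairwise 1 - allele-sharing distance matrix
#'
#' Mean mismatch over jointly called sites for every pair of pseudo-haploid
#' call vectors; the diagonal is zero and pairs with no shared called site
#' are `NA` (flagged with a warning).
#'
#' @param calls individuals x sites matrix of pseudo-haploid calls
#'   (0/1/`NA`).
#' @return Symmetric numeric distance matrix.
#' @export
pairwise_distance <- function(calls) {
  ids <- rownames(calls)
  n <- nrow(calls)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  any_empty <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
        any_empty <- TRUE
      } else {
        d[i, j] <- d[j, i] <- mean(calls[i, ok] != calls[j, ok])
      }
    }
  }
  if (any_empty) warning("some pairs share no called sites; distances set to NA")
  d
}
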