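# Per-site mixture components for the pairwise IBD likelihood.
# For alt frequency p (q = 1 - p) and per-genotype likelihood columns
# Li, Lj (site x 3, linear scale), the joint genotype distribution under
# 0/1/2 alleles shared IBD gives, summed over genotype pairs:
#   A0 = (Li . HW)(Lj . HW)
#   A1 = q (Li . u)(Lj . u) + p (Li . v)(Lj . v),  u = (q, p, 0), v = (0, q, p)
#   A2 = sum_g Li(g) Lj(g) HW(g)
pair_site_components <- function(Li, Lj, p) {
  q <- 1 - p
  hw0 <- q^2; hw1 <- 2 * p * q; hw2 <- p^2
  A0 <- (Li[, 1] * hw0 + Li[, 2] * hw1 + Li[, 3] * hw2) *
        (Lj[, 1] * hw0 + Lj[, 2] * hw1 + Lj[, 3] * hw2)
  A1 <- q * (Li[, 1] * q + Li[, 2] * p) * (Lj[, 1] * q + Lj[, 2] * p) +
        p * (Li[, 2] * q + Li[, 3] * p) * (Lj[, 2] * q + Lj[, 3] * p)
  A2 <- Li[, 1] * Lj[, 1] * hw0 + Li[, 2] * Lj[, 2] * hw1 +
        Li[, 3] * Lj[, 3] * hw2
  list(A0 = A0, A1 = A1, A2 = A2)
}

gl_pair_matrices <- function(gls, i, j, sites = NULL) {
  Li <- exp(cbind(gls$ll0[i, ], gls$ll1[i, ], gls$ll2[i, ]))
  Lj <- exp(cbind(gls$ll0[j, ], gls$ll1[j, ], gls$ll2[j, ]))
  if (!is.null(sites)) {
    Li <- Li[sites, , drop = FALSE]
    Lj <- Lj[sites, , drop = FALSE]
  }
  list(Li = Li, Lj = Lj)
}

#' Pairwise log-likelihood of IBD coefficients
#'
#' Log-likelihood of `k = (k0, k1, k2)` for one pair of individuals: the
#' sum over sites of the log of the genotype-pair likelihood, mixing the
#' unrelated, one-allele-IBD and two-alleles-IBD joint genotype
#' distributions under Hardy-Weinberg at the panel frequencies.
#'
#' @param gls a `gl_set`.
#' @param i,j individual IDs (row names of the likelihood matrices).
#' @param panel frequency panel matching the sites.
#' @param k numeric vector `(k0, k1, k2)` on the probability simplex.
#' @param sites optional logical/integer site subset.
#' @return Scalar log-likelihood (up to a k-independent constant).
#' @export
pair_loglikelihood <- function(gls, i, j, panel, k, sites = NULL) {
  if (length(k) != 3 || any(k < -1e-12) || abs(sum(k) - 1) > 1e-9) {
    stop_param("k must be a point on the 2-simplex")
  }
  validate_panel(panel)
  m <- gl_pair_matrices(gls, i, j, sites)
  p <- if (is.null(sites)) panel$p else panel$p[sites]
  A <- pair_site_components(m$Li, m$Lj, p)
  sum(log(k[1] * A$A0 + k[2] * A$A1 + k[3] * A$A2))
}

# simplex grid with given step; rows (k0, k1, k2)
simplex_grid <- function(step) {
  k0 <- rep(seq(0, 1, by = step), each = length(seq(0, 1, by = step)))
  k1 <- rep(seq(0, 1, by = step), times = length(seq(0, 1, by = step)))
  keep <- k0 + k1 <= 1 + 1e-12
  cbind(k0 = k0[keep], k1 = k1[keep], k2 = pmax(0, 1 - k0[keep] - k1[keep]))
}

#' Maximum-likelihood IBD coefficients for a pair
#'
#' Maximizes [pair_loglikelihood()] over the simplex by a deterministic
#' projected grid search (step 0.01) followed by local refinement (step
#' 0.001), using only sites where both individuals have coverage. Pairs
#' with fewer than `n_min` such sites raise an insufficient-data error
#' rather than returning an unreliable estimate.
#'
#' @inheritParams pair_loglikelihood
#' @param n_min minimum number of overlapping covered sites (default 1000).
#' @param feasible_only if `TRUE`, restrict the search to the
#'   pedigree-feasible region `k1^2 >= 4 k0 k2`.
#' @param sites optional logical site mask applied before the coverage
#'   overlap requirement (e.g. from [site_filter()]).
#' @return A `kinship_estimate` list: `i`, `j`, `k0`, `k1`, `k2`,
#'   `r = k1/2 + k2`, `n_sites`, `loglik`.
#' @export
estimate_k <- function(gls, i, j, panel, n_min = 1000L,
                       feasible_only = FALSE, sites = NULL) {
  validate_panel(panel)
  ov <- gls$coverage[i, ] > 0 & gls$coverage[j, ] > 0
  if (!is.null(sites)) ov <- ov & sites
  n_sites <- sum(ov)
  if (n_sites < n_min) {
    stop_data("pair (", i, ", ", j, "): only ", n_sites,
              " overlapping covered sites (need >= ", n_min, ")")
  }
  m <- gl_pair_matrices(gls, i, j, ov)
  A <- pair_site_components(m$Li, m$Lj, panel$p[ov])
  K <- simplex_grid(0.01)
  if (feasible_only) K <- K[K[, 2]^2 >= 4 * K[, 1] * K[, 3] - 1e-12, , drop = FALSE]
  ll <- kin_grid_loglik(A$A0, A$A1, A$A2, K)
  best <- K[which.max(ll), ]
  # local refinement on a 0.001 lattice around the coarse optimum
  d <- seq(-0.01, 0.01, by = 0.001)
  k0 <- rep(best[1] + d, each = length(d))
  k1 <- rep(best[2] + d, times = length(d))
  keep <- k0 >= 0 & k1 >= 0 & k0 + k1 <= 1 + 1e-12
  Kf <- cbind(k0[keep], k1[keep], pmax(0, 1 - k0[keep] - k1[keep]))
  if (feasible_only) Kf <- Kf[Kf[, 2]^2 >= 4 * Kf[, 1] * Kf[, 3] - 1e-12, , drop = FALSE]
  llf <- kin_grid_loglik(A$A0, A$A1, A$A2, Kf)
  bf <- Kf[which.max(llf), ]
  structure(list(i = i, j = j, k0 = unname(bf[1]), k1 = unname(bf[2]),
                 k2 = unname(bf[3]), r = unname(bf[2] / 2 + bf[3]),
                 n_sites = n_sites, loglik = max(llf)),
            class = "kinship_estimate")
}

#' IBD estimates for every pair in a cohort
#'
#' @inheritParams estimate_k
#' @param on_too_few what to do with pairs below `n_min` overlapping sites:
#'   `"na"` (default) reports them with `NA` coefficients and degree
#'   `"no call"`, `"error"` propagates the error.
#' @return Data frame with one row per unordered pair: `id1`, `id2`, `k0`,
#'   `k1`, `k2`, `r`, `n_sites`, `loglik`, `degree`, `method`.
#' @export
estimate_k_all <- function(gls, panel, n_min = 1000L, feasible_only = FALSE,
                           sites = NULL, on_too_few = c("na", "error")) {
  on_too_few <- match.arg(on_too_few)
  ids <- rownames(gls$ll0)
  prs <- combn(ids, 2)
  rows <- lapply(seq_len(ncol(prs)), function(c) {
    i <- prs[1, c]; j <- prs[2, c]
    est <- tryCatch(estimate_k(gls, i, j, panel, n_min, feasible_only, sites),
                    paleokin_data_error = function(e) {
                      if (on_too_few == "error") stop(e)
                      NULL
                    })
    if (is.null(est)) {
      data.frame(id1 = i, id2 = j, k0 = NA_real_, k1 = NA_real_,
                 k2 = NA_real_, r = NA_real_, n_sites = NA_integer_,
                 loglik = NA_real_, degree = "no call",
                 method = "likelihood", stringsAsFactors = FALSE)
    } else {
      cl <- classify_degree(est)
      data.frame(id1 = i, id2 = j, k0 = est$k0, k1 = est$k1, k2 = est$k2,
                 r = est$r, n_sites = est$n_sites, loglik = est$loglik,
                 degree = cl$degree, method = "likelihood",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

# expected r per degree: identical 1, first 1/2, second 1/4, third 1/8;
# bin edges are geometric midpoints 2^-(d + 1/2)
.degree_edges <- 2^(-c(1, 3, 5, 7, 9) / 2)

#' Classify relationship degree from IBD coefficients
#'
#' Degrees are binned on `r = k1/2 + k2` at the geometric midpoints between
#' the expected `r` of adjacent degrees: identical above 0.7071, first
#' degree (0.3536, 0.7071], second (0.1768, 0.3536]. The third-degree bin
#' extends down to 0.0442 (the midpoint below the expected `r` of a
#' fourth-degree pair): low-coverage data cannot resolve degrees beyond the
#' third, so any weak but detectable relatedness is reported as third
#' rather than split into unresolvable higher degrees; below 0.0442 a pair
#' is unrelated. First degree splits into parent-offspring (`k0 < 0.1`)
#' versus siblings.
#'
#' @param estimate a `kinship_estimate` (or list with `k0`, `k1`, `k2`, `r`).
#' @return A `relationship_call` list with `degree` in
#'   `{"identical", "first (parent-offspring)", "first (siblings)",
#'     "second", "third", "unrelated"}` and `method = "likelihood"`.
#' @export
classify_degree <- function(estimate) {
  r <- estimate$r
  e <- .degree_edges
  degree <- if (r > e[1]) "identical"
    else if (r > e[2]) {
      if (estimate$k0 < 0.1) "first (parent-offspring)" else "first (siblings)"
    }
    else if (r > e[3]) "second"
    else if (r > e[5]) "third"
    else "unrelated"
  structure(list(i = estimate$i, j = estimate$j, degree = degree,
                 method = "likelihood"),
            class = "relationship_call")
}

#' Windowed pseudo-haploid mismatch profile for a pair
#'
#' Splits the jointly called sites into consecutive non-overlapping windows
#' of `window_sites` sites and reports the per-window mismatch proportion
#' `P0`, its mean and standard error, and (when a cohort `baseline` is
#' supplied) the normalized mismatch `mean P0 / baseline` — the statistic
#' used by mismatch-based relatedness classifiers.
#'
#' @param calls_i,calls_j pseudo-haploid call vectors (0/1/`NA`).
#' @param window_sites sites per window (>= 100).
#' @param baseline cohort baseline mismatch (median of pair means), or
#'   `NULL` to leave `normalized` as `NA`.
#' @return A `mismatch_profile` list: `p0_windows`, `mean_p0`, `se`,
#'   `normalized`, `n_sites`, `n_windows`.
#' @export
mismatch_profile <- function(calls_i, calls_j, window_sites = 5000L,
                             baseline = NULL) {
  if (window_sites < 100L) stop_param("window_sites must be >= 100")
  ok <- which(!is.na(calls_i) & !is.na(calls_j))
  if (!length(ok)) stop_data("no overlapping called sites for this pair")
  mm <- calls_i[ok] != calls_j[ok]
  nw <- length(ok) %/% window_sites
  if (nw < 1L) {
    # fewer sites than one window: use all sites as a single window
    nw <- 1L
    p0 <- mean(mm)
  } else {
    idx <- rep(seq_len(nw), each = window_sites)
    p0 <- tapply(mm[seq_along(idx)], idx, mean)
  }
  mean_p0 <- mean(p0)
  structure(list(p0_windows = as.numeric(p0), mean_p0 = mean_p0,
                 se = if (nw > 1) sd(p0) / sqrt(nw) else NA_real_,
                 normalized = if (is.null(baseline)) NA_real_
                              else mean_p0 / baseline,
                 n_sites = length(ok), n_windows = nw),
            class = "mismatch_profile")
}

#' Cohort-wide mismatch profiles with median normalization
#'
#' Computes [mismatch_profile()] for every pair and normalizes each pair's
#' mean mismatch by the cohort baseline, taken as the median of pair means
#' — valid when most pairs are unrelated, as in typical cemetery cohorts.
#'
#' @param calls individuals x sites matrix of pseudo-haploid calls.
#' @param window_sites sites per window.
#' @return List with `pairs` (data frame: `id1`, `id2`, `mean_p0`,
#'   `normalized`, `n_sites`, `degree`, `method`) and `baseline`.
#' @export
mismatch_cohort <- function(calls, window_sites = 5000L) {
  ids <- rownames(calls)
  prs <- combn(ids, 2)
  means <- numeric(ncol(prs)); nsites <- integer(ncol(prs))
  for (c in seq_len(ncol(prs))) {
    pr <- mismatch_profile(calls[prs[1, c], ], calls[prs[2, c], ], window_sites)
    means[c] <- pr$mean_p0; nsites[c] <- pr$n_sites
  }
  baseline <- median(means)
  if (baseline <= 0) stop_data("cohort mismatch baseline is zero")
  norm <- means / baseline
  degree <- vapply(norm, function(x) classify_mismatch_value(x), character(1))
  list(pairs = data.frame(id1 = prs[1, ], id2 = prs[2, ], mean_p0 = means,
                          normalized = norm, n_sites = nsites,
                          degree = degree, method = "mismatch",
                          stringsAsFactors = FALSE),
       baseline = baseline)
}

classify_mismatch_value <- function(x) {
  # geometric midpoints between expected normalized mismatch of
  # unrelated (1), first degree (0.875... see below) classes:
  # expectations 1, 0.875, 0.75, 0.5 -> cuts 0.90625, 0.8125, 0.625
  if (x >= 0.90625) "unrelated"
  else if (x >= 0.8125) "second"
  else if (x >= 0.625) "first"
  else "identical"
}

#' Classify relationship degree from a normalized mismatch profile
#'
#' Thresholds are midpoints between the expected normalized mismatch of
#' adjacent classes under pseudo-haploid sampling (unrelated 1, second
#' degree 0.875, first degree 0.75, identical 0.5): cuts at 0.90625,
#' 0.8125 and 0.625. Resolution stops at the second degree, as is typical
#' for mismatch-based classifiers on low-coverage data.
#'
#' @param profile a `mismatch_profile` with a finite `normalized` value.
#' @return A `relationship_call` with `method = "mismatch"`.
#' @export
classify_mismatch <- function(profile) {
  x <- profile$normalized
  if (!is.finite(x)) stop_data("profile has no normalized mismatch (baseline missing)")
  structure(list(degree = classify_mismatch_value(x), method = "mismatch"),
            class = "relationship_call")
}

#' Annotated relationship table for called-related pairs
#'
#' Joins called-related pairs with cemetery metadata, in the style of a
#' published kinship-results table, and lists the individuals with no
#' called relative.
#'
#' @param estimates data frame from [estimate_k_all()] (or any frame with
#'   `id1`, `id2`, `degree`).
#' @param metadata cemetery metadata with columns `individual`, `sex`,
#'   `age_class` (others are carried along if present).
#' @return List with `pairs` (annotated data frame of related pairs) and
#'   `unrelated` (character vector of individuals never called related).
#' @export
relationship_table <- function(estimates, metadata) {
  rel <- estimates[!estimates$degree %in% c("unrelated", "no call"), , drop = FALSE]
  ann <- function(ids, what) metadata[[what]][match(ids, metadata$individual)]
  pairs <- data.frame(
    id1 = rel$id1, id2 = rel$id2, degree = rel$degree,
    sex1 = ann(rel$id1, "sex"), age1 = ann(rel$id1, "age_class"),
    sex2 = ann(rel$id2, "sex"), age2 = ann(rel$id2, "age_class"),
    stringsAsFactors = FALSE
  )
  if (!is.null(rel$r)) pairs$r <- rel$r
  related_ids <- unique(c(rel$id1, rel$id2))
  list(pairs = pairs,
       unrelated = setdiff(metadata$individual, related_ids))
}
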