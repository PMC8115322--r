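#' Canonical pedigrees for pairwise-relationship simulations
#'
#' Builds a minimal pedigree realizing a given relationship between a
#' target pair, optionally padded with unrelated founders (useful as an
#' unrelated background when normalizing mismatch profiles).
#'
#' @param type relationship of the target pair.
#' @param extra_founders number of additional unrelated founders.
#' @return List with `ped` (a [pedigree_spec()]), `pair` (the two target
#'   IDs) and `truth` (the expected degree label at the resolution of
#'   [classify_degree()]).
#' @export
relationship_pedigree <- function(type = c("parent-offspring", "siblings",
                                           "half-siblings", "cousins",
                                           "unrelated"),
                                  extra_founders = 0L) {
  type <- match.arg(type)
  base <- switch(type,
    "parent-offspring" = list(
      id = c("F1", "M1", "C1"), father = c(NA, NA, "F1"),
      mother = c(NA, NA, "M1"), sex = c("M", "F", "F"),
      pair = c("F1", "C1"), truth = "first"),
    "siblings" = list(
      id = c("F1", "M1", "S1", "S2"), father = c(NA, NA, "F1", "F1"),
      mother = c(NA, NA, "M1", "M1"), sex = c("M", "F", "F", "M"),
      pair = c("S1", "S2"), truth = "first"),
    "half-siblings" = list(
      id = c("F1", "M1", "M2", "H1", "H2"),
      father = c(NA, NA, NA, "F1", "F1"),
      mother = c(NA, NA, NA, "M1", "M2"),
      sex = c("M", "F", "F", "M", "M"),
      pair = c("H1", "H2"), truth = "second"),
    "cousins" = list(
      id = c("GF", "GM", "A", "B", "SA", "SB", "C1", "C2"),
      father = c(NA, NA, "GF", "GF", NA, NA, "A", "SB"),
      mother = c(NA, NA, "GM", "GM", NA, NA, "SA", "B"),
      sex = c("M", "F", "M", "F", "F", "M", "F", "M"),
      pair = c("C1", "C2"), truth = "third"),
    "unrelated" = list(
      id = c("U1", "U2"), father = c(NA, NA), mother = c(NA, NA),
      sex = c("M", "F"), pair = c("U1", "U2"), truth = "unrelated"))
  if (extra_founders > 0) {
    xid <- paste0("X", seq_len(extra_founders))
    base$id <- c(base$id, xid)
    base$father <- c(base$father, rep(NA, extra_founders))
    base$mother <- c(base$mother, rep(NA, extra_founders))
    base$sex <- c(base$sex, rep(c("M", "F"), length.out = extra_founders))
  }
  list(ped = pedigree_spec(base$id, base$father, base$mother, base$sex),
       pair = base$pair, truth = base$truth)
}

# truth/degree labels collapsed to the degree level for comparisons
truth_level <- function(x) sub(" \\(.*\\)$", "", x)

#' Simulation study of relationship-degree recovery
#'
#' For each relationship class (parent-offspring, siblings, half-siblings,
#' cousins, unrelated) simulates `n_per_class` independent pairs at the
#' given coverage and error rate, estimates IBD coefficients by maximum
#' likelihood, and classifies each pair with both the likelihood and the
#' pseudo-haploid mismatch method. Each replicate cohort includes four
#' unrelated background founders so the mismatch baseline (median of pair
#' means) is dominated by unrelated pairs, as in a real cemetery cohort.
#'
#' @param n_per_class simulated pairs per relationship class.
#' @param n_sites panel size.
#' @param depth mean sequencing depth.
#' @param epsilon sequencing error rate.
#' @param seed integer master seed.
#' @param window_sites mismatch window size.
#' @return Data frame with one row per simulated pair: `class`, `truth`,
#'   `ml_degree`, `mm_degree`, `k0`, `k1`, `k2`, `r`, `n_sites`.
#' @export
kinship_recovery_experiment <- function(n_per_class = 50L, n_sites = 20000L,
                                        depth = 1, epsilon = 0.005,
                                        seed = 1L, window_sites = 1000L) {
  panel <- draw_frequency_panel(n_sites, 0.05, seed = sub_seed(seed, "panel"))
  em <- error_model(epsilon, 0)
  classes <- c("parent-offspring", "siblings", "half-siblings", "cousins",
               "unrelated")
  rows <- list()
  for (cl in classes) {
    setup <- relationship_pedigree(cl, extra_founders = 4L)
    cohort <- c(setup$pair, paste0("X", 1:4))
    for (rep in seq_len(n_per_class)) {
      tag <- paste0(cl, rep)
      gd <- gene_drop(setup$ped, panel, seed = sub_seed(seed, paste0("gd", tag)))
      pu <- simulate_pileups(gd$genotypes[cohort, , drop = FALSE], panel,
                             depth_mean = depth, error_rate = epsilon,
                             damage_rate = 0,
                             seed = sub_seed(seed, paste0("pu", tag)))
      gls <- genotype_likelihoods(pu, panel, em)
      est <- estimate_k(gls, setup$pair[1], setup$pair[2], panel)
      ml <- classify_degree(est)$degree
      calls <- majority_allele_call(pu, seed = sub_seed(seed, paste0("mc", tag)))
      mm <- mismatch_cohort(calls, window_sites = window_sites)
      hit <- (mm$pairs$id1 == setup$pair[1] & mm$pairs$id2 == setup$pair[2]) |
             (mm$pairs$id1 == setup$pair[2] & mm$pairs$id2 == setup$pair[1])
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, truth = setup$truth,
        ml_degree = ml, mm_degree = mm$pairs$degree[hit],
        k0 = est$k0, k1 = est$k1, k2 = est$k2, r = est$r,
        n_sites = est$n_sites, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summary metrics of a kinship-recovery experiment
#'
#' @param res result of [kinship_recovery_experiment()].
#' @return List: `accuracy` (degree-level classification accuracy over the
#'   classes of degree <= 2), `agreement` (fraction of degree <= 2 pairs on
#'   which the likelihood and mismatch classifiers give the same degree),
#'   `by_class` (per-class accuracy).
#' @export
kinship_recovery_summary <- function(res) {
  lev <- truth_level(res$ml_degree)
  close_deg <- res$truth %in% c("first", "second")
  by_class <- tapply(lev == res$truth, res$class, mean)
  list(accuracy = mean(lev[close_deg] == res$truth[close_deg]),
       agreement = mean(lev[close_deg] ==
                          truth_level(res$mm_degree)[close_deg]),
       by_class = by_class)
}

#' Simulation study of inbreeding-coefficient recovery
#'
#' Simulates a cohort of founders whose two allele copies are identical by
#' descent with probability `f_true` (so genotypes follow the
#' heterozygote-deficit model exactly), generates low-coverage damaged
#' pileups, filters sites, and estimates `F` back by MCMC.
#'
#' @param f_true true inbreeding coefficient.
#' @param n_ind cohort size.
#' @param n_sites panel size.
#' @param depth mean depth.
#' @param epsilon,delta error-model parameters.
#' @param iterations,burnin MCMC settings.
#' @param seed integer master seed.
#' @return An `inbreeding_estimate` (see [estimate_inbreeding()]).
#' @export
inbreeding_recovery_experiment <- function(f_true = 0, n_ind = 20L,
                                           n_sites = 50000L, depth = 2,
                                           epsilon = 0.005, delta = 0.02,
                                           iterations = 1e5, burnin = 5000,
                                           seed = 1L) {
  panel <- draw_frequency_panel(n_sites, 0.05, seed = sub_seed(seed, "panel"))
  ids <- sprintf("I%02d", seq_len(n_ind))
  ped <- pedigree_spec(ids, sex = rep(c("F", "M"), length.out = n_ind),
                       f_founder = f_true)
  gd <- gene_drop(ped, panel, seed = sub_seed(seed, "gd"))
  pu <- simulate_pileups(gd$genotypes, panel, depth_mean = depth,
                         error_rate = epsilon, damage_rate = delta,
                         seed = sub_seed(seed, "pu"))
  gls <- genotype_likelihoods(pu, panel, error_model(epsilon, delta))
  mask <- site_filter(panel, gls, maf_min = 0.05, min_depth = 2L,
                      min_samples = min(10L, n_ind))
  estimate_inbreeding(gls, panel, sites = mask, iterations = iterations,
                      burnin = burnin, seed = sub_seed(seed, "mcmc"))
}

#' Hudson's F_ST across random splits of one panmictic cohort
#'
#' Simulates a single unstructured cohort and computes the genome-wide
#' Hudson F_ST for random half splits; under panmixia the estimator is
#' unbiased around zero.
#'
#' @param n_ind cohort size (split into halves).
#' @param n_sites panel size.
#' @param n_splits number of random splits.
#' @param seed integer master seed.
#' @return Numeric vector of per-split F_ST estimates.
#' @export
fst_panmixia_experiment <- function(n_ind = 24L, n_sites = 20000L,
                                    n_splits = 200L, seed = 1L) {
  panel <- draw_frequency_panel(n_sites, 0.05, seed = sub_seed(seed, "panel"))
  ids <- sprintf("I%02d", seq_len(n_ind))
  ped <- pedigree_spec(ids, sex = rep(c("F", "M"), length.out = n_ind))
  gd <- gene_drop(ped, panel, seed = sub_seed(seed, "gd"))
  g <- gd$genotypes
  with_seed(sub_seed(seed, "splits"), {
    vapply(seq_len(n_splits), function(k) {
      half <- sample(n_ind, n_ind %/% 2)
      hudson_fst_genotypes(g[half, , drop = FALSE],
                           g[-half, , drop = FALSE])$fst
    }, numeric(1))
  })
}
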