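test_that("pair log-likelihood matches brute-force enumeration and limits", {
  # two-site toy with explicit likelihoods vs nine-term enumeration
  panel <- panel_const(c(0.5, 0.5))
  Li <- rbind(c(0.8, 0.15, 0.05), c(0.1, 0.6, 0.3))
  Lj <- rbind(c(0.2, 0.5, 0.3), c(0.05, 0.15, 0.8))
  gls <- structure(list(
    ll0 = rbind(i = log(Li[, 1]), j = log(Lj[, 1])),
    ll1 = rbind(i = log(Li[, 2]), j = log(Lj[, 2])),
    ll2 = rbind(i = log(Li[, 3]), j = log(Lj[, 3])),
    coverage = matrix(1L, 2, 2, dimnames = list(c("i", "j"), panel$site_id)),
    site_id = panel$site_id), class = "gl_set")
  dimnames(gls$ll0) <- dimnames(gls$ll1) <- dimnames(gls$ll2) <-
    list(c("i", "j"), panel$site_id)
  for (k in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.2, 0.5, 0.3))) {
    expect_equal(pair_loglikelihood(gls, "i", "j", panel, k),
                 brute_pair_loglik(Li, Lj, panel$p, k))
  }
  expect_error(pair_loglikelihood(gls, "i", "j", panel, c(0.5, 0.5, 0.5)),
               class = "paleokin_parameter_error")

  # at k = (1,0,0) with hard calls the likelihood factorizes into
  # independent Hardy-Weinberg genotype probabilities
  panel2 <- panel_const(runif(200, 0.1, 0.9))
  set.seed(3)
  g <- matrix(rbinom(2 * 200, 2, rep(panel2$p, each = 2)), 2, 200,
              dimnames = list(c("a", "b"), panel2$site_id))
  glh <- gl_hard(g)
  hw <- function(g, p) ifelse(g == 0, (1 - p)^2,
                              ifelse(g == 1, 2 * p * (1 - p), p^2))
  expected <- sum(log(hw(g["a", ], panel2$p))) + sum(log(hw(g["b", ], panel2$p)))
  expect_equal(pair_loglikelihood(glh, "a", "b", panel2, c(1, 0, 0)), expected)

  # identical data favour k = (0,0,1) over k = (1,0,0)
  gsame <- rbind(a = g[1, ], b = g[1, ])
  glsame <- gl_hard(gsame)
  expect_gt(pair_loglikelihood(glsame, "a", "b", panel2, c(0, 0, 1)),
            pair_loglikelihood(glsame, "a", "b", panel2, c(1, 0, 0)))
})

test_that("IBD coefficients are recovered for simulated pairs", {
  panel <- draw_frequency_panel(20000, seed = 21)
  em <- error_model(0.005, 0)
  po <- relationship_pedigree("parent-offspring")
  gd <- gene_drop(po$ped, panel, seed = 22)
  pu <- simulate_pileups(gd$genotypes, panel, depth_mean = 1,
                         error_rate = 0.005, damage_rate = 0, seed = 23)
  gls <- genotype_likelihoods(pu, panel, em)
  est <- estimate_k(gls, "F1", "C1", panel)
  # the grid optimum can never fall below the likelihood at the truth
  ov <- gls$coverage["F1", ] > 0 & gls$coverage["C1", ] > 0
  expect_gte(est$loglik,
             pair_loglikelihood(gls, "F1", "C1", panel, c(0, 1, 0), ov))
  expect_gte(est$k1, 0.8)
  expect_lt(abs(est$k0 - 0) + abs(est$k1 - 1) + abs(est$k2 - 0), 0.4)
  expect_equal(est$k0 + est$k1 + est$k2, 1, tolerance = 1e-9)

  est_un <- estimate_k(gls, "F1", "M1", panel)
  expect_gte(est_un$k0, 0.85)

  # a self-comparison at high depth is called identical
  pu2 <- simulate_pileups(gd$genotypes, panel, depth_mean = 8,
                          error_rate = 0.005, damage_rate = 0, seed = 24)
  gls2 <- genotype_likelihoods(pu2, panel, em)
  two <- structure(list(ll0 = gls2$ll0[c(1, 1), ], ll1 = gls2$ll1[c(1, 1), ],
                        ll2 = gls2$ll2[c(1, 1), ],
                        coverage = gls2$coverage[c(1, 1), ],
                        site_id = gls2$site_id), class = "gl_set")
  rn <- c("self1", "self2")
  for (f in c("ll0", "ll1", "ll2", "coverage")) rownames(two[[f]]) <- rn
  est_self <- estimate_k(two, "self1", "self2", panel)
  expect_gte(est_self$k2, 0.95)

  # too little overlap raises an informative error naming the pair
  expect_error(estimate_k(gls, "F1", "C1", panel, n_min = 1e6),
               "F1.*C1", class = "paleokin_data_error")
})

test_that("degree classification uses the geometric bin edges", {
  call_of <- function(k0, k1, k2) {
    classify_degree(list(i = "a", j = "b", k0 = k0, k1 = k1, k2 = k2,
                         r = k1 / 2 + k2))$degree
  }
  expect_equal(call_of(0, 1, 0), "first (parent-offspring)")
  expect_equal(call_of(0.25, 0.5, 0.25), "first (siblings)")
  expect_equal(call_of(0.5, 0.5, 0), "second")
  # r = 0.0625 sits between the third-degree edges 0.0442 and 0.0884
  expect_equal(call_of(0.875, 0.125, 0), "third")
  expect_equal(call_of(1, 0, 0), "unrelated")
  expect_equal(call_of(0, 0, 1), "identical")
})

test_that("mismatch profiles hit the closed-form extremes and expectations", {
  a <- rep(0L, 1000)
  expect_equal(mismatch_profile(a, a, 100)$mean_p0, 0)
  expect_equal(mismatch_profile(a, 1L - a, 100)$mean_p0, 1)
  expect_error(mismatch_profile(a, rep(NA_integer_, 1000), 100),
               class = "paleokin_data_error")
  expect_error(mismatch_profile(a, a, 50), class = "paleokin_parameter_error")

  # a parent-offspring pair in a mostly unrelated cohort sits near the
  # pseudo-haploid expectation of 0.75 of the unrelated baseline
  panel <- draw_frequency_panel(20000, seed = 31)
  po <- relationship_pedigree("parent-offspring", extra_founders = 8)
  gd <- gene_drop(po$ped, panel, seed = 32)
  cohort <- c("F1", "C1", paste0("X", 1:8))
  pu <- simulate_pileups(gd$genotypes[cohort, ], panel, depth_mean = 2,
                         error_rate = 0.005, damage_rate = 0, seed = 33)
  calls <- majority_allele_call(pu, seed = 34)
  mc <- mismatch_cohort(calls, window_sites = 1000)
  target <- mc$pairs$normalized[mc$pairs$id1 == "F1" & mc$pairs$id2 == "C1"]
  expect_lt(abs(target - 0.75), 0.05)
  expect_equal(mc$pairs$degree[mc$pairs$id1 == "F1" & mc$pairs$id2 == "C1"],
               "first")
})

test_that("mismatch classification uses the midpoint thresholds", {
  cls <- function(x) classify_mismatch(
    structure(list(normalized = x), class = "mismatch_profile"))$degree
  expect_equal(cls(1.0), "unrelated")
  expect_equal(cls(0.91), "unrelated")
  expect_equal(cls(0.85), "second")
  expect_equal(cls(0.75), "first")
  expect_equal(cls(0.5), "identical")
})

test_that("mean mismatch increases with the true share of non-IBD sites", {
  panel <- draw_frequency_panel(8000, seed = 41)
  classes <- c("parent-offspring", "siblings", "half-siblings", "cousins",
               "unrelated")
  mean_p0 <- vapply(seq_along(classes), function(ci) {
    setup <- relationship_pedigree(classes[ci])
    reps <- vapply(1:3, function(r) {
      gd <- gene_drop(setup$ped, panel, seed = 100 * ci + r)
      pu <- simulate_pileups(gd$genotypes[setup$pair, ], panel,
                             depth_mean = 2, error_rate = 0.005,
                             damage_rate = 0, seed = 200 * ci + r)
      calls <- majority_allele_call(pu, seed = 300 * ci + r)
      mismatch_profile(calls[1, ], calls[2, ], 1000)$mean_p0
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  # expected k0: PO 0 < sib 0.25 < half-sib 0.5 < cousin 0.75 < unrelated 1
  expect_true(all(diff(mean_p0) > 0))
})

test_that("relationship tables annotate pairs and list isolated individuals", {
  meta <- mokrin_meta()
  pairs <- mokrin_pairs()
  pairs$method <- "fixture"
  tab <- relationship_table(pairs, meta)
  expect_equal(nrow(tab$pairs), 9)
  expect_equal(length(unique(c(tab$pairs$id1, tab$pairs$id2))), 15)
  expect_equal(length(tab$unrelated), 9)
  expect_equal(tab$pairs$sex1[tab$pairs$id1 == "257A"][1], "XX")

  empty <- relationship_table(pairs[0, ], meta)
  expect_equal(nrow(empty$pairs), 0)
  expect_equal(sort(empty$unrelated), sort(meta$individual))

  one <- relationship_table(pairs[1, ], meta)
  expect_equal(nrow(one$pairs), 1)
  expect_equal(length(unique(c(one$pairs$id1, one$pairs$id2))), 2)
})
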