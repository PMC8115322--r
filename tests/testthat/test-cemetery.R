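test_that("same-group pair counting handles the bundled cohort and edge cases", {
  groups <- mokrin_groups()
  pairs <- mokrin_pairs()[, c("id1", "id2")]
  expect_equal(same_group_pair_count(pairs, groups), 8L)

  one_group <- setNames(rep("G", 24), names(groups))
  expect_equal(same_group_pair_count(pairs, one_group), nrow(pairs))
  own_group <- setNames(paste0("g", seq_along(groups)), names(groups))
  expect_equal(same_group_pair_count(pairs, own_group), 0L)
  expect_error(same_group_pair_count(rbind(c("nobody", "161")), groups),
               "nobody", class = "paleokin_data_error")
})

test_that("spatial permutation test matches its conventions", {
  groups <- mokrin_groups()
  # no pairs: observed zero, p = 1
  none <- spatial_kin_permutation(mokrin_pairs()[0, 1:2], groups,
                                  n_perm = 1000, seed = 1)
  expect_equal(none$observed, 0L)
  expect_equal(none$p, 1)
  # degenerate single group warns and returns p = 1
  one_group <- setNames(rep("G", 24), names(groups))
  expect_warning(res <- spatial_kin_permutation(mokrin_pairs()[, 1:2],
                                                one_group, 1000, seed = 1),
                 "degenerate")
  expect_equal(res$p, 1)
  expect_error(spatial_kin_permutation(mokrin_pairs()[, 1:2], groups,
                                       n_perm = 10, seed = 1),
               class = "paleokin_parameter_error")
  # invariance to group relabelling (same seed, identical permutations)
  relab <- setNames(c(NE = "g1", NW = "g2", SE = "g3", SW = "g4")[groups],
                    names(groups))
  a <- spatial_kin_permutation(mokrin_pairs()[, 1:2], groups, 5000, seed = 3)
  b <- spatial_kin_permutation(mokrin_pairs()[, 1:2], relab, 5000, seed = 3)
  expect_equal(a$p, b$p)
  expect_equal(a$observed, b$observed)
})

test_that("permutation p-values agree with exact enumeration", {
  instances <- list(
    list(assignment = setNames(c("A", "A", "B", "B"), c("p", "q", "r", "s")),
         pairs = rbind(c("p", "q"))),
    list(assignment = setNames(rep(c("A", "B", "C"), each = 2),
                               letters[1:6]),
         pairs = rbind(c("a", "b"), c("c", "e"))),
    list(assignment = setNames(rep(c("A", "B"), each = 4), letters[1:8]),
         pairs = rbind(c("a", "b"), c("a", "c"), c("e", "h")))
  )
  for (ins in instances) {
    ex <- exact_pair_statistic_null(ins$pairs, ins$assignment)
    mc <- spatial_kin_permutation(ins$pairs, ins$assignment, n_perm = 2e4,
                                  seed = 9)
    se <- sqrt(ex$p_exact * (1 - ex$p_exact) / mc$n_perm)
    expect_lt(abs(mc$p - ex$p_exact), 3 * se + 2 / mc$n_perm)
  }
  # hand enumeration: 4 individuals in two groups of 2, one pair ->
  # of the 6 distinct splits, 2 put both members together
  ex <- exact_pair_statistic_null(rbind(c("p", "q")),
                                  setNames(c("A", "A", "B", "B"),
                                           c("p", "q", "r", "s")))
  expect_equal(ex$p_exact, 1 / 3)
  expect_equal(ex$n_assignments, 6)
  # refuses instances too large to enumerate
  big <- setNames(rep(c("A", "B"), each = 15), sprintf("i%d", 1:30))
  expect_error(exact_pair_statistic_null(rbind(c("i1", "i2")), big,
                                         max_assignments = 1e5),
               class = "paleokin_parameter_error")
})

test_that("composition probability is exact hypergeometric arithmetic", {
  expect_equal(composition_probability(24, 14, 9), 2002 / 1307504)
  expect_equal(composition_probability(10, 10, 5), 1)
  expect_error(composition_probability(10, 4, 5),
               class = "paleokin_parameter_error")
  # Monte-Carlo cross-check of the all-carrier subset probability
  set.seed(5)
  hits <- replicate(2e5, all(sample(rep(c(TRUE, FALSE), c(14, 10)), 9)))
  p_hat <- mean(hits)
  se <- sqrt(p_hat * (1 - p_hat) / 2e5)
  expect_lt(abs(composition_probability(24, 14, 9) - p_hat), 3 * se)
})

test_that("status concordance counts evaluable dyads only", {
  meta <- mokrin_meta()
  res <- status_concordance(mokrin_pairs(), meta)
  expect_equal(res$n_concordant, 2L)
  # statuses are recorded only where the source states them: both dyads
  # involving 257B and the sibling dyad 122E-211 lack one side
  expect_equal(res$n_discordant, 4L)
  expect_equal(res$n_excluded, 3L)
  conc <- res$dyads[which(res$dyads$concordant), ]
  expect_setequal(paste(conc$id1, conc$id2),
                  c("163 181", "220 225"))

  all_same <- data.frame(id1 = c("220", "163"), id2 = c("225", "181"))
  expect_equal(status_concordance(all_same, meta)$n_concordant, 2L)
  empty <- status_concordance(mokrin_pairs()[0, ], meta)
  expect_equal(empty$n_concordant, 0L)
  expect_equal(nrow(empty$dyads), 0L)
})

test_that("cohort summaries count related and isolated individuals", {
  meta <- mokrin_meta()
  summ <- summarize_cohort(mokrin_pairs(), meta)
  expect_equal(summ$n_related, 15L)
  expect_equal(summ$n_unrelated, 9L)
  expect_equal(unname(summ$unrelated_sex[["XX"]]), 9L)
  expect_equal(sum(summ$pairs_by_degree), 9L)

  trio_meta <- data.frame(individual = c("a", "b", "c"),
                          sex = c("XY", "XX", "XX"))
  po <- data.frame(id1 = "a", id2 = "b", degree = "first (parent-offspring)")
  s2 <- summarize_cohort(po, trio_meta)
  expect_equal(s2$n_related, 2L)
  expect_equal(s2$n_unrelated, 1L)
  s3 <- summarize_cohort(po[0, ], trio_meta)
  expect_equal(s3$n_related, 0L)
  expect_equal(s3$n_unrelated, 3L)
})
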