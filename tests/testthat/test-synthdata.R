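test_that("frequency panels honour the MAF filter and reject impossible ones", {
  panel <- draw_frequency_panel(1000, maf_min = 0.05, seed = 1)
  expect_true(all(panel$p >= 0.05 & panel$p <= 0.95))
  expect_false(anyDuplicated(panel$site_id) > 0)
  expect_true(all(diff(panel$pos) > 0))
  expect_error(draw_frequency_panel(100, maf_min = 0.5), class = "paleokin_parameter_error")
  expect_error(draw_frequency_panel(0), class = "paleokin_parameter_error")
})

test_that("panel MAF distribution matches the truncated-Beta expectation", {
  panel <- draw_frequency_panel(10000, maf_min = 0.05, seed = 7)
  maf <- pmin(panel$p, 1 - panel$p)
  # oracle: numeric integration of min(p, 1-p) under Beta(0.8, 0.8)
  # truncated to [0.05, 0.95]
  dens <- function(p) dbeta(p, 0.8, 0.8)
  z <- integrate(dens, 0.05, 0.95)$value
  expected <- integrate(function(p) pmin(p, 1 - p) * dens(p) / z, 0.05, 0.95)$value
  se <- sd(maf) / sqrt(length(maf))
  expect_lt(abs(mean(maf) - expected), 3 * se)
})

test_that("panel draws are reproducible for a fixed seed", {
  expect_identical(draw_frequency_panel(500, seed = 42),
                   draw_frequency_panel(500, seed = 42))
  ped <- relationship_pedigree("siblings")$ped
  panel <- draw_frequency_panel(200, seed = 1)
  expect_identical(gene_drop(ped, panel, seed = 9),
                   gene_drop(ped, panel, seed = 9))
})

test_that("pedigree validation catches malformed structures", {
  expect_error(pedigree_spec(c("a", "a"), sex = c("M", "F")),
               class = "paleokin_data_error")
  expect_error(pedigree_spec(c("a", "b"), father = c(NA, "zz"),
                             mother = c(NA, "a"), sex = c("F", "M")),
               class = "paleokin_data_error")
  # one parent only
  expect_error(pedigree_spec(c("a", "b"), father = c(NA, "a"),
                             mother = c(NA, NA), sex = c("M", "M")),
               class = "paleokin_data_error")
  # parents of the same sex
  expect_error(pedigree_spec(c("a", "b", "c"), father = c(NA, NA, "a"),
                             mother = c(NA, NA, "b"), sex = c("M", "M", "F")),
               class = "paleokin_data_error")
})

test_that("founder genotypes follow Hardy-Weinberg at p = 0.5", {
  panel <- panel_const(rep(0.5, 1e5))
  ped <- pedigree_spec("solo", sex = "F")
  gd <- gene_drop(ped, panel, seed = 3)
  het <- mean(gd$genotypes == 1L)
  expect_lt(abs(het - 0.5), 0.005)
})

test_that("gene dropping is Mendelian and tracks IBD exactly", {
  panel <- draw_frequency_panel(1e5, seed = 5)
  po <- relationship_pedigree("parent-offspring")
  gd <- gene_drop(po$ped, panel, seed = 11)
  g <- gd$genotypes
  # no opposite homozygotes between parent and child
  expect_equal(sum(g["F1", ] == 0 & g["C1", ] == 2), 0)
  expect_equal(sum(g["F1", ] == 2 & g["C1", ] == 0), 0)
  # parent-offspring pairs share exactly one allele IBD everywhere
  expect_true(all(ibd_states(gd, "F1", "C1") == 1L))

  sib <- relationship_pedigree("siblings")
  gds <- gene_drop(sib$ped, panel, seed = 13)
  st <- ibd_states(gds, "S1", "S2")
  frac <- tabulate(st + 1L, 3) / length(st)
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / length(st))
  expect_true(all(abs(frac - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("uniparental lineages are inherited along the correct lines", {
  ped <- ped_study_like()
  panel <- draw_frequency_panel(100, seed = 2)
  gd <- gene_drop(ped, panel, seed = 4)
  fa <- setNames(ped$father, ped$id)
  mo <- setNames(ped$mother, ped$id)
  for (id in ped$id[!is.na(mo)]) {
    expect_identical(gd$mt_lineage[[id]], gd$mt_lineage[[mo[[id]]]])
    if (ped$sex[ped$id == id] == "M") {
      expect_identical(gd$y_lineage[[id]], gd$y_lineage[[fa[[id]]]])
    }
  }
  expect_true(all(is.na(gd$y_lineage[ped$sex == "F"])))
})

test_that("pileup simulation respects depth, noise-free limits, and read sampling", {
  panel <- panel_const(rep(0.5, 2000))
  g <- matrix(0L, 1, 2000, dimnames = list("i1", panel$site_id))
  # depth 0 -> empty pileup
  pu0 <- simulate_pileups(g, panel, depth_mean = 0, seed = 1)
  expect_true(all(pu0$n_ref + pu0$n_alt == 0))
  # noise-free homozygote -> no alt reads
  pu <- simulate_pileups(g, panel, depth_mean = 3, error_rate = 0,
                         damage_rate = 0, seed = 2)
  expect_true(all(pu$n_alt == 0))
  expect_error(simulate_pileups(g, panel, depth_mean = -1),
               class = "paleokin_parameter_error")

  # heterozygote read sampling: alt-read fraction 1/2 within binomial error
  panel2 <- panel_const(rep(0.5, 1e5))
  gh <- matrix(1L, 1, 1e5, dimnames = list("i1", panel2$site_id))
  puh <- simulate_pileups(gh, panel2, depth_mean = 2, error_rate = 0.01,
                          damage_rate = 0, seed = 3)
  n_tot <- sum(puh$n_ref + puh$n_alt)
  frac <- sum(puh$n_alt) / n_tot
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_tot))
})

test_that("cemetery simulation respects pedigree structure and scenarios", {
  sib <- relationship_pedigree("siblings", extra_founders = 4)
  scen <- list(group_sizes = c(4, 4), kin_group_prob = 1)
  meta <- simulate_cemetery(sib$ped, scen, seed = 6)
  grp <- setNames(meta$group, meta$individual)
  # forced clustering: the whole family shares one group
  fam <- c("F1", "M1", "S1", "S2")
  expect_equal(length(unique(grp[fam])), 1L)
  # sexes and uniparental labels consistent with the pedigree
  expect_equal(unname(meta$sex[meta$individual == "F1"]), "XY")
  expect_identical(meta$mt_haplotype[meta$individual == "S1"],
                   meta$mt_haplotype[meta$individual == "M1"])
  expect_identical(meta$y_haplotype[meta$individual == "S2"],
                   meta$y_haplotype[meta$individual == "F1"])
  expect_true(all(is.na(meta$y_haplotype[meta$sex == "XX"])))
  # group sizes must sum to the cohort size
  expect_error(simulate_cemetery(sib$ped, list(group_sizes = c(4, 3)), seed = 1),
               class = "paleokin_parameter_error")
  # in-migrants carry novel mitochondrial labels
  scen2 <- list(group_sizes = c(5, 5), kin_group_prob = 0.5, n_inmigrants = 2)
  meta2 <- simulate_cemetery(sib$ped, scen2, seed = 8)
  mig <- grepl("^MIG", meta2$individual)
  expect_equal(sum(mig), 2L)
  expect_false(any(meta2$mt_haplotype[mig] %in% meta2$mt_haplotype[!mig]))
  expect_true(all(meta2$sex[mig] == "XX"))
})

test_that("study-like cohorts give the spatial permutation test high power", {
  ped <- ped_study_like()
  scen <- list(group_sizes = c(3, 4, 5, 12), kin_group_prob = 0.95,
               n_inmigrants = 9, include = study_like_sampled)
  n_rep <- 200
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    meta <- simulate_cemetery(ped, scen, seed = 1000 + r)
    grp <- setNames(meta$group, meta$individual)
    res <- spatial_kin_permutation(study_like_pairs, grp, n_perm = 1999,
                                   seed = 5000 + r)
    reject[r] <- res$p <= 0.01
  }
  expect_gte(mean(reject), 0.95)
})
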