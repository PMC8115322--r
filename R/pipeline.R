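#' Run the full kinship and cemetery analysis pipeline
#'
#' Executes the stages in order — simulate or load inputs, genotype
#' likelihoods and site filtering, pairwise kinship by both the
#' maximum-likelihood and the mismatch method, cohort statistics, and the
#' cemetery social-structure tests — and writes TSV tables plus a JSON
#' report. Every stochastic stage derives its randomness from the single
#' master seed via [sub_seed()]; rerunning with the same configuration and
#' seed reproduces the report exactly.
#'
#' The configuration is a named list (or the path to a YAML file with the
#' same structure):
#' \describe{
#'   \item{seed}{integer master seed (required for stochastic stages).}
#'   \item{out_dir}{output directory (created if missing); omit to skip
#'     writing files.}
#'   \item{simulate}{list passed to the synthetic generator: `n_sites`,
#'     `maf_min`, `pedigree` (a [pedigree_spec()]), `depth_mean`,
#'     `error_rate`, `damage_rate`, `scenario` (see
#'     [simulate_cemetery()]).}
#'   \item{panel, pileups, metadata, pairs}{input TSV paths when not
#'     simulating. `pairs` + `metadata` alone run just the cemetery
#'     stage.}
#'   \item{error_model}{list `epsilon`, `delta`.}
#'   \item{filter}{list `maf_min`, `min_depth`, `min_samples`.}
#'   \item{kinship}{list `n_min`, `window_sites`.}
#'   \item{cemetery}{list `n_perm`.}
#'   \item{inbreeding}{list `iterations`, `burnin`, or `NULL` to skip.}
#' }
#'
#' @param config named list or YAML path.
#' @return The report as a nested list (also written to
#'   `out_dir/report.json` when `out_dir` is set), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_param("config must be a list or a YAML path")
  seed <- config$seed
  if (is.null(seed)) stop_param("config$seed is required")
  report <- list(tool = "paleokin",
                 version = as.character(packageVersion("paleokin")),
                 seed = seed,
                 config_hash = config_hash(config))

  have_geno <- !is.null(config$simulate) ||
    (!is.null(config$panel) && !is.null(config$pileups))

  panel <- NULL; pileup <- NULL; meta <- NULL; gd <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    panel <- draw_frequency_panel(sim$n_sites %||% 20000L,
                                  sim$maf_min %||% 0.05,
                                  seed = sub_seed(seed, "panel"))
    ped <- sim$pedigree
    if (is.null(ped)) stop_param("simulate stage needs a pedigree")
    gd <- gene_drop(ped, panel, seed = sub_seed(seed, "genedrop"))
    pileup <- simulate_pileups(gd$genotypes, panel,
                               depth_mean = sim$depth_mean %||% 0.85,
                               error_rate = sim$error_rate %||% 0.005,
                               damage_rate = sim$damage_rate %||% 0.02,
                               seed = sub_seed(seed, "pileup"))
    if (!is.null(sim$scenario)) {
      meta <- simulate_cemetery(ped, sim$scenario,
                                seed = sub_seed(seed, "cemetery"))
    }
    report$simulate <- list(n_sites = nrow(panel),
                            n_individuals = nrow(ped))
  } else {
    if (!is.null(config$panel)) panel <- read_panel_tsv(config$panel)
    if (!is.null(config$pileups)) pileup <- read_pileup_tsv(config$pileups, panel)
    if (!is.null(config$metadata)) meta <- read_tsv_(config$metadata)
  }

  pairs_tab <- NULL
  if (have_geno) {
    em <- error_model(config$error_model$epsilon %||% 0.005,
                      config$error_model$delta %||% 0.02)
    gls <- genotype_likelihoods(pileup, panel, em)
    calls <- majority_allele_call(pileup, seed = sub_seed(seed, "calls"))
    flt <- config$filter
    mask <- site_filter(panel, gls, flt$maf_min %||% 0.05,
                        flt$min_depth %||% 1L, flt$min_samples %||% 2L)
    report$filter <- list(n_sites = length(mask), n_pass = sum(mask))
    kn <- config$kinship
    ml <- estimate_k_all(gls, panel, n_min = kn$n_min %||% 1000L,
                         sites = mask)
    mm <- mismatch_cohort(calls, window_sites = kn$window_sites %||% 5000L)
    pairs_tab <- ml
    report$kinship <- list(
      n_pairs = nrow(ml),
      n_called_related = sum(!ml$degree %in% c("unrelated", "no call")),
      mismatch_baseline = mm$baseline,
      method_agreement = mean(degree_level(ml$degree) ==
                                degree_level(mm$pairs$degree))
    )
    report$popstats <- list(
      inbreeding = if (!is.null(config$inbreeding)) {
        ib <- estimate_inbreeding(gls, panel, sites = mask,
                                  iterations = config$inbreeding$iterations %||% 1e5,
                                  burnin = config$inbreeding$burnin %||% 5000,
                                  seed = sub_seed(seed, "inbreeding"))
        list(F = ib$F, lo = ib$lo, hi = ib$hi, acceptance = ib$acceptance)
      }
    )
  } else if (!is.null(config$pairs)) {
    pairs_tab <- read_tsv_(config$pairs)
  }

  if (!is.null(meta)) {
    if (!is.null(meta$mt_haplotype)) {
      report$popstats$mt_diversity <- haplotype_diversity(meta$mt_haplotype)
      report$popstats$n_mt_haplotypes <-
        length(unique(stats::na.omit(meta$mt_haplotype)))
    }
    yh <- meta$y_haplotype
    if (!is.null(yh) && sum(!is.na(yh)) >= 2) {
      report$popstats$y_diversity <- haplotype_diversity(yh)
      report$popstats$n_y_haplotypes <- length(unique(stats::na.omit(yh)))
    }
  }

  if (!is.null(pairs_tab) && !is.null(meta)) {
    rel <- relationship_table(pairs_tab, meta)
    assignment <- setNames(meta$group, meta$individual)
    pm <- spatial_kin_permutation(rel$pairs[, c("id1", "id2")], assignment,
                                  n_perm = config$cemetery$n_perm %||% 1e5,
                                  seed = sub_seed(seed, "permutation"))
    summ <- summarize_cohort(rel$pairs, meta)
    conc <- status_concordance(rel$pairs, meta)
    report$cemetery <- list(
      same_group_pairs = pm$observed,
      n_perm = pm$n_perm,
      p_value = pm$p,
      perm_seed = pm$seed,
      null_mean = pm$null_mean,
      n_related = summ$n_related,
      n_unrelated = summ$n_unrelated,
      unrelated_sex = as.list(summ$unrelated_sex),
      status_concordant = conc$n_concordant,
      status_discordant = conc$n_discordant,
      status_excluded = conc$n_excluded
    )
    if (summ$n_unrelated > 0 && length(summ$unrelated_sex) > 0) {
      dominant <- max(summ$unrelated_sex)
      n_attr <- sum(meta$sex == names(which.max(summ$unrelated_sex)),
                    na.rm = TRUE)
      if (dominant == summ$n_unrelated) {
        report$cemetery$uniform_sex_probability <-
          composition_probability(nrow(meta), n_attr, summ$n_unrelated)
      }
    }
  }

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(panel)) write_panel_tsv(panel, file.path(out_dir, "panel.tsv"))
    if (!is.null(pairs_tab)) write_tsv_(pairs_tab, file.path(out_dir, "pairs.tsv"))
    if (!is.null(meta)) write_tsv_(as.data.frame(meta),
                                   file.path(out_dir, "metadata.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(report)
}

# collapse sub-labels so the likelihood and mismatch classifiers can be
# compared at the degree level ("first (siblings)" -> "first"; mismatch
# cannot resolve the third degree, so "third" counts as "unrelated")
degree_level <- function(x) {
  x <- sub(" \\(.*\\)$", "", x)
  x[x == "third"] <- "unrelated"
  x
}

config_hash <- function(config) {
  config$out_dir <- NULL
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967296)
}
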