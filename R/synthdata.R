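#' Define a pedigree for gene-dropping simulation
#'
#' A pedigree is a table of individuals with optional parent links. Founders
#' have both parents `NA`; every non-founder must have both parents present
#' in the table, of opposite sex. Individuals may be flagged as in-migrants
#' (used by [simulate_cemetery()] to assign novel mitochondrial lineages,
#' emulating female exogamy).
#'
#' @param id character vector of unique individual IDs.
#' @param father,mother character vectors of parent IDs (`NA` for founders).
#' @param sex character vector, `"M"` or `"F"`.
#' @param f_founder founder inbreeding coefficient in `[0, 1)`: probability
#'   that a founder's two allele copies are identical by descent.
#' @return A `pedigree_spec` data frame ordered so parents precede children.
#' @examples
#' trio <- pedigree_spec(c("dad", "mum", "kid"),
#'                       father = c(NA, NA, "dad"),
#'                       mother = c(NA, NA, "mum"),
#'                       sex    = c("M", "F", "F"))
#' @export
pedigree_spec <- function(id, father = NA, mother = NA, sex, f_founder = 0) {
  n <- length(id)
  ped <- data.frame(id = as.character(id),
                    father = as.character(rep_len(father, n)),
                    mother = as.character(rep_len(mother, n)),
                    sex = as.character(rep_len(sex, n)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop_data("pedigree IDs must be unique")
  if (!all(ped$sex %in% c("M", "F"))) stop_param("sex must be 'M' or 'F'")
  if (!is.numeric(f_founder) || f_founder < 0 || f_founder >= 1) {
    stop_param("f_founder must lie in [0, 1)")
  }
  has_f <- !is.na(ped$father)
  has_m <- !is.na(ped$mother)
  if (any(has_f != has_m)) {
    stop_data("each non-founder needs exactly two parents: ",
              paste(ped$id[has_f != has_m], collapse = ", "))
  }
  miss <- c(setdiff(ped$father[has_f], ped$id), setdiff(ped$mother[has_m], ped$id))
  if (length(miss)) stop_data("missing parent(s): ", paste(unique(miss), collapse = ", "))
  fs <- ped$sex[match(ped$father[has_f], ped$id)]
  ms <- ped$sex[match(ped$mother[has_m], ped$id)]
  if (any(fs != "M") || any(ms != "F")) {
    stop_data("fathers must be male and mothers female")
  }
  ped <- topo_sort_pedigree(ped)
  attr(ped, "f_founder") <- f_founder
  class(ped) <- c("pedigree_spec", "data.frame")
  ped
}

# Order individuals so every parent precedes its children; errors on cycles.
topo_sort_pedigree <- function(ped) {
  placed <- character(0)
  remaining <- ped$id
  while (length(remaining)) {
    ready <- vapply(remaining, function(i) {
      r <- ped[ped$id == i, ]
      (is.na(r$father) || r$father %in% placed) &&
        (is.na(r$mother) || r$mother %in% placed)
    }, logical(1))
    if (!any(ready)) stop_data("pedigree contains a cycle")
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  out <- ped[match(placed, ped$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected kinship coefficients from a pedigree
#'
#' Computes the kinship matrix phi by the standard recursion
#' (phi(i,i) = (1 + phi(f_i, m_i)) / 2; phi(i,j) = (phi(f_i, j) + phi(m_i, j)) / 2)
#' assuming non-inbred founders. Expected relatedness is `r = 2 * phi` for
#' distinct non-inbred individuals.
#'
#' @param ped a [pedigree_spec()].
#' @return Symmetric numeric matrix of kinship coefficients.
#' @export
pedigree_kinship <- function(ped) {
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  for (i in seq_len(n)) {
    phi[i, i] <- if (is.na(fi[i])) 0.5 else 0.5 * (1 + phi[fi[i], mi[i]])
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        phi[i, j] <- phi[j, i] <-
          if (is.na(fi[i])) 0 else 0.5 * (phi[fi[i], j] + phi[mi[i], j])
      }
    }
  }
  phi
}

#' Draw a biallelic site panel with population allele frequencies
#'
#' Frequencies are drawn from a symmetric Beta(0.8, 0.8) — a U-shaped,
#' SFS-like distribution resembling common-SNP ascertainment — truncated to
#' the minor-allele-frequency filter `min(p, 1 - p) >= maf_min`. Each site is
#' labelled damage-susceptible with probability 1/2, standing in for the
#' C->T / G->A strand classes affected by post-mortem deamination.
#'
#' @param n_sites number of sites (>= 1).
#' @param maf_min minor-allele-frequency floor, in `[0, 0.5)`.
#' @param seed integer seed.
#' @param chrom chromosome label for all sites.
#' @return A `freq_panel` data frame: `site_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `p` (alternate-allele frequency), `damage` (susceptibility flag).
#' @export
draw_frequency_panel <- function(n_sites, maf_min = 0.05, seed = 1L, chrom = "1") {
  if (!is.numeric(n_sites) || n_sites < 1) stop_param("n_sites must be >= 1")
  if (!is.numeric(maf_min) || maf_min < 0 || maf_min >= 0.5) {
    stop_param("maf_min must lie in [0, 0.5)")
  }
  n_sites <- as.integer(n_sites)
  with_seed(seed, {
    # inverse-CDF sampling from Beta(0.8, 0.8) truncated to [maf_min, 1 - maf_min]
    lo <- stats::pbeta(maf_min, 0.8, 0.8)
    hi <- stats::pbeta(1 - maf_min, 0.8, 0.8)
    p <- stats::qbeta(runif(n_sites, lo, hi), 0.8, 0.8)
    p <- pmin(pmax(p, maf_min), 1 - maf_min)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    panel <- data.frame(
      site_id = sprintf("s%06d", seq_len(n_sites)),
      chrom = chrom,
      pos = cumsum(1L + rpois(n_sites, 999)),
      ref = unname(ref), alt = unname(alt),
      p = p,
      damage = runif(n_sites) < 0.5,
      stringsAsFactors = FALSE
    )
    class(panel) <- c("freq_panel", "data.frame")
    panel
  })
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("site_id", "p") %in% names(panel)))
  if (anyDuplicated(panel$site_id)) stop_data("panel site IDs must be unique")
  if (any(panel$p < 0 | panel$p > 1)) stop_data("panel frequencies outside [0, 1]")
  invisible(panel)
}

#' Drop alleles through a pedigree
#'
#' Founders draw two allele copies per site from the panel frequencies
#' (identical by descent with probability `f_founder`); non-founders receive
#' one allele from each parent by Mendelian transmission, independently per
#' site (free recombination). Founder-allele labels are tracked so realized
#' identity-by-descent states can be read off exactly (see [ibd_states()]).
#'
#' @param ped a [pedigree_spec()].
#' @param panel a frequency panel from [draw_frequency_panel()].
#' @param seed integer seed.
#' @return A `gene_drop` list: `genotypes` (individuals x sites integer
#'   matrix of alt-allele dosages), label matrices `lab1`/`lab2`, the
#'   pedigree, and maternal (`mt_lineage`) / paternal (`y_lineage`) founder
#'   lineage labels per individual (`y_lineage` is `NA` for females).
#' @export
gene_drop <- function(ped, panel, seed = 1L) {
  stopifnot(inherits(ped, "pedigree_spec"))
  validate_panel(panel)
  n <- nrow(ped)
  S <- nrow(panel)
  f0 <- attr(ped, "f_founder")
  if (is.null(f0)) f0 <- 0
  with_seed(seed, {
    v1 <- matrix(0L, n, S, dimnames = list(ped$id, panel$site_id))
    v2 <- v1
    l1 <- v1
    l2 <- v1
    fi <- match(ped$father, ped$id)
    mi <- match(ped$mother, ped$id)
    next_lab <- 1L
    for (i in seq_len(n)) {
      if (is.na(fi[i])) {
        a <- as.integer(runif(S) < panel$p)
        b <- as.integer(runif(S) < panel$p)
        la <- rep.int(next_lab, S)
        lb <- rep.int(next_lab + 1L, S)
        next_lab <- next_lab + 2L
        if (f0 > 0) {
          ibd <- runif(S) < f0
          b[ibd] <- a[ibd]
          lb[ibd] <- la[ibd]
        }
        v1[i, ] <- a; v2[i, ] <- b; l1[i, ] <- la; l2[i, ] <- lb
      } else {
        pick_f <- runif(S) < 0.5
        pick_m <- runif(S) < 0.5
        v1[i, ] <- ifelse(pick_f, v1[fi[i], ], v2[fi[i], ])
        l1[i, ] <- ifelse(pick_f, l1[fi[i], ], l2[fi[i], ])
        v2[i, ] <- ifelse(pick_m, v1[mi[i], ], v2[mi[i], ])
        l2[i, ] <- ifelse(pick_m, l1[mi[i], ], l2[mi[i], ])
      }
    }
    mt <- character(n); yl <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      mt[i] <- if (is.na(mi[i])) paste0("mt_", ped$id[i]) else mt[mi[i]]
      if (ped$sex[i] == "M") {
        yl[i] <- if (is.na(fi[i])) paste0("y_", ped$id[i]) else yl[fi[i]]
      }
    }
    structure(list(genotypes = v1 + v2, lab1 = l1, lab2 = l2,
                   pedigree = ped, panel_sites = panel$site_id,
                   mt_lineage = setNames(mt, ped$id),
                   y_lineage = setNames(yl, ped$id)),
              class = "gene_drop")
  })
}

#' Realized identity-by-descent states for a simulated pair
#'
#' Reads the per-site IBD state (0, 1 or 2 alleles shared identical by
#' descent) off the founder-allele labels tracked by [gene_drop()], by
#' maximum matching of the two label pairs.
#'
#' @param gd a `gene_drop` object.
#' @param i,j individual IDs.
#' @return Integer vector of per-site IBD states in `{0, 1, 2}`.
#' @export
ibd_states <- function(gd, i, j) {
  stopifnot(inherits(gd, "gene_drop"))
  x1 <- gd$lab1[i, ]; x2 <- gd$lab2[i, ]
  y1 <- gd$lab1[j, ]; y2 <- gd$lab2[j, ]
  c11 <- x1 == y1; c12 <- x1 == y2; c21 <- x2 == y1; c22 <- x2 == y2
  two <- (c11 & c22) | (c12 & c21)
  one <- !two & (c11 | c12 | c21 | c22)
  as.integer(two) * 2L + as.integer(one)
}

#' Draw per-individual mean depths mimicking a low-coverage cohort
#'
#' Normal(0.85, 0.25) truncated below at 0.1, matching shotgun coverages
#' typical of well-preserved petrous-bone samples.
#'
#' @param n number of individuals.
#' @param seed integer seed.
#' @param mean,sd,floor distribution parameters.
#' @return Numeric vector of mean depths.
#' @export
draw_depths <- function(n, seed = 1L, mean = 0.85, sd = 0.25, floor = 0.1) {
  with_seed(seed, {
    d <- rnorm(n, mean, sd)
    while (any(d < floor)) d[d < floor] <- rnorm(sum(d < floor), mean, sd)
    d
  })
}

#' Simulate allele-count pileups over a genotype table
#'
#' Per-site read depth is Poisson with the given mean (scalar, or one mean
#' per individual). Each read samples one of the two alleles uniformly and
#' is then mis-read with probability `error_rate`; at damage-susceptible
#' sites homozygote reads are additionally flipped with probability
#' `damage_rate`, reproducing the allele-biased error of post-mortem
#' deamination. The per-read alternate-allele probability is therefore
#' `a(0) = e + d*s`, `a(1) = 1/2`, `a(2) = 1 - e - d*s` with `s` the
#' susceptibility flag — the same model the genotype-likelihood engine
#' inverts.
#'
#' @param genotypes individuals x sites integer matrix of alt dosages.
#' @param panel the matching frequency panel (provides damage flags).
#' @param depth_mean mean depth (>= 0), scalar or per-individual vector.
#' @param error_rate base mis-read probability in `[0, 1)`.
#' @param damage_rate extra flip probability at susceptible sites, `[0, 1)`.
#' @param seed integer seed.
#' @return A `pileup_table` list with integer matrices `n_ref` and `n_alt`.
#' @export
simulate_pileups <- function(genotypes, panel, depth_mean = 0.85,
                             error_rate = 0.005, damage_rate = 0.02,
                             seed = 1L) {
  validate_panel(panel)
  if (any(depth_mean < 0)) stop_param("depth_mean must be >= 0")
  if (error_rate < 0 || error_rate >= 1) stop_param("error_rate must lie in [0, 1)")
  if (damage_rate < 0 || damage_rate >= 1) stop_param("damage_rate must lie in [0, 1)")
  n <- nrow(genotypes); S <- ncol(genotypes)
  stopifnot(S == nrow(panel))
  depth_mean <- rep_len(depth_mean, n)
  with_seed(seed, {
    depth <- matrix(rpois(n * S, rep(depth_mean, S)), n, S)
    s <- matrix(rep(as.numeric(panel$damage), each = n), n, S)
    a <- matrix(NA_real_, n, S)
    a[genotypes == 0L] <- error_rate + damage_rate * s[genotypes == 0L]
    a[genotypes == 1L] <- 0.5
    a[genotypes == 2L] <- 1 - error_rate - damage_rate * s[genotypes == 2L]
    n_alt <- matrix(rbinom(n * S, depth, a), n, S)
    dimnames(n_alt) <- dimnames(genotypes)
    n_ref <- depth - n_alt
    dimnames(n_ref) <- dimnames(genotypes)
    structure(list(n_ref = n_ref, n_alt = n_alt, site_id = panel$site_id),
              class = "pileup_table")
  })
}

#' Simulate cemetery metadata over a simulated pedigree
#'
#' Builds per-individual burial metadata consistent with the pedigree:
#' sexes come from the pedigree, mitochondrial labels follow maternal lines
#' and Y labels paternal lines, families tend to share a spatial group, and
#' optional unrelated in-migrant females (with novel mitochondrial labels,
#' emulating female exogamy) fill out the cohort.
#'
#' @param ped a [pedigree_spec()] of the locally born individuals.
#' @param scenario list with elements:
#'   \describe{
#'     \item{group_sizes}{named or unnamed integer vector; must sum to the
#'       cohort size (pedigree members kept plus in-migrants).}
#'     \item{kin_group_prob}{probability that a family member is buried in
#'       the family's home group (default 0.9).}
#'     \item{n_inmigrants}{number of unrelated in-migrant females appended
#'       to the cohort (default 0).}
#'     \item{include}{optional character vector restricting the cohort to a
#'       subset of pedigree IDs (e.g. "sampled" individuals).}
#'     \item{status_prob}{probability an individual is classed
#'       "prestigious" (default 0.5).}
#'   }
#' @param seed integer seed.
#' @return A `cemetery_meta` data frame: `individual`, `burial`, `group`,
#'   `x`, `y`, `sex` (XX/XY), `age_class`, `status`, `mt_haplotype`,
#'   `y_haplotype`.
#' @export
simulate_cemetery <- function(ped, scenario, seed = 1L) {
  stopifnot(inherits(ped, "pedigree_spec"), is.list(scenario))
  kin_p <- scenario$kin_group_prob %||% 0.9
  n_mig <- scenario$n_inmigrants %||% 0L
  keep <- scenario$include %||% ped$id
  status_p <- scenario$status_prob %||% 0.5
  if (!all(keep %in% ped$id)) stop_data("unknown IDs in scenario$include")
  ids <- keep
  n_cohort <- length(ids) + n_mig
  sizes <- scenario$group_sizes
  if (is.null(sizes) || sum(sizes) != n_cohort) {
    stop_param("scenario$group_sizes must sum to the cohort size (",
               n_cohort, ")")
  }
  glabs <- if (!is.null(names(sizes))) names(sizes) else paste0("G", seq_along(sizes))

  # family = connected component of the parent-child graph
  comp <- pedigree_components(ped)

  with_seed(seed, {
    mt <- character(nrow(ped)); yl <- rep(NA_character_, nrow(ped))
    fi <- match(ped$father, ped$id); mi <- match(ped$mother, ped$id)
    for (i in seq_len(nrow(ped))) {
      mt[i] <- if (is.na(mi[i])) paste0("MT_", ped$id[i]) else mt[mi[i]]
      if (ped$sex[i] == "M") {
        yl[i] <- if (is.na(fi[i])) paste0("Y_", ped$id[i]) else yl[fi[i]]
      }
    }
    names(mt) <- names(yl) <- ped$id

    cap <- as.integer(sizes)
    assign_grp <- setNames(rep(NA_integer_, n_cohort),
                           c(ids, if (n_mig > 0) paste0("MIG", seq_len(n_mig))))
    fam_of <- comp[match(ids, ped$id)]
    fams <- names(sort(table(fam_of), decreasing = TRUE))
    for (f in fams) {
      members <- ids[fam_of == f]
      ok <- if (kin_p >= 1) which(cap >= length(members)) else which(cap > 0)
      if (!length(ok)) stop_param("group sizes cannot host a family of ",
                                  length(members), " with kin_group_prob = 1")
      home <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = cap[ok])
      for (m in members) {
        g <- if (runif(1) < kin_p && cap[home] > 0) home else {
          avail <- which(cap > 0)
          if (length(avail) == 1L) avail else sample(avail, 1L, prob = cap[avail])
        }
        assign_grp[m] <- g
        cap[g] <- cap[g] - 1L
      }
    }
    if (n_mig > 0) {
      for (m in paste0("MIG", seq_len(n_mig))) {
        avail <- which(cap > 0)
        g <- if (length(avail) == 1L) avail else sample(avail, 1L, prob = cap[avail])
        assign_grp[m] <- g
        cap[g] <- cap[g] - 1L
      }
    }

    all_ids <- names(assign_grp)
    is_mig <- grepl("^MIG", all_ids)
    sexes <- ifelse(is_mig, "F", ped$sex[match(all_ids, ped$id)])
    centers <- cbind(runif(length(sizes), 0, 100), runif(length(sizes), 0, 100))
    ages <- sample(c("infans", "juvenis", "adultus", "maturus", "senior"),
                   n_cohort, replace = TRUE,
                   prob = c(0.25, 0.15, 0.3, 0.2, 0.1))
    meta <- data.frame(
      individual = all_ids,
      burial = all_ids,
      group = glabs[assign_grp],
      x = centers[assign_grp, 1] + rnorm(n_cohort, 0, 3),
      y = centers[assign_grp, 2] + rnorm(n_cohort, 0, 3),
      sex = ifelse(sexes == "M", "XY", "XX"),
      age_class = ages,
      status = ifelse(runif(n_cohort) < status_p, "prestigious", "simple"),
      mt_haplotype = ifelse(is_mig, paste0("MTX", seq_len(n_cohort)[is_mig]),
                            mt[all_ids]),
      y_haplotype = ifelse(sexes == "M", yl[all_ids], NA_character_),
      stringsAsFactors = FALSE
    )
    rownames(meta) <- NULL
    class(meta) <- c("cemetery_meta", "data.frame")
    meta
  })
}

# connected components of the pedigree's parent-child graph (union-find)
pedigree_components <- function(ped) {
  parent <- seq_len(nrow(ped))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  fi <- match(ped$father, ped$id); mi <- match(ped$mother, ped$id)
  for (i in seq_len(nrow(ped))) {
    if (!is.na(fi[i])) union_(i, fi[i])
    if (!is.na(mi[i])) union_(i, mi[i])
  }
  as.character(vapply(seq_len(nrow(ped)), find, integer(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
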