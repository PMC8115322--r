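as_pair_matrix <- function(pairs) {
  if (is.data.frame(pairs)) {
    cbind(as.character(pairs[[1]]), as.character(pairs[[2]]))
  } else if (is.matrix(pairs)) {
    pairs
  } else {
    stop_param("pairs must be a two-column data frame or matrix")
  }
}

check_assignment <- function(pairs, assignment) {
  miss <- setdiff(unique(as.vector(pairs)), names(assignment))
  if (length(miss)) {
    stop_data("individual(s) not in the group assignment: ",
              paste(miss, collapse = ", "))
  }
}

#' Count kin pairs buried in the same spatial group
#'
#' @param pairs two-column data frame or matrix of related-pair IDs.
#' @param assignment named character vector mapping individual -> group
#'   label.
#' @return Integer count of pairs with both members in one group.
#' @export
same_group_pair_count <- function(pairs, assignment) {
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) == 0) return(0L)
  check_assignment(pairs, assignment)
  sum(assignment[pairs[, 1]] == assignment[pairs[, 2]])
}

#' Permutation test for spatial clustering of relatives
#'
#' Permutes the individual-to-group assignment while preserving group
#' sizes and compares the observed number of same-group kin pairs against
#' the permutation null. The one-sided p-value uses the add-one convention
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`, which never reports an
#' exact zero.
#'
#' @param pairs two-column data frame or matrix of related-pair IDs.
#' @param assignment named character vector individual -> group (must
#'   cover every individual in the cohort, not only pair members).
#' @param n_perm number of permutations (>= 1000).
#' @param seed integer seed.
#' @return A `permutation_result` list: `observed`, `n_perm`, `p`, `seed`,
#'   `null_mean`, `null_q95`.
#' @export
spatial_kin_permutation <- function(pairs, assignment, n_perm = 1e6,
                                    seed = 1L) {
  if (n_perm < 1000) stop_param("n_perm must be >= 1000")
  n_perm <- as.integer(n_perm)
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) == 0) {
    return(structure(list(observed = 0L, n_perm = n_perm, p = 1,
                          seed = seed, null_mean = 0, null_q95 = 0),
                     class = "permutation_result"))
  }
  check_assignment(pairs, assignment)
  obs <- same_group_pair_count(pairs, assignment)
  if (length(unique(assignment)) < 2L) {
    warning("degenerate grouping (single group): p = 1")
    return(structure(list(observed = obs, n_perm = n_perm, p = 1,
                          seed = seed, null_mean = obs, null_q95 = obs),
                     class = "permutation_result"))
  }
  ids <- names(assignment)
  g <- as.integer(factor(assignment))
  pi <- match(pairs[, 1], ids)
  pj <- match(pairs[, 2], ids)
  stats <- with_seed(seed,
                     perm_same_group_stats(g, pi - 1L, pj - 1L, n_perm))
  p <- (1 + sum(stats >= obs)) / (1 + n_perm)
  structure(list(observed = obs, n_perm = n_perm, p = p, seed = seed,
                 null_mean = mean(stats),
                 null_q95 = unname(quantile(stats, 0.95))),
            class = "permutation_result")
}

#' Exact null tail probability of the same-group pair statistic
#'
#' Enumerates every distinct assignment of individuals to groups of the
#' given sizes and returns the exact `P(statistic >= observed)`. Intended
#' as an oracle for [spatial_kin_permutation()] on small cohorts; refuses
#' instances with more than `max_assignments` distinct assignments.
#'
#' @param pairs two-column data frame or matrix of related-pair IDs.
#' @param assignment named character vector individual -> group (defines
#'   both the cohort, the group sizes, and the observed statistic).
#' @param observed observed statistic; defaults to the statistic of
#'   `assignment`.
#' @param max_assignments enumeration cap (default 1e7).
#' @return List: `p_exact`, `observed`, `n_assignments`, `null` (table of
#'   the exact null distribution).
#' @export
exact_pair_statistic_null <- function(pairs, assignment, observed = NULL,
                                      max_assignments = 1e7) {
  pairs <- as_pair_matrix(pairs)
  check_assignment(pairs, assignment)
  ids <- names(assignment)
  sizes <- table(assignment)
  n_assign <- exp(lgamma(length(ids) + 1) - sum(lgamma(sizes + 1)))
  if (n_assign > max_assignments) {
    stop_param("instance has ~", format(n_assign, digits = 3),
               " assignments (> ", max_assignments,
               "); use spatial_kin_permutation() instead")
  }
  if (is.null(observed)) observed <- same_group_pair_count(pairs, assignment)
  pi <- match(pairs[, 1], ids)
  pj <- match(pairs[, 2], ids)
  counts <- integer(nrow(pairs) + 1L)  # stat value s -> count at index s+1
  recurse <- function(remaining, cur, gi) {
    if (gi > length(sizes)) {
      s <- sum(cur[pi] == cur[pj])
      counts[s + 1L] <<- counts[s + 1L] + 1L
      return(invisible())
    }
    for (members in combn_list(remaining, sizes[[gi]])) {
      nxt <- cur
      nxt[members] <- gi
      recurse(setdiff(remaining, members), nxt, gi + 1L)
    }
    invisible()
  }
  recurse(seq_along(ids), integer(length(ids)), 1L)
  total <- sum(counts)
  p_exact <- sum(counts[seq_along(counts) >= observed + 1L]) / total
  list(p_exact = p_exact, observed = observed, n_assignments = total,
       null = setNames(counts / total, 0:nrow(pairs)))
}

combn_list <- function(x, m) {
  if (m == length(x)) return(list(x))
  cmb <- combn(x, m)
  lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
}

#' Probability that a random subset is composed entirely of carriers
#'
#' Hypergeometric tail point: the probability that `n_selected`
#' individuals drawn without replacement from a cohort of `n_total`, of
#' whom `n_with_attribute` carry an attribute, all carry it:
#' `choose(n_with_attribute, n_selected) / choose(n_total, n_selected)`.
#' Used e.g. to ask how surprising it is that every individual without a
#' genetic relative in a cemetery is female.
#'
#' @param n_total cohort size.
#' @param n_with_attribute number of carriers in the cohort.
#' @param n_selected size of the observed subset.
#' @return Scalar probability.
#' @export
composition_probability <- function(n_total, n_with_attribute, n_selected) {
  if (n_selected > n_with_attribute || n_with_attribute > n_total ||
      n_selected < 0) {
    stop_param("need n_selected <= n_with_attribute <= n_total")
  }
  choose(n_with_attribute, n_selected) / choose(n_total, n_selected)
}

#' Grave-good status concordance among kin dyads
#'
#' For each related pair, compares the two members' binary status classes
#' (prestigious/simple). Pairs with a missing status on either side are
#' flagged and excluded from the totals.
#'
#' @param pairs data frame with `id1`, `id2` and optionally `degree`.
#' @param metadata cemetery metadata with columns `individual`, `status`.
#' @return A `dyad_status_table` list: `dyads` (per-pair frame with
#'   `status1`, `status2`, `concordant`, `evaluable`), `n_concordant`,
#'   `n_discordant`, `n_excluded`.
#' @export
status_concordance <- function(pairs, metadata) {
  if (nrow(pairs) == 0) {
    return(structure(list(dyads = data.frame(), n_concordant = 0L,
                          n_discordant = 0L, n_excluded = 0L),
                     class = "dyad_status_table"))
  }
  st <- function(ids) {
    s <- metadata$status[match(ids, metadata$individual)]
    s[s %in% c("", ".")] <- NA
    s
  }
  s1 <- st(pairs$id1); s2 <- st(pairs$id2)
  evaluable <- !is.na(s1) & !is.na(s2)
  conc <- evaluable & s1 == s2
  dyads <- data.frame(id1 = pairs$id1, id2 = pairs$id2,
                      degree = if (!is.null(pairs$degree)) pairs$degree else NA,
                      status1 = s1, status2 = s2,
                      concordant = ifelse(evaluable, conc, NA),
                      evaluable = evaluable, stringsAsFactors = FALSE)
  structure(list(dyads = dyads,
                 n_concordant = sum(conc),
                 n_discordant = sum(evaluable & !conc),
                 n_excluded = sum(!evaluable)),
            class = "dyad_status_table")
}

#' Cohort-level kinship summary
#'
#' Counts related pairs by degree, the distinct individuals involved in
#' any relationship, and the individuals with no called relative (with a
#' sex breakdown).
#'
#' @param pairs data frame of called-related pairs (`id1`, `id2`,
#'   optionally `degree`).
#' @param metadata cemetery metadata (`individual`, `sex`).
#' @return List: `n_pairs`, `pairs_by_degree`, `related`, `n_related`,
#'   `unrelated`, `n_unrelated`, `unrelated_sex` (table).
#' @export
summarize_cohort <- function(pairs, metadata) {
  related <- if (nrow(pairs)) unique(c(pairs$id1, pairs$id2)) else character(0)
  unrelated <- setdiff(metadata$individual, related)
  list(n_pairs = nrow(pairs),
       pairs_by_degree = if (nrow(pairs) && !is.null(pairs$degree))
         table(pairs$degree) else table(character(0)),
       related = related, n_related = length(related),
       unrelated = unrelated, n_unrelated = length(unrelated),
       unrelated_sex = table(metadata$sex[match(unrelated,
                                                metadata$individual)]))
}
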