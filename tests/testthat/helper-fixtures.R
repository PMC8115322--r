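# Shared test helpers: tiny containers built in code, plus independent
# oracles kept deliberately separate from the package implementation.

# constant-frequency panel
panel_const <- function(p, damage = FALSE) {
  n <- length(p)
  df <- data.frame(site_id = sprintf("s%05d", seq_len(n)), chrom = "1",
                   pos = seq_len(n) * 1000L, ref = "A", alt = "G",
                   p = p, damage = rep_len(damage, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("freq_panel", "data.frame")
  df
}

# pileup table from explicit count matrices
pileup_tbl <- function(n_ref, n_alt) {
  structure(list(n_ref = n_ref, n_alt = n_alt, site_id = colnames(n_ref)),
            class = "pileup_table")
}

# hard-call genotype likelihoods: 1 for the true genotype, 0 otherwise
gl_hard <- function(geno, coverage = 100L) {
  pick <- function(g) matrix(ifelse(geno == g, 0, -1000),
                             nrow(geno), ncol(geno), dimnames = dimnames(geno))
  structure(list(ll0 = pick(0L), ll1 = pick(1L), ll2 = pick(2L),
                 coverage = matrix(coverage, nrow(geno), ncol(geno),
                                   dimnames = dimnames(geno)),
                 site_id = colnames(geno)),
            class = "gl_set")
}

# Independent brute-force oracle for the pairwise IBD log-likelihood:
# per site, enumerate all nine genotype pairs; the one-allele-IBD joint
# probability is derived allele-by-allele (shared allele plus one free
# allele per individual), not via the package's factorized components.
brute_pair_loglik <- function(Li, Lj, p, k) {
  total <- 0
  for (s in seq_along(p)) {
    ps <- p[s]
    f <- c(1 - ps, ps)
    hw <- c((1 - ps)^2, 2 * ps * (1 - ps), ps^2)
    site <- 0
    for (gi in 0:2) {
      for (gj in 0:2) {
        s1 <- 0
        for (a in 0:1) {
          bi <- gi - a
          bj <- gj - a
          if (bi >= 0 && bi <= 1 && bj >= 0 && bj <= 1) {
            s1 <- s1 + f[a + 1] * f[bi + 1] * f[bj + 1]
          }
        }
        pr <- k[1] * hw[gi + 1] * hw[gj + 1] + k[2] * s1 +
          k[3] * (gi == gj) * hw[gi + 1]
        site <- site + Li[s, gi + 1] * Lj[s, gj + 1] * pr
      }
    }
    total <- total + log(site)
  }
  total
}

# pedigree mirroring the structure of the bundled cemetery cohort:
# seven families realizing three parent-offspring, two sibling, three
# second-degree and one cousin pair among 15 sampled individuals
ped_study_like <- function() {
  pedigree_spec(
    id = c("257A", "U1", "243", "U3", "U4", "257B",
           "228", "U5", "260",
           "181", "U6", "163",
           "U7", "U8", "122E", "211",
           "U9", "U10", "161", "295",
           "U11", "U12", "U13", "220", "225",
           "U14", "U15", "U16", "U17", "U18", "U19", "282", "288"),
    father = c(NA, NA, "U1", "U1", NA, "U4",
               NA, NA, "U5",
               NA, NA, "U6",
               NA, NA, "U7", "U7",
               NA, NA, "U9", "U9",
               NA, NA, NA, "U11", "U11",
               NA, NA, "U14", "U14", NA, NA, "U16", "U19"),
    mother = c(NA, NA, "257A", "257A", NA, "U3",
               NA, NA, "228",
               NA, NA, "181",
               NA, NA, "U8", "U8",
               NA, NA, "U10", "U10",
               NA, NA, NA, "U12", "U13",
               NA, NA, "U15", "U15", NA, NA, "U18", "U17"),
    sex = c("F", "M", "M", "F", "M", "M",
            "F", "M", "M",
            "F", "M", "M",
            "M", "F", "M", "M",
            "M", "F", "F", "M",
            "M", "F", "F", "M", "M",
            "M", "F", "M", "F", "F", "M", "M", "F")
  )
}

study_like_sampled <- c("257A", "243", "257B", "228", "260", "181", "163",
                        "122E", "211", "161", "295", "220", "225", "282", "288")

study_like_pairs <- rbind(
  c("257A", "243"), c("228", "260"), c("163", "181"),
  c("122E", "211"), c("161", "295"),
  c("257B", "257A"), c("257B", "243"), c("220", "225"),
  c("282", "288"))
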