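# TSV dialect used throughout: tab-separated, UTF-8, header row, "." for
# missing, 1-based positions (VCF convention).

read_tsv_ <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
             stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_ <- function(df, path) {
  df[] <- lapply(df, function(x) ifelse(is.na(x), ".", as.character(x)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write frequency-panel TSV files
#'
#' Columns: `site_id`, `chrom`, `pos`, `ref`, `alt`, `p`, `damage`.
#'
#' @param panel a `freq_panel` data frame.
#' @param path file path.
#' @return `read_panel_tsv()` returns a `freq_panel`; the writer returns
#'   the path invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- as.data.frame(panel)
  df$p <- sprintf("%.17g", df$p)
  write_tsv_(df, path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- read_tsv_(path)
  df$p <- as.numeric(df$p)
  df$pos <- as.integer(df$pos)
  df$damage <- as.logical(df$damage)
  class(df) <- c("freq_panel", "data.frame")
  validate_panel(df)
  df
}

#' Read and write pileup TSV files
#'
#' Long format: `individual`, `site_id`, `n_ref`, `n_alt`. Sites absent
#' for an individual are zero-coverage.
#'
#' @param pileup a `pileup_table`.
#' @param path file path.
#' @param panel frequency panel defining the site universe (for reading).
#' @return `read_pileup_tsv()` returns a `pileup_table`.
#' @export
write_pileup_tsv <- function(pileup, path) {
  nr <- pileup$n_ref; na_ <- pileup$n_alt
  covered <- which(nr + na_ > 0, arr.ind = TRUE)
  df <- data.frame(individual = rownames(nr)[covered[, 1]],
                   site_id = colnames(nr)[covered[, 2]],
                   n_ref = nr[covered], n_alt = na_[covered],
                   stringsAsFactors = FALSE)
  df <- df[order(df$individual, match(df$site_id, colnames(nr))), ]
  write_tsv_(df, path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path, panel) {
  validate_panel(panel)
  df <- read_tsv_(path)
  ids <- unique(df$individual)
  S <- nrow(panel)
  nr <- matrix(0L, length(ids), S, dimnames = list(ids, panel$site_id))
  na_ <- nr
  ri <- match(df$individual, ids)
  ci <- match(df$site_id, panel$site_id)
  if (anyNA(ci)) stop_data("pileup refers to sites absent from the panel")
  nr[cbind(ri, ci)] <- as.integer(df$n_ref)
  na_[cbind(ri, ci)] <- as.integer(df$n_alt)
  structure(list(n_ref = nr, n_alt = na_, site_id = panel$site_id),
            class = "pileup_table")
}

#' Read and write genotype-likelihood TSV files
#'
#' Long format with natural-log likelihoods normalized to a per-site
#' maximum of 0: `individual`, `site_id`, `ll_homref`, `ll_het`,
#' `ll_homalt`. Full precision (17 significant digits) is written so a
#' write/read round trip is exact.
#'
#' @param gls a `gl_set`.
#' @param path file path.
#' @param panel frequency panel defining the site universe (for reading).
#' @return `read_gl_tsv()` returns a `gl_set`.
#' @export
write_gl_tsv <- function(gls, path) {
  cov <- gls$coverage > 0
  covered <- which(cov, arr.ind = TRUE)
  o <- order(covered[, 1], covered[, 2])
  covered <- covered[o, , drop = FALSE]
  df <- data.frame(individual = rownames(gls$ll0)[covered[, 1]],
                   site_id = colnames(gls$ll0)[covered[, 2]],
                   coverage = gls$coverage[covered],
                   ll_homref = sprintf("%.17g", gls$ll0[covered]),
                   ll_het = sprintf("%.17g", gls$ll1[covered]),
                   ll_homalt = sprintf("%.17g", gls$ll2[covered]),
                   stringsAsFactors = FALSE)
  write_tsv_(df, path)
}

#' @rdname write_gl_tsv
#' @export
read_gl_tsv <- function(path, panel) {
  validate_panel(panel)
  df <- read_tsv_(path)
  ids <- unique(df$individual)
  S <- nrow(panel)
  zero <- matrix(0, length(ids), S, dimnames = list(ids, panel$site_id))
  ll0 <- ll1 <- ll2 <- zero
  cov <- matrix(0L, length(ids), S, dimnames = list(ids, panel$site_id))
  ri <- match(df$individual, ids)
  ci <- match(df$site_id, panel$site_id)
  if (anyNA(ci)) stop_data("GL table refers to sites absent from the panel")
  ll0[cbind(ri, ci)] <- as.numeric(df$ll_homref)
  ll1[cbind(ri, ci)] <- as.numeric(df$ll_het)
  ll2[cbind(ri, ci)] <- as.numeric(df$ll_homalt)
  cov[cbind(ri, ci)] <- as.integer(df$coverage)
  structure(list(ll0 = ll0, ll1 = ll1, ll2 = ll2, coverage = cov,
                 site_id = panel$site_id),
            class = "gl_set")
}

#' Read genotype likelihoods from a VCF
#'
#' Parses biallelic SNP records with per-sample `GL` (log10-scaled) or
#' `PL` (Phred-scaled) likelihood fields, converting to natural logs
#' normalized to a per-site maximum of 0. Records with multiple alternate
#' alleles are skipped with a message; samples without the field at a site
#' are uninformative (three equal likelihoods, coverage 0).
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return List with `gls` (a `gl_set`) and `panel` (a panel skeleton:
#'   `site_id`, `chrom`, `pos`, `ref`, `alt`, `p` from the INFO `AF` field
#'   where present, `damage = FALSE`).
#' @export
read_gl_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop_data("cannot parse VCF '", path,
                                                "': ", conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) |
    nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L
  if (any(multi)) {
    message(sum(multi), " multi-allelic/non-SNP record(s) skipped")
  }
  keep <- which(!multi)
  if (!length(keep)) stop_data("no biallelic SNP records in '", path, "'")
  fmt <- vcf@gt[keep, 1L]
  use_gl <- all(grepl("(^|:)GL(:|$)", fmt))
  elem <- if (use_gl) "GL" else "PL"
  raw <- vcfR::extract.gt(vcf, element = elem, as.numeric = FALSE)
  raw <- raw[keep, , drop = FALSE]
  samples <- colnames(raw)
  S <- length(keep)
  zero <- matrix(0, length(samples), S)
  ll0 <- ll1 <- ll2 <- zero
  cov <- matrix(0L, length(samples), S)
  for (s in seq_along(samples)) {
    vals <- strsplit(raw[, s], ",", fixed = TRUE)
    has <- lengths(vals) == 3L & !is.na(raw[, s])
    m <- matrix(as.numeric(unlist(vals[has])), ncol = 3, byrow = TRUE)
    ll <- if (use_gl) m * log(10) else -m / 10 * log(10)
    ll <- ll - apply(ll, 1, max)
    ll0[s, has] <- ll[, 1]; ll1[s, has] <- ll[, 2]; ll2[s, has] <- ll[, 3]
    cov[s, has] <- 1L
  }
  af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "AF")))[keep]
  site_id <- ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                    paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"]),
                    fix[keep, "ID"])
  dn <- list(samples, site_id)
  dimnames(ll0) <- dimnames(ll1) <- dimnames(ll2) <- dimnames(cov) <- dn
  panel <- data.frame(site_id = site_id, chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                      p = af, damage = FALSE, stringsAsFactors = FALSE)
  class(panel) <- c("freq_panel", "data.frame")
  list(gls = structure(list(ll0 = ll0, ll1 = ll1, ll2 = ll2,
                            coverage = cov, site_id = site_id),
                       class = "gl_set"),
       panel = panel)
}

#' Write a genotype-likelihood VCF
#'
#' Emits biallelic SNP records with a per-sample `GL` field (log10-scaled
#' likelihoods, full precision) for sites with coverage, and the panel
#' frequency as INFO `AF`.
#'
#' @param gls a `gl_set`.
#' @param panel matching frequency panel.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gl_vcf <- function(gls, panel, path) {
  validate_panel(panel)
  samples <- rownames(gls$ll0)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=paleokin-", as.character(packageVersion("paleokin"))),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Panel alternate allele frequency\">",
    "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Log10 genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  l10 <- log(10)
  for (k in seq_len(nrow(panel))) {
    gt <- vapply(seq_along(samples), function(s) {
      if (gls$coverage[s, k] > 0) {
        sprintf("%.17g,%.17g,%.17g", gls$ll0[s, k] / l10,
                gls$ll1[s, k] / l10, gls$ll2[s, k] / l10)
      } else {
        "."
      }
    }, character(1))
    writeLines(paste(c(panel$chrom[k], panel$pos[k], panel$site_id[k],
                       panel$ref[k], panel$alt[k], ".", "PASS",
                       sprintf("AF=%.17g", panel$p[k]), "GL", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Bundled Early Bronze Age cemetery fixtures (Mokrin)
#'
#' Small plain-text tables describing the published Mokrin cohort:
#' `mokrin_meta()` returns per-individual burial metadata (genetic sex,
#' age class, grave-good status where stated in the source discussion,
#' mitochondrial and Y haplotype labels, spatial group);
#' `mokrin_pairs()` the nine genetically related pairs with their called
#' degrees; `mokrin_groups()` the four geographic burial groups as a named
#' individual -> group vector.
#'
#' @return Data frames (or a named character vector for
#'   `mokrin_groups()`).
#' @export
mokrin_meta <- function() {
  read_tsv_(system.file("extdata", "mokrin_meta.tsv", package = "paleokin"))
}

#' @rdname mokrin_meta
#' @export
mokrin_pairs <- function() {
  read_tsv_(system.file("extdata", "mokrin_pairs.tsv", package = "paleokin"))
}

#' @rdname mokrin_meta
#' @export
mokrin_groups <- function() {
  df <- read_tsv_(system.file("extdata", "mokrin_groups.tsv",
                              package = "paleokin"))
  setNames(df$group, df$individual)
}
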