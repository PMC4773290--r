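#' Squared dosage correlation between two variants
#'
#' Composite LD: the squared Pearson correlation of genotype dosages over
#' pairwise-complete samples. This is the standard surrogate for
#' haplotype-based r-squared when phase is unknown, and equals it under
#' Hardy-Weinberg random mating.
#'
#' @param dosage_a,dosage_b per-sample dosage vectors (0/1/2, `NA` allowed).
#' @return list with `r2` and `n_informative` (samples non-missing at both
#'   sites).
#' @export
dosage_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b))
    stop2("dosage vectors differ in length (%d vs %d)",
          length(dosage_a), length(dosage_b))
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  n <- sum(ok)
  if (n < 2L) stop2("need >= 2 pairwise-complete samples, got %d", n)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop2("undefined LD: monomorphic site among informative samples")
  r <- stats::cor(a, b)
  list(r2 = r * r, n_informative = n)
}

#' LD of every variant with a lead SNP
#'
#' @param genotypes sample x variant dosage matrix with variant ids as column
#'   names.
#' @param lead_id column name of the lead SNP.
#' @return data.frame with one row per variant (including the lead itself,
#'   r2 = 1): `variant`, `lead`, `r2`, `n_informative`, `defined` (FALSE where
#'   LD is undefined because a site is monomorphic — reported, not dropped).
#' @export
ld_with_lead <- function(genotypes, lead_id) {
  if (!lead_id %in% colnames(genotypes))
    stop2("lead variant '%s' not present in genotype matrix", lead_id)
  lead <- genotypes[, lead_id]
  res <- lapply(colnames(genotypes), function(v) {
    r2 <- NA_real_; n <- NA_integer_; defined <- FALSE
    ok <- try(dosage_r2(genotypes[, v], lead), silent = TRUE)
    if (!inherits(ok, "try-error")) {
      r2 <- ok$r2; n <- ok$n_informative; defined <- TRUE
    }
    data.frame(variant = v, lead = lead_id, r2 = r2,
               n_informative = n, defined = defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Build the candidate variant pool by the union selection rule
#'
#' A variant enters the candidate set if it satisfies any of: (i) strong LD
#' with the lead SNP (r2 >= `r2_min`, inclusive); (ii) genome-wide significant
#' trait association (p < `p_gwas`, strict) within `locus_window_bp` of the
#' anchor gene; (iii) significant eQTL evidence (p < `p_eqtl`, strict) while
#' in strong LD with the lead. Provenance flags record which rules fired.
#'
#' @param ld data.frame from [ld_with_lead()].
#' @param gwas association table with columns `variant`, `pos`, `p` (the
#'   trait GWAS); may be `NULL`.
#' @param eqtl association table with columns `variant`, `p` (the expression
#'   scan); may be `NULL`.
#' @param r2_min inclusive LD threshold (default 0.8).
#' @param p_gwas strict genome-wide significance threshold (default 5e-8).
#' @param p_eqtl strict eQTL threshold; defaults to `p_gwas` (the source
#'   methodology states none for eQTL inclusion).
#' @param locus_window_bp window around the anchor gene for GWAS hits
#'   (default 500 kb).
#' @param gene_anchor_pos anchor position (e.g. nearest gene-body edge of the
#'   target gene); `NULL` disables the window filter.
#' @param window_eqtl also apply the window to eQTL hits (default FALSE).
#' @return data.frame of class `candidate_set`: `variant`, `r2`, `gwas_p`,
#'   `eqtl_p` and logical flags `ld_with_lead`, `gwas_significant`,
#'   `eqtl_significant`. Every retained variant has >= 1 flag set.
#' @export
select_candidates <- function(ld, gwas = NULL, eqtl = NULL,
                              r2_min = 0.8, p_gwas = 5e-8, p_eqtl = p_gwas,
                              locus_window_bp = 500000L,
                              gene_anchor_pos = NULL,
                              window_eqtl = FALSE) {
  stopifnot(is.data.frame(ld), all(c("variant", "r2") %in% names(ld)))
  variants <- ld$variant
  r2 <- ld$r2
  in_window <- function(tab) {
    if (is.null(gene_anchor_pos) || !"pos" %in% names(tab))
      return(rep(TRUE, length(variants)))
    pos <- tab$pos[match(variants, tab$variant)]
    !is.na(pos) & abs(pos - gene_anchor_pos) <= locus_window_bp
  }
  flag_ld <- !is.na(r2) & r2 >= r2_min
  gwas_p <- eqtl_p <- rep(NA_real_, length(variants))
  flag_gwas <- flag_eqtl <- rep(FALSE, length(variants))
  if (!is.null(gwas) && nrow(gwas)) {
    gwas_p <- gwas$p[match(variants, gwas$variant)]
    flag_gwas <- !is.na(gwas_p) & gwas_p < p_gwas & in_window(gwas)
  }
  if (!is.null(eqtl) && nrow(eqtl)) {
    eqtl_p <- eqtl$p[match(variants, eqtl$variant)]
    flag_eqtl <- !is.na(eqtl_p) & eqtl_p < p_eqtl & flag_ld
    if (window_eqtl) flag_eqtl <- flag_eqtl & in_window(eqtl)
  }
  keep <- flag_ld | flag_gwas | flag_eqtl
  if (!any(keep)) warn2("no variants satisfied any selection rule")
  out <- data.frame(variant = variants, r2 = r2,
                    gwas_p = gwas_p, eqtl_p = eqtl_p,
                    ld_with_lead = flag_ld,
                    gwas_significant = flag_gwas,
                    eqtl_significant = flag_eqtl,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: %d variants (%d LD, %d GWAS, %d eQTL)\n",
              nrow(x), sum(x$ld_with_lead), sum(x$gwas_significant),
              sum(x$eqtl_significant)))
  NextMethod()
}
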