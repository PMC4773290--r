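#' Priors for the five-hypothesis colocalisation model
#'
#' @param p1 prior probability a variant is causal for trait 1 only.
#' @param p2 same for trait 2.
#' @param p12 prior a variant is causal for both traits.
#' @param w1,w2 prior variance of the (standardised) effect size for each
#'   trait; the default 0.0225 corresponds to a prior effect SD of 0.15
#'   phenotype SD per allele copy, the conventional choice for quantitative
#'   traits.
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w1 = 0.0225, w2 = 0.0225) {
  if (!(p12 > 0 && p12 <= p1 && p12 <= p2 && p1 < 1 && p2 < 1))
    stop2("priors must satisfy 0 < p12 <= p1, p2 < 1")
  if (w1 <= 0 || w2 <= 0) stop2("prior effect variances must be > 0")
  structure(list(p1 = p1, p2 = p2, p12 = p12, w1 = w1, w2 = w2),
            class = "coloc_priors")
}

#' Log approximate Bayes factor for association at one variant
#'
#' Wakefield's asymptotic Bayes factor in favour of association, computed
#' from an effect estimate and its standard error under a N(0, w) effect
#' prior: with V = se^2, z = beta/se and shrinkage r = w/(V + w),
#' log ABF = 0.5 * (log(1 - r) + r * z^2).
#'
#' @param beta effect estimate.
#' @param se standard error (> 0).
#' @param w prior effect variance (> 0).
#' @return log Bayes factor (vectorised over inputs).
#' @export
log_abf <- function(beta, se, w = 0.0225) {
  if (any(se <= 0)) stop2("se must be > 0 (degenerate input)")
  if (any(w <= 0)) stop2("prior variance w must be > 0")
  V <- se^2
  z <- beta / se
  r <- w / (V + w)
  0.5 * (log1p(-r) + r * z^2)
}

#' Signed z-score from a two-sided p-value
#'
#' @param p two-sided p-value in (0, 1].
#' @param sign sign of the effect (+1/-1; 0 allowed for a null effect).
#' @return signed standard-normal quantile of p/2.
#' @export
zscore_from_p <- function(p, sign = 1) {
  if (any(p <= 0))
    stop2("p = 0 cannot be inverted; supply beta/se directly")
  if (any(p > 1)) stop2("p must lie in (0, 1]")
  base::sign(sign) * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Approximate sampling variance of a standardised effect from MAF and n
#'
#' For a standardised quantitative trait, the variance of the marginal effect
#' estimate is approximately 1 / (2 n f (1 - f)).
#'
#' @param maf minor-allele frequency in (0, 0.5].
#' @param n sample size (>= 2).
#' @return approximate variance V of the effect estimate.
#' @export
var_from_freq <- function(maf, n) {
  if (any(maf <= 0 | maf > 0.5)) stop2("maf must lie in (0, 0.5]")
  if (any(n < 2)) stop2("n must be >= 2")
  1 / (2 * n * maf * (1 - maf))
}

# per-variant log ABFs from an association table: (beta, se) preferred,
# (p, maf, n) fallback
abf_from_stats <- function(stats, w) {
  has_bse <- all(c("beta", "se") %in% names(stats)) &&
    !all(is.na(stats$beta)) && !all(is.na(stats$se))
  if (has_bse && all(stats$se > 0, na.rm = TRUE)) {
    return(log_abf(stats$beta, stats$se, w))
  }
  needed <- c("p", "maf", "n")
  if (!all(needed %in% names(stats)))
    stop2("association table needs (beta, se) or (p, maf, n)")
  z <- zscore_from_p(stats$p, sign = if ("beta" %in% names(stats))
    sign(stats$beta) else 1)
  V <- var_from_freq(stats$maf, stats$n)
  log_abf(z * sqrt(V), sqrt(V), w)
}

#' Posterior probabilities of the five colocalisation hypotheses
#'
#' Given per-variant summary statistics for two traits at one locus, computes
#' the posterior probability that the locus harbours: no association (H0), an
#' association with trait 1 only (H1), trait 2 only (H2), two distinct causal
#' variants (H3), or a single shared causal variant (H4). Assumes at most one
#' causal variant per trait. Per-variant evidence enters through Wakefield
#' log ABFs; hypothesis weights are accumulated entirely in log space.
#'
#' @param stats1,stats2 association tables with a `variant` column and either
#'   (`beta`, `se`) or (`p`, `maf`, `n`). Joined on variant id; variants
#'   present in only one table are dropped (count reported via a message).
#' @param priors a [coloc_priors()].
#' @return object of class `coloc_result`: `pp` (named numeric, H0..H4,
#'   summing to 1), `n_variants`, `priors`, `log_abf_1`, `log_abf_2` (named
#'   per-variant log ABFs).
#' @export
coloc_posteriors <- function(stats1, stats2, priors = coloc_priors()) {
  stopifnot(inherits(priors, "coloc_priors"))
  shared <- intersect(stats1$variant, stats2$variant)
  if (length(shared) == 0L) stop2("no shared variants between the two tables")
  dropped <- length(union(stats1$variant, stats2$variant)) - length(shared)
  if (dropped > 0)
    message(sprintf("coloc: dropped %d variant(s) present in only one table",
                    dropped))
  s1 <- stats1[match(shared, stats1$variant), , drop = FALSE]
  s2 <- stats2[match(shared, stats2$variant), , drop = FALSE]
  l1 <- stats::setNames(abf_from_stats(s1, priors$w1), shared)
  l2 <- stats::setNames(abf_from_stats(s2, priors$w2), shared)
  S1 <- logsumexp(l1)
  S2 <- logsumexp(l2)
  S12 <- logsumexp(l1 + l2)
  L <- c(H0 = 0,
         H1 = log(priors$p1) + S1,
         H2 = log(priors$p2) + S2,
         H3 = log(priors$p1) + log(priors$p2) + logdiffexp(S1 + S2, S12),
         H4 = log(priors$p12) + S12)
  pp <- exp(L - logsumexp(L))
  pp <- pp / sum(pp)
  structure(list(pp = pp, n_variants = length(shared), priors = priors,
                 log_abf_1 = l1, log_abf_2 = l2),
            class = "coloc_result")
}

#' Label colocalisation evidence by the strong-evidence rule
#'
#' A hypothesis is called "strong" when its posterior probability strictly
#' exceeds the threshold (default 0.75, i.e. the >75% rule); otherwise the
#' evidence is "inconclusive".
#'
#' @param result a [coloc_posteriors()] result.
#' @param threshold strict posterior threshold (default 0.75).
#' @return named character vector over H0..H4 with values
#'   `"strong"`/`"inconclusive"`.
#' @export
coloc_classify <- function(result, threshold = 0.75) {
  stopifnot(inherits(result, "coloc_result"))
  stats::setNames(ifelse(result$pp > threshold, "strong", "inconclusive"),
                  names(result$pp))
}

#' @export
print.coloc_result <- function(x, digits = 4, ...) {
  cat(sprintf("Colocalisation over %d shared variants\n", x$n_variants))
  cat("Posterior probabilities:\n")
  print(round(x$pp, digits))
  lab <- coloc_classify(x)
  strong <- names(lab)[lab == "strong"]
  if (length(strong))
    cat(sprintf("Strong evidence (>75%%) for %s\n",
                paste(strong, collapse = ", ")))
  else cat("No hypothesis reaches the strong-evidence threshold\n")
  invisible(x)
}

#' @export
summary.coloc_result <- function(object, ...) {
  top1 <- names(sort(object$log_abf_1, decreasing = TRUE))[1L]
  top2 <- names(sort(object$log_abf_2, decreasing = TRUE))[1L]
  out <- list(pp = object$pp, n_variants = object$n_variants,
              priors = unclass(object$priors),
              top_variant_trait1 = top1, top_variant_trait2 = top2,
              label = coloc_classify(object))
  class(out) <- "summary.coloc_result"
  out
}

#' @export
print.summary.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalisation summary (%d variants)\n", x$n_variants))
  print(round(x$pp, 4))
  cat(sprintf("Top variant, trait 1: %s; trait 2: %s\n",
              x$top_variant_trait1, x$top_variant_trait2))
  cat(sprintf("Priors: p1=%g p2=%g p12=%g w1=%g w2=%g\n", x$priors$p1,
              x$priors$p2, x$priors$p12, x$priors$w1, x$priors$w2))
  invisible(x)
}
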