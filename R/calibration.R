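#' Simulate one locus and colocalise its trait and expression signals
#'
#' One replicate of the colocalisation calibration experiment: simulate a
#' haplotype-block locus, place the causal variant(s) for the chosen
#' scenario, generate the two phenotypes, compute marginal summary
#' statistics for each, and run [coloc_posteriors()] with the supplied
#' priors. Causal variants are required to be polymorphic (MAF >=
#' `min_maf`): under H4 the eligible variant nearest the locus centre is
#' used; under H3 the pair of eligible variants from the first and last LD
#' blocks with the smallest realised dosage r-squared, so the two signals
#' are well separated.
#'
#' @param seed integer seed for the replicate.
#' @param scenario `"H4"` (shared causal variant), `"H3"` (two distinct
#'   causal variants) or `"H0"` (no causal variant).
#' @param spec a [locus_spec()] describing the locus (its seed is replaced
#'   by `seed`).
#' @param n_samples cohort size.
#' @param beta causal effect per allele copy (phenotype SD) for both traits.
#' @param noise_sd residual SD.
#' @param min_maf minimum MAF for a variant to be eligible as causal.
#' @param priors a [coloc_priors()].
#' @return the `coloc_result`, with the chosen causal indices and their
#'   realised dosage r-squared (H3) attached as attributes `"causal"` and
#'   `"causal_r2"`.
#' @export
simulate_coloc_replicate <- function(seed, scenario = c("H4", "H3", "H0"),
                                     spec = locus_spec(),
                                     n_samples = 2000L, beta = 0.4,
                                     noise_sd = 1, min_maf = 0.1,
                                     priors = coloc_priors()) {
  scenario <- match.arg(scenario)
  spec$seed <- as.integer(seed)
  hap <- simulate_haplotypes(spec, n_samples)
  odd <- seq(1L, nrow(hap), by = 2L)
  dosage <- hap[odd, , drop = FALSE] + hap[odd + 1L, , drop = FALSE]
  af <- colMeans(dosage) / 2
  maf <- pmin(af, 1 - af)
  eligible <- which(maf >= min_maf)
  if (length(eligible) < 2L)
    stop2("locus has too few polymorphic variants (MAF >= %g)", min_maf)
  causal <- integer(0)
  r2_pair <- NA_real_
  if (scenario == "H4") {
    centre <- spec$n_variants / 2
    causal <- eligible[which.min(abs(eligible - centre))]
    cc <- causal_config("H4", trait_causal = causal, expr_causal = causal,
                        beta_trait = beta, beta_expr = beta,
                        noise_sd = noise_sd, n_samples = n_samples,
                        seed = seed + 1L)
  } else if (scenario == "H3") {
    blocks <- rep(seq_along(spec$block_lengths), spec$block_lengths)
    first <- intersect(eligible, which(blocks == 1L))
    last <- intersect(eligible, which(blocks == max(blocks)))
    if (!length(first) || !length(last))
      stop2("no eligible causal pair in the outer LD blocks")
    r2 <- stats::cor(dosage[, first, drop = FALSE],
                     dosage[, last, drop = FALSE])^2
    best <- arrayInd(which.min(r2), dim(r2))
    causal <- c(first[best[1L]], last[best[2L]])
    r2_pair <- min(r2)
    cc <- causal_config("H3", trait_causal = causal[1L],
                        expr_causal = causal[2L],
                        beta_trait = beta, beta_expr = beta,
                        noise_sd = noise_sd, n_samples = n_samples,
                        seed = seed + 1L)
  } else {
    cc <- causal_config("H0", noise_sd = noise_sd, n_samples = n_samples,
                        seed = seed + 1L)
  }
  bundle <- simulate_traits(hap, cc)
  pos <- bundle$variants$pos
  gwas <- eqtl_scan(bundle$genotypes, bundle$trait, pos, trait_id = "trait")
  eqtl <- eqtl_scan(bundle$genotypes, bundle$expression, pos,
                    trait_id = "expression")
  res <- coloc_posteriors(gwas, eqtl, priors)
  attr(res, "causal") <- causal
  attr(res, "causal_r2") <- r2_pair
  res
}

#' Replicate colocalisation calibration under a simulation scenario
#'
#' Runs [simulate_coloc_replicate()] over consecutive seeds and collects the
#' five posterior probabilities per replicate — the package's operating-
#' characteristics experiment for the shared-causal-variant decision rule.
#'
#' @param n_rep number of replicate loci.
#' @param scenario simulation scenario, see [simulate_coloc_replicate()].
#' @param seed seed of the first replicate (replicate i uses `seed + i - 1`).
#' @param ... further arguments passed to [simulate_coloc_replicate()].
#' @return data.frame with columns `seed`, `H0`..`H4`, `top` (hypothesis
#'   with the largest posterior).
#' @export
coloc_calibration <- function(n_rep = 100L, scenario = "H4", seed = 1L, ...) {
  rows <- lapply(seq_len(n_rep), function(i) {
    res <- simulate_coloc_replicate(seed + i - 1L, scenario = scenario, ...)
    pp <- res$pp
    data.frame(seed = seed + i - 1L, t(pp),
               top = names(pp)[which.max(pp)], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
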