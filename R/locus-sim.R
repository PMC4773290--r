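#' Specify a synthetic haplotype-block locus
#'
#' Defines the LD architecture of a simulated locus: variants are organised in
#' blocks, each block carries a small pool of founder haplotypes, and sample
#' haplotypes are assembled by copying founders block-by-block. Strong LD
#' within blocks and weak LD between them emulates the haplotype-block
#' structure typical of a trait-associated locus spanning a few hundred kb,
#' where hundreds of variants can sit at r-squared > 0.8 with the lead SNP.
#'
#' @param n_variants total number of biallelic variants at the locus.
#' @param block_lengths integer vector of variants per LD block; must sum to
#'   `n_variants`. Default: blocks of 15 (or one block if `n_variants` < 15).
#' @param n_founders founder haplotypes per block (>= 1). Fewer founders means
#'   stronger within-block LD; 2 founders with no mutation gives r2 = 1 for
#'   every segregating pair.
#' @param recomb_prob probability in \[0,1\] that a haplotype switches to a
#'   freshly drawn founder between adjacent blocks.
#' @param mutation_prob per-site allele flip probability in \[0,1\]; erodes LD.
#' @param positions strictly increasing 1-based bp coordinates, one per
#'   variant. Default: evenly spaced over ~250 kb starting at 1e5.
#' @param chrom chromosome label used in all emitted records.
#' @param seed integer seed; all randomness in the bundle flows from it.
#'
#' @return An object of class `locus_spec`.
#' @export
locus_spec <- function(n_variants = 60,
                       block_lengths = NULL,
                       n_founders = 4,
                       recomb_prob = 0.1,
                       mutation_prob = 0.01,
                       positions = NULL,
                       chrom = "1",
                       seed = 1L) {
  if (is.null(block_lengths)) {
    bl <- min(15L, n_variants)
    block_lengths <- rep(bl, n_variants %/% bl)
    if (n_variants %% bl) block_lengths <- c(block_lengths, n_variants %% bl)
  }
  if (sum(block_lengths) != n_variants)
    stop2("block_lengths must sum to n_variants (%d != %d)",
          sum(block_lengths), n_variants)
  if (n_founders < 1) stop2("n_founders must be >= 1")
  for (p in c(recomb_prob, mutation_prob))
    if (p < 0 || p > 1) stop2("probabilities must lie in [0,1]")
  if (is.null(positions)) {
    positions <- round(seq(100000L, 100000L + 250000L, length.out = n_variants))
    positions <- as.integer(positions + seq_len(n_variants) - 1L) # break ties
  }
  if (length(positions) != n_variants || any(diff(positions) <= 0))
    stop2("positions must be strictly increasing, one per variant")
  structure(list(n_variants = as.integer(n_variants),
                 block_lengths = as.integer(block_lengths),
                 n_founders = as.integer(n_founders),
                 recomb_prob = recomb_prob,
                 mutation_prob = mutation_prob,
                 positions = as.integer(positions),
                 chrom = as.character(chrom),
                 seed = as.integer(seed)),
            class = "locus_spec")
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("Synthetic locus spec: %d variants in %d blocks, %d founders/block\n",
              x$n_variants, length(x$block_lengths), x$n_founders))
  cat(sprintf("  span: chr%s:%d-%d; recomb_prob=%g, mutation_prob=%g, seed=%d\n",
              x$chrom, min(x$positions), max(x$positions),
              x$recomb_prob, x$mutation_prob, x$seed))
  invisible(x)
}

#' Configure the causal architecture of a simulated trait/expression pair
#'
#' Encodes which colocalisation hypothesis the simulated locus realises:
#' H0 no causal variant for either phenotype, H1 trait only, H2 expression
#' only, H3 two distinct causal variants, H4 one shared causal variant.
#'
#' @param scenario one of `"H0".."H4"`.
#' @param trait_causal,expr_causal causal variant column index (or `NA`).
#' @param beta_trait,beta_expr per-allele-copy effect in phenotype SD units.
#' @param noise_sd residual standard deviation.
#' @param n_samples cohort size.
#' @param seed integer seed for phenotype noise.
#' @return An object of class `causal_config`.
#' @export
causal_config <- function(scenario = c("H4", "H0", "H1", "H2", "H3"),
                          trait_causal = NA_integer_,
                          expr_causal = NA_integer_,
                          beta_trait = 0.4,
                          beta_expr = 0.4,
                          noise_sd = 1,
                          n_samples = 2000L,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  tc <- !is.na(trait_causal); ec <- !is.na(expr_causal)
  ok <- switch(scenario,
    H0 = !tc && !ec,
    H1 = tc && !ec,
    H2 = !tc && ec,
    H3 = tc && ec && trait_causal != expr_causal,
    H4 = tc && ec && trait_causal == expr_causal)
  if (!ok)
    stop2("causal indices inconsistent with scenario %s", scenario)
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  structure(list(scenario = scenario,
                 trait_causal = as.integer(trait_causal),
                 expr_causal = as.integer(expr_causal),
                 beta_trait = beta_trait, beta_expr = beta_expr,
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "causal_config")
}

#' Simulate phased haplotypes under the founder-copy model
#'
#' Each of the `2 * n_samples` haplotypes is assembled block-by-block by
#' copying one of the block's founder haplotypes, switching to a freshly
#' drawn founder between adjacent blocks with probability `recomb_prob`, then
#' flipping each site independently with probability `mutation_prob`.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [locus_spec()].
#' @param n_samples number of diploid samples.
#' @return `2*n_samples x n_variants` 0/1 matrix; columns named by variant id
#'   (`rs_sim_<i>`), with the spec attached as attribute `"spec"`.
#' @export
simulate_haplotypes <- function(spec, n_samples) {
  stopifnot(inherits(spec, "locus_spec"), n_samples >= 1)
  if (spec$n_founders < 1) stop2("invalid spec: n_founders < 1")
  n_hap <- 2L * as.integer(n_samples)
  with_seed(spec$seed, {
    # founder haplotype pools, one per block
    founders <- lapply(spec$block_lengths, function(len) {
      matrix(rbinom(spec$n_founders * len, 1L, 0.5),
             nrow = spec$n_founders, ncol = len)
    })
    hap <- matrix(0L, nrow = n_hap, ncol = spec$n_variants)
    # founder assignment chain across blocks
    f <- sample.int(spec$n_founders, n_hap, replace = TRUE)
    col0 <- 0L
    for (b in seq_along(spec$block_lengths)) {
      if (b > 1L) {
        switch_mask <- runif(n_hap) < spec$recomb_prob
        f[switch_mask] <- sample.int(spec$n_founders, sum(switch_mask),
                                     replace = TRUE)
      }
      len <- spec$block_lengths[b]
      hap[, col0 + seq_len(len)] <- founders[[b]][f, , drop = FALSE]
      col0 <- col0 + len
    }
    if (spec$mutation_prob > 0) {
      flips <- matrix(runif(length(hap)) < spec$mutation_prob,
                      nrow = n_hap)
      hap[flips] <- 1L - hap[flips]
    }
    colnames(hap) <- sprintf("rs_sim_%d", seq_len(spec$n_variants))
    attr(hap, "spec") <- spec
    hap
  })
}

#' Simulate a quantitative trait and an expression phenotype on haplotypes
#'
#' Genotype dosage is the per-sample haplotype sum; each phenotype is a linear
#' effect of its causal variant's dosage plus Gaussian noise. Under H0 both
#' phenotypes are pure noise. Deterministic given `config$seed`.
#'
#' @param haplotypes output of [simulate_haplotypes()].
#' @param config a [causal_config()]; `config$n_samples` must match the
#'   haplotype matrix.
#' @return An object of class `truth_bundle`: genotype dosage matrix, trait
#'   and expression vectors, variant table (id/chrom/pos/ref/alt/maf) and the
#'   causal configuration as ground truth.
#' @export
simulate_traits <- function(haplotypes, config) {
  stopifnot(inherits(config, "causal_config"))
  spec <- attr(haplotypes, "spec")
  n_var <- ncol(haplotypes)
  if (nrow(haplotypes) != 2L * config$n_samples)
    stop2("haplotype matrix has %d rows; expected 2*n_samples = %d",
          nrow(haplotypes), 2L * config$n_samples)
  for (idx in c(config$trait_causal, config$expr_causal))
    if (!is.na(idx) && (idx < 1L || idx > n_var))
      stop2("causal index %d outside 1..%d", idx, n_var)
  odd <- seq(1L, nrow(haplotypes), by = 2L)
  geno <- haplotypes[odd, , drop = FALSE] + haplotypes[odd + 1L, , drop = FALSE]
  rownames(geno) <- sprintf("S%04d", seq_len(config$n_samples))
  with_seed(config$seed, {
    n <- config$n_samples
    trait <- rnorm(n, 0, config$noise_sd)
    expression <- rnorm(n, 0, config$noise_sd)
    if (!is.na(config$trait_causal))
      trait <- trait + config$beta_trait * geno[, config$trait_causal]
    if (!is.na(config$expr_causal))
      expression <- expression + config$beta_expr * geno[, config$expr_causal]
    names(trait) <- names(expression) <- rownames(geno)
    alleles <- t(replicate(n_var, sample(c("A", "C", "G", "T"), 2L)))
    af <- colMeans(geno) / 2
    variants <- data.frame(
      id = colnames(geno),
      chrom = if (is.null(spec)) "1" else spec$chrom,
      pos = if (is.null(spec)) seq_len(n_var) else spec$positions,
      ref = alleles[, 1L], alt = alleles[, 2L],
      maf = pmin(af, 1 - af),
      stringsAsFactors = FALSE)
    structure(list(genotypes = geno, trait = trait, expression = expression,
                   variants = variants, causal_truth = config,
                   spec = spec, annotation_truth = NULL,
                   imbalance_truth = NULL, baf = NULL, annotations = NULL),
              class = "truth_bundle")
  })
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("Synthetic locus bundle: %d samples x %d variants (scenario %s)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$causal_truth$scenario))
  if (!is.na(x$causal_truth$trait_causal))
    cat(sprintf("  trait causal: %s (beta=%g)\n",
                x$variants$id[x$causal_truth$trait_causal],
                x$causal_truth$beta_trait))
  if (!is.na(x$causal_truth$expr_causal))
    cat(sprintf("  expression causal: %s (beta=%g)\n",
                x$variants$id[x$causal_truth$expr_causal],
                x$causal_truth$beta_expr))
  if (!is.null(x$annotation_truth))
    cat(sprintf("  annotation truth: %d within / %d near / %d none\n",
                sum(x$annotation_truth == "within"),
                sum(x$annotation_truth == "near"),
                sum(x$annotation_truth == "none")))
  invisible(x)
}

#' Simulate regulatory-annotation intervals with known per-variant labels
#'
#' Emulates regulatory tracks (DNase, histone, protein-bound peaks): a chosen
#' fraction of variants receives an interval covering their position
#' ("within"), another fraction an interval whose nearest edge sits a uniform
#' 1..`near_gap_bp` away ("near"); the remaining variants end up farther than
#' `near_gap_bp` from every interval. Placement is verified against the
#' intended labels and retried if variants interfere.
#'
#' @param positions 1-based variant positions (named by variant id if
#'   available).
#' @param fraction_within,fraction_near fractions of variants labelled
#'   within/near (sum <= 1).
#' @param interval_length_bp length of each simulated peak.
#' @param near_gap_bp maximum edge distance that still counts as "near".
#' @param chrom chromosome label.
#' @param seed integer seed.
#' @param max_tries placement attempts before giving up.
#' @return list with `intervals` (BED-convention data.frame: chrom, start
#'   0-based, end exclusive, track) and `truth` (within/near/none per variant).
#' @export
simulate_annotations <- function(positions, fraction_within, fraction_near,
                                 interval_length_bp = 200L,
                                 near_gap_bp = 500L, chrom = "1",
                                 seed = 1L, max_tries = 25L) {
  if (fraction_within + fraction_near > 1)
    stop2("fraction_within + fraction_near must be <= 1")
  n <- length(positions)
  ids <- names(positions) %||% sprintf("rs_sim_%d", seq_len(n))
  tracks <- c("promoter_histone", "enhancer_histone", "dnase", "protein_bound")
  with_seed(seed, {
    n_within <- round(fraction_within * n)
    n_near <- round(fraction_near * n)
    chosen <- sample.int(n, n_within + n_near)
    truth <- rep("none", n); names(truth) <- ids
    truth[chosen[seq_len(n_within)]] <- "within"
    if (n_near > 0) truth[chosen[n_within + seq_len(n_near)]] <- "near"
    for (try in seq_len(max_tries)) {
      rows <- list()
      k <- 0L
      for (i in which(truth != "none")) {
        k <- k + 1L
        len <- interval_length_bp
        if (truth[i] == "within") {
          offset <- sample.int(len, 1L) - 1L      # pos covered by interval
          start1 <- positions[i] - offset
        } else {
          gap <- sample.int(near_gap_bp, 1L)
          if (runif(1) < 0.5) start1 <- positions[i] + gap   # right of SNP
          else start1 <- positions[i] - gap - len + 1L       # left of SNP
        }
        start1 <- max(1L, start1)
        rows[[k]] <- data.frame(chrom = chrom, start = start1 - 1L,
                                end = start1 + len - 1L,
                                track = tracks[1L + (k - 1L) %% length(tracks)],
                                stringsAsFactors = FALSE)
      }
      intervals <- if (k) do.call(rbind, rows) else
        data.frame(chrom = character(), start = integer(), end = integer(),
                   track = character(), stringsAsFactors = FALSE)
      # verify realised labels match intent (variants can interfere)
      realised <- vapply(positions, function(p) {
        naive_status(p, intervals$start, intervals$end, near_gap_bp)
      }, character(1))
      if (all(realised == truth)) {
        return(list(intervals = intervals, truth = truth))
      }
    }
    stop2("could not place annotation intervals consistent with labels after %d tries",
          max_tries)
  })
}

# status of one 1-based position against 0-based half-open intervals
naive_status <- function(pos, start0, end0, near_bp) {
  if (length(start0) == 0L) return("none")
  p0 <- pos - 1L
  if (any(start0 <= p0 & p0 < end0)) return("within")
  gap <- pmax(start0 - p0, p0 - end0 + 1L)
  if (min(gap) <= near_bp) "near" else "none"
}

#' Simulate paired control/FAIRE B-allele-frequency records
#'
#' For each sample and variant, emits a control (non-enriched chromatin) and a
#' FAIRE-enriched BAF readout. Heterozygotes centre at 0.5 in the control arm
#' and at `0.5 + shift` under FAIRE, so a non-zero shift injects an
#' allele-specific chromatin-accessibility imbalance; homozygotes cluster at 0
#' or 1 in both arms. Gaussian noise is added and values are clipped to
#' \[0,1\].
#'
#' @param genotypes sample x variant dosage matrix (0/1/2).
#' @param imbalance named numeric vector of BAF shifts in (-0.5, 0.5), one per
#'   assayed variant (names must be genotype columns); variants without an
#'   entry are not assayed.
#' @param baf_noise_sd readout noise SD.
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `variant`, `treatment`
#'   (`control`/`faire`), `baf`.
#' @export
simulate_faire_baf <- function(genotypes, imbalance, baf_noise_sd = 0.02,
                               seed = 1L) {
  if (any(abs(imbalance) >= 0.5))
    stop2("imbalance shifts must lie in (-0.5, 0.5)")
  bad <- setdiff(names(imbalance), colnames(genotypes))
  if (length(bad)) stop2("unknown variants in imbalance map: %s",
                         paste(bad, collapse = ", "))
  with_seed(seed, {
    out <- lapply(names(imbalance), function(v) {
      g <- genotypes[, v]
      centre_ctrl <- c(`0` = 0, `1` = 0.5, `2` = 1)[as.character(g)]
      centre_faire <- centre_ctrl + ifelse(g == 1L, imbalance[[v]], 0)
      n <- length(g)
      data.frame(
        sample = rep(rownames(genotypes), 2L),
        variant = v,
        treatment = rep(c("control", "faire"), each = n),
        baf = pmin(1, pmax(0, c(centre_ctrl, centre_faire) +
                                rnorm(2L * n, 0, baf_noise_sd))),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate a complete locus bundle
#'
#' Convenience wrapper chaining [simulate_haplotypes()], [simulate_traits()],
#' [simulate_annotations()] and [simulate_faire_baf()] into one
#' `truth_bundle` driven by a single seed, ready for [run_pipeline()] or
#' [write_fixture_bundle()].
#'
#' @param spec a [locus_spec()] (its seed is overridden by `seed`).
#' @param config a [causal_config()] (its seed is overridden by `seed + 1`).
#' @param fraction_within,fraction_near annotated fractions, see
#'   [simulate_annotations()].
#' @param faire_variants variant ids to assay; default: the causal variant(s).
#' @param faire_shift injected heterozygote BAF shift for assayed variants.
#' @param baf_noise_sd BAF readout noise.
#' @param seed master integer seed.
#' @return a `truth_bundle` with annotation and BAF components filled in.
#' @export
simulate_locus <- function(spec = locus_spec(),
                           config = causal_config(trait_causal = 30L,
                                                  expr_causal = 30L),
                           fraction_within = 0.2, fraction_near = 0.1,
                           faire_variants = NULL, faire_shift = 0.1,
                           baf_noise_sd = 0.02, seed = 1L) {
  spec$seed <- as.integer(seed)
  config$seed <- as.integer(seed) + 1L
  hap <- simulate_haplotypes(spec, config$n_samples)
  bundle <- simulate_traits(hap, config)
  pos <- bundle$variants$pos
  names(pos) <- bundle$variants$id
  ann <- simulate_annotations(pos, fraction_within, fraction_near,
                              chrom = spec$chrom, seed = seed + 2L)
  bundle$annotations <- ann$intervals
  bundle$annotation_truth <- ann$truth
  if (is.null(faire_variants)) {
    faire_variants <- bundle$variants$id[
      unique(stats::na.omit(c(config$trait_causal, config$expr_causal)))]
  }
  if (length(faire_variants)) {
    shifts <- stats::setNames(rep(faire_shift, length(faire_variants)),
                              faire_variants)
    bundle$baf <- simulate_faire_baf(bundle$genotypes, shifts,
                                     baf_noise_sd = baf_noise_sd,
                                     seed = seed + 3L)
    bundle$imbalance_truth <- shifts
  }
  bundle
}
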