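# Locus simulator: founder-copy haplotypes, phenotypes, annotations, BAF.

test_that("degenerate founder settings give the expected haplotype structure", {
  # single founder, no recombination/mutation: every haplotype identical
  spec1 <- locus_spec(n_variants = 20, block_lengths = c(10, 10),
                      n_founders = 1, recomb_prob = 0, mutation_prob = 0,
                      seed = 3)
  hap1 <- simulate_haplotypes(spec1, n_samples = 25)
  expect_equal(nrow(unique(hap1)), 1L)

  # two founders, no mutation: r2 = 1 for every segregating pair in a block
  spec2 <- locus_spec(n_variants = 20, block_lengths = 20, n_founders = 2,
                      recomb_prob = 0, mutation_prob = 0, seed = 11)
  hap2 <- simulate_haplotypes(spec2, n_samples = 100)
  seg <- which(apply(hap2, 2, var) > 0)
  expect_gt(length(seg), 1)
  for (j in seg[-1]) {
    expect_equal(dosage_r2(hap2[, seg[1]], hap2[, j])$r2, 1, tolerance = 1e-12)
  }
})

test_that("simulation is bit-identical under the same seed", {
  spec <- locus_spec(seed = 7)
  h1 <- simulate_haplotypes(spec, 50)
  h2 <- simulate_haplotypes(spec, 50)
  expect_identical(h1, h2)
  cc <- causal_config("H4", 5L, 5L, n_samples = 50L, seed = 7L)
  expect_identical(simulate_traits(h1, cc)$trait, simulate_traits(h2, cc)$trait)
})

test_that("invalid specs and causal configurations are rejected", {
  expect_error(locus_spec(n_variants = 10, block_lengths = c(4, 4)),
               "sum")
  expect_error(locus_spec(n_founders = 0), "n_founders")
  expect_error(locus_spec(recomb_prob = 1.5), "probabilities")
  expect_error(causal_config("H4", trait_causal = 1L, expr_causal = 2L),
               "inconsistent")
  expect_error(causal_config("H3", trait_causal = 1L, expr_causal = 1L),
               "inconsistent")
  expect_error(causal_config("H0", trait_causal = 1L), "inconsistent")
  hap <- simulate_haplotypes(locus_spec(n_variants = 15,
                                        block_lengths = 15, seed = 1), 10)
  expect_error(simulate_traits(hap, causal_config("H1", trait_causal = 99L,
                                                  n_samples = 10L)),
               "outside")
})

test_that("phenotypes follow the causal model", {
  spec <- locus_spec(seed = 5)
  hap <- simulate_haplotypes(spec, 500)

  # H0: no dosage column correlates with the trait
  b0 <- simulate_traits(hap, causal_config("H0", n_samples = 500L, seed = 2L))
  r <- abs(cor(b0$trait, b0$genotypes))
  r <- r[!is.na(r)]   # monomorphic columns have no correlation
  expect_lt(max(r), 0.2)

  # H4 with zero noise: phenotypes are deterministic in the causal dosage
  b4 <- simulate_traits(hap, causal_config("H4", 30L, 30L, beta_trait = 0.5,
                                           beta_expr = 0.5, noise_sd = 0,
                                           n_samples = 500L, seed = 2L))
  expect_equal(cor(b4$trait, b4$genotypes[, 30], method = "spearman"), 1)
  expect_equal(cor(b4$expression, b4$genotypes[, 30], method = "spearman"), 1)
})

test_that("a strong shared signal reaches genome-wide significance", {
  # power at n=2000, beta=0.4: non-centrality n*beta^2*2f(1-f)/var(y) makes
  # p < 5e-8 at the causal variant essentially certain
  res <- simulate_coloc_replicate(1, "H4")
  causal <- attr(res, "causal")
  expect_gt(res$log_abf_1[causal], 10)
  expect_gt(res$log_abf_2[causal], 10)
  spec <- locus_spec(seed = 1)
  hap <- simulate_haplotypes(spec, 2000)
  b <- simulate_traits(hap, causal_config("H4", causal, causal,
                                          n_samples = 2000L, seed = 2L))
  stat <- marginal_regression(b$genotypes[, causal], b$trait)
  expect_lt(stat$p, 5e-8)
})

test_that("simulated MAF tracks the founder-pool frequency", {
  spec <- locus_spec(n_variants = 30, block_lengths = 30, n_founders = 4,
                     recomb_prob = 0, mutation_prob = 0, seed = 21)
  n <- 400
  hap <- simulate_haplotypes(spec, n)
  # founder pool frequencies recovered from the distinct haplotype rows
  af <- colMeans(hap)
  # founders drawn uniformly: binomial sampling error around pool frequency
  pool <- colMeans(unique(hap))
  tol <- 4 * sqrt(0.25 / (2 * n)) + 0.15   # pool freq itself is estimated
  expect_true(all(abs(af - pool) < tol))
})

test_that("within-block LD decays as the mutation rate rises", {
  mean_r2 <- function(mut) {
    vals <- vapply(1:50, function(s) {
      spec <- locus_spec(n_variants = 10, block_lengths = 10, n_founders = 2,
                         recomb_prob = 0, mutation_prob = mut, seed = s)
      hap <- simulate_haplotypes(spec, 60)
      seg <- which(apply(hap, 2, var) > 0)
      if (length(seg) < 2) return(NA_real_)
      pairs <- combn(seg, 2)
      mean(apply(pairs, 2, function(ij)
        tryCatch(dosage_r2(hap[, ij[1]], hap[, ij[2]])$r2,
                 error = function(e) NA_real_)), na.rm = TRUE)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  r2_levels <- c(mean_r2(0), mean_r2(0.05), mean_r2(0.25))
  expect_equal(r2_levels[1], 1, tolerance = 1e-12)
  expect_true(all(diff(r2_levels) < 0))
})

test_that("annotation placement honours the intended labels", {
  pos <- seq(1000, 250000, length.out = 46)
  names(pos) <- sprintf("v%02d", 1:46)

  sat <- simulate_annotations(pos, fraction_within = 1, fraction_near = 0,
                              seed = 4)
  expect_true(all(sat$truth == "within"))

  none <- simulate_annotations(pos, 0, 0, seed = 4)
  expect_true(all(none$truth == "none"))
  expect_equal(nrow(none$intervals), 0L)

  # fractions tuned to the 33-within / 13-near split of a 46-variant pool
  ann <- simulate_annotations(pos, fraction_within = 33 / 46,
                              fraction_near = 13 / 46, seed = 4)
  expect_equal(sum(ann$truth == "within"), 33L)
  expect_equal(sum(ann$truth == "near"), 13L)

  # realised labels via the annotator match the recorded truth
  vars <- data.frame(id = names(pos), pos = as.integer(pos))
  m <- build_annotation_matrix(vars, ann$intervals)
  expect_identical(unname(attr(m, "summary")), unname(ann$truth))
  expect_error(simulate_annotations(pos, 0.7, 0.6, seed = 1), "<= 1")
})

test_that("BAF generation encodes genotype clusters and injected shifts", {
  geno <- matrix(c(0, 1, 1, 2, 1, 1, 1, 1, 1, 1), ncol = 1,
                 dimnames = list(sprintf("S%02d", 1:10), "v1"))
  # noiseless null: FAIRE and control identical for every sample
  b0 <- simulate_faire_baf(geno, c(v1 = 0), baf_noise_sd = 0, seed = 1)
  ctrl <- b0$baf[b0$treatment == "control"]
  faire <- b0$baf[b0$treatment == "faire"]
  expect_identical(ctrl, faire)
  expect_equal(sort(unique(ctrl)), c(0, 0.5, 1))

  # injected shift moves heterozygote FAIRE BAF; construction mirrors a
  # ~20% relative enrichment (0.5 -> 0.602)
  g10 <- matrix(1, nrow = 10, ncol = 1,
                dimnames = list(sprintf("S%02d", 1:10), "v1"))
  b1 <- simulate_faire_baf(g10, c(v1 = 0.102), baf_noise_sd = 0.02, seed = 9)
  mf <- mean(b1$baf[b1$treatment == "faire"])
  expect_equal(mf, 0.602, tolerance = 0.02)
  imb <- allelic_imbalance(b1[, c("sample", "treatment", "baf")])
  expect_equal(imb$enrichment_pct, 20.4, tolerance = 3)

  expect_error(simulate_faire_baf(geno, c(v1 = 0.6)), "shifts")
  expect_error(simulate_faire_baf(geno, c(nope = 0.1)), "unknown")
})
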