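# Dosage r^2 and the union candidate-selection rule.

test_that("dosage r2 matches the Pearson definition and its symmetries", {
  a <- c(0, 1, 2, 0, 1, 2)
  expect_equal(dosage_r2(a, a)$r2, 1)
  expect_equal(dosage_r2(a, 2 - a)$r2, 1)         # allele-label flip
  # six-pair fixture checked against the hand-computed Pearson value
  expect_equal(dosage_r2(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 1, 2))$r2,
               0.5, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:100) {
    x <- sample(0:2, 30, replace = TRUE)
    y <- sample(0:2, 30, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    got <- dosage_r2(x, y)
    expect_equal(got$r2, oracle_r2(x, y), tolerance = 1e-12)
    expect_true(got$r2 >= 0 && got$r2 <= 1)
    expect_equal(got$r2, dosage_r2(y, x)$r2)
  }
})

test_that("undefined LD and malformed input raise errors", {
  expect_error(dosage_r2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
  expect_error(dosage_r2(0:2, 0:1), "length")
  expect_error(dosage_r2(c(0, NA), c(NA, 1)), "pairwise-complete")
})

test_that("missing genotypes are handled pairwise-complete", {
  x <- c(0, 1, 2, NA, 1, 0, 2, 1)
  y <- c(0, 1, 2, 1, NA, 0, 2, 1)
  got <- dosage_r2(x, y)
  expect_equal(got$n_informative, 6L)
  ok <- !is.na(x) & !is.na(y)
  expect_equal(got$r2, oracle_r2(x[ok], y[ok]), tolerance = 1e-12)
})

test_that("ld_with_lead reports every variant and flags undefined sites", {
  spec <- locus_spec(n_variants = 12, block_lengths = 12, n_founders = 2,
                     recomb_prob = 0, mutation_prob = 0, seed = 2)
  hap <- simulate_haplotypes(spec, 80)
  geno <- hap[seq(1, 160, 2), ] + hap[seq(2, 160, 2), ]
  seg <- which(apply(geno, 2, var) > 0)
  lead <- colnames(geno)[seg[1]]
  ld <- ld_with_lead(geno, lead)
  expect_equal(nrow(ld), 12L)
  expect_equal(ld$r2[ld$variant == lead], 1)
  # two founders, no mutation: every defined pair is in perfect LD
  expect_true(all(abs(ld$r2[ld$defined] - 1) < 1e-12))
  expect_true(all(!ld$defined | !is.na(ld$r2)))
  expect_error(ld_with_lead(geno, "rs_nope"), "rs_nope")
})

test_that("dosage r2 recovers the closed-form haplotype r2", {
  # three founders with known patterns at two sites; population haplotype
  # frequencies give r2 = D^2 / (pA(1-pA) pB(1-pB))
  founders <- matrix(c(1, 1,
                       1, 0,
                       0, 0), ncol = 2, byrow = TRUE)
  set.seed(33)
  n_hap <- 6000
  f <- sample(1:3, n_hap, replace = TRUE)
  hap <- founders[f, ]
  pA <- mean(founders[, 1]); pB <- mean(founders[, 2])
  p11 <- mean(founders[, 1] == 1 & founders[, 2] == 1)
  D <- p11 - pA * pB
  r2_pop <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dos <- hap[seq(1, n_hap, 2), ] + hap[seq(2, n_hap, 2), ]
  expect_equal(dosage_r2(dos[, 1], dos[, 2])$r2, r2_pop, tolerance = 0.05)
})

test_that("candidate selection applies the union rule with correct bounds", {
  ld <- data.frame(variant = paste0("v", 1:5), lead = "v1",
                   r2 = c(1, 0.8, 0.79, 0.2, 0.5),
                   n_informative = 100L, defined = TRUE)
  gwas <- data.frame(variant = paste0("v", 1:5), pos = c(1e5, 2e5, 3e5, 4e5, 9e6),
                     p = c(1e-9, 0.5, 1, 4e-8, 1e-12))
  eqtl <- data.frame(variant = paste0("v", 1:5), p = c(0.9, 1e-9, 1e-9, 1, 1))

  # nothing significant anywhere -> empty set with a warning
  ld0 <- ld; ld0$r2 <- 0.1
  g0 <- gwas; g0$p <- 1
  expect_warning(cs0 <- select_candidates(ld0, g0, NULL), "no variants")
  expect_equal(nrow(cs0), 0L)

  cs <- select_candidates(ld, gwas, eqtl, gene_anchor_pos = 2e5)
  # v2: r2 exactly 0.8 -> retained (inclusive threshold)
  expect_true("v2" %in% cs$variant)
  expect_true(cs$ld_with_lead[cs$variant == "v2"])
  # v3: r2 just below, eQTL significant but not in LD -> excluded
  expect_false("v3" %in% cs$variant)
  # v4: GWAS p = 4e-8 < 5e-8 within window -> retained via GWAS flag only
  expect_true(cs$gwas_significant[cs$variant == "v4"])
  expect_false(cs$ld_with_lead[cs$variant == "v4"])
  # v5: genome-wide significant but 8.8 Mb from the anchor -> no GWAS flag
  expect_false("v5" %in% cs$variant)
  # every retained variant carries at least one provenance flag
  expect_true(all(cs$ld_with_lead | cs$gwas_significant | cs$eqtl_significant))
})

test_that("selection is anti-monotone in thresholds and union-consistent", {
  set.seed(7)
  n <- 40
  ld <- data.frame(variant = paste0("v", 1:n), lead = "v1",
                   r2 = runif(n), n_informative = 100L, defined = TRUE)
  gwas <- data.frame(variant = ld$variant, pos = round(runif(n, 1, 1e6)),
                     p = 10^runif(n, -12, 0))
  eqtl <- data.frame(variant = ld$variant, p = 10^runif(n, -12, 0))
  base <- select_candidates(ld, gwas, eqtl, gene_anchor_pos = 5e5)
  stricter <- select_candidates(ld, gwas, eqtl, r2_min = 0.9,
                                p_gwas = 5e-10, gene_anchor_pos = 5e5)
  expect_true(all(stricter$variant %in% base$variant))

  # dropping the eQTL table removes only variants whose sole flag was eQTL
  no_eqtl <- suppressWarnings(select_candidates(ld, gwas, NULL,
                                                gene_anchor_pos = 5e5))
  removed <- setdiff(base$variant, no_eqtl$variant)
  sole_eqtl <- base$variant[base$eqtl_significant &
                              !base$ld_with_lead & !base$gwas_significant]
  expect_setequal(removed, sole_eqtl)
})

test_that("candidates on a simulated shared-causal locus match the truth tables", {
  res <- simulate_coloc_replicate(3, "H4")
  spec <- locus_spec(seed = 3)
  hap <- simulate_haplotypes(spec, 2000)
  causal <- attr(res, "causal")
  b <- simulate_traits(hap, causal_config("H4", causal, causal,
                                          n_samples = 2000L, seed = 4L))
  gwas <- eqtl_scan(b$genotypes, b$trait, b$variants$pos, trait_id = "trait")
  ld <- ld_with_lead(b$genotypes, b$variants$id[causal])
  cs <- select_candidates(ld, gwas, NULL)
  # expected set recomputed directly from the evidence tables
  expected <- union(ld$variant[ld$defined & ld$r2 >= 0.8],
                    gwas$variant[gwas$p < 5e-8])
  expect_setequal(cs$variant, expected)
  expect_true(b$variants$id[causal] %in% cs$variant)
})
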