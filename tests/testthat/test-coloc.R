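# Approximate Bayes factors and five-hypothesis colocalisation posteriors.

test_that("log ABF follows the closed form and its limits", {
  # frozen value from an independent high-precision evaluation of
  # 0.5*(log(1-r) + r z^2) with V=0.01, w=0.0225
  expect_equal(log_abf(0.5, 0.1, 0.0225), 8.064518655675331,
               tolerance = 1e-12)
  # null effect: log ABF = 0.5 log(1-r) < 0
  expect_lt(log_abf(0, 0.1, 0.0225), 0)
  expect_equal(log_abf(0, 0.1, 0.0225), 0.5 * log(1 - 0.0225 / 0.0325),
               tolerance = 1e-12)
  # vacuous prior: w -> 0 gives log ABF -> 0
  expect_equal(log_abf(0.5, 0.1, 1e-14), 0, tolerance = 1e-6)
  expect_error(log_abf(0.5, 0), "se")
  expect_error(log_abf(0.5, 0.1, w = -1), "w")
})

test_that("p-to-z and frequency-to-variance conversions are exact", {
  expect_equal(zscore_from_p(1), 0)
  expect_equal(zscore_from_p(0.05), 1.959964, tolerance = 1e-6)
  expect_equal(zscore_from_p(0.05, sign = -1), -1.959964, tolerance = 1e-6)
  expect_error(zscore_from_p(0), "beta/se")
  expect_equal(var_from_freq(0.5, 1000), 0.002)
  expect_error(var_from_freq(0.6, 100), "maf")
})

test_that("prior constraints are enforced", {
  expect_error(coloc_priors(p12 = 1e-3), "p12")
  expect_error(coloc_priors(w1 = 0), "variances")
  pr <- coloc_priors()
  expect_equal(c(pr$p1, pr$p2, pr$p12), c(1e-4, 1e-4, 1e-5))
})

test_that("single-variant algebra zeroes H3 exactly", {
  s1 <- data.frame(variant = "v1", beta = 0.5, se = 0.05)
  s2 <- data.frame(variant = "v1", beta = 0.4, se = 0.05)
  res <- coloc_posteriors(s1, s2)
  expect_identical(unname(res$pp["H3"]), 0)
  expect_true(res$pp["H4"] > max(res$pp[c("H0", "H1", "H2")]))
  expect_equal(sum(res$pp), 1, tolerance = 1e-12)
})

test_that("posteriors match the exhaustive configuration-enumeration oracle", {
  # three-variant fixture with fixed effects and standard errors
  ids <- c("v1", "v2", "v3")
  b1 <- c(0.30, 0.10, -0.05); s1 <- c(0.08, 0.10, 0.06)
  b2 <- c(0.25, -0.02, 0.40); s2 <- c(0.07, 0.09, 0.12)
  res <- coloc_posteriors(data.frame(variant = ids, beta = b1, se = s1),
                          data.frame(variant = ids, beta = b2, se = s2))
  l1 <- log_abf(b1, s1); l2 <- log_abf(b2, s2)
  expect_equal(unname(res$log_abf_1), l1, tolerance = 1e-12)
  expect_equal(unname(res$pp),
               unname(oracle_coloc(l1, l2)), tolerance = 1e-10)

  # 100 random instances with up to 6 variants
  set.seed(101)
  for (i in 1:100) {
    m <- sample(1:6, 1)
    b1 <- rnorm(m, 0, 0.3); b2 <- rnorm(m, 0, 0.3)
    se1 <- runif(m, 0.05, 0.3); se2 <- runif(m, 0.05, 0.3)
    ids <- paste0("v", 1:m)
    res <- coloc_posteriors(data.frame(variant = ids, beta = b1, se = se1),
                            data.frame(variant = ids, beta = b2, se = se2))
    want <- oracle_coloc(log_abf(b1, se1), log_abf(b2, se2))
    expect_equal(unname(res$pp), unname(want), tolerance = 1e-10)
    expect_equal(sum(res$pp), 1, tolerance = 1e-12)
    expect_true(all(res$pp >= 0))
  }
})

test_that("null signals favour H0 and trait swap permutes H1/H2", {
  ids <- paste0("v", 1:5)
  null1 <- data.frame(variant = ids, beta = 0, se = 0.2)
  null2 <- data.frame(variant = ids, beta = 0, se = 0.2)
  res0 <- coloc_posteriors(null1, null2)
  expect_equal(names(which.max(res0$pp)), "H0")

  set.seed(55)
  s1 <- data.frame(variant = ids, beta = rnorm(5, 0.2, 0.2),
                   se = runif(5, 0.05, 0.2))
  s2 <- data.frame(variant = ids, beta = rnorm(5, 0, 0.2),
                   se = runif(5, 0.05, 0.2))
  pr <- coloc_priors(p1 = 2e-4, p2 = 5e-5, p12 = 1e-5, w1 = 0.03, w2 = 0.01)
  pr_sw <- coloc_priors(p1 = 5e-5, p2 = 2e-4, p12 = 1e-5, w1 = 0.01,
                        w2 = 0.03)
  a <- coloc_posteriors(s1, s2, pr)
  b <- coloc_posteriors(s2, s1, pr_sw)
  expect_equal(unname(a$pp[c("H0", "H3", "H4")]),
               unname(b$pp[c("H0", "H3", "H4")]), tolerance = 1e-12)
  expect_equal(unname(a$pp["H1"]), unname(b$pp["H2"]), tolerance = 1e-12)
  expect_equal(unname(a$pp["H2"]), unname(b$pp["H1"]), tolerance = 1e-12)
})

test_that("variants present in one table only are dropped with a message", {
  s1 <- data.frame(variant = c("a", "b", "c"), beta = 0.1, se = 0.1)
  s2 <- data.frame(variant = c("b", "c", "d"), beta = 0.1, se = 0.1)
  expect_message(res <- coloc_posteriors(s1, s2), "dropped 2")
  expect_equal(res$n_variants, 2L)
  expect_error(coloc_posteriors(s1, data.frame(variant = "z", beta = 1,
                                               se = 1)), "shared")
})

test_that("p/maf/n parameterised tables reproduce beta/se results", {
  set.seed(9)
  n <- 5000; maf <- 0.3
  beta <- c(0.15, -0.02, 0.08)
  se <- sqrt(var_from_freq(maf, n))
  z <- beta / se
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  ids <- paste0("v", 1:3)
  full <- data.frame(variant = ids, beta = beta, se = se)
  # p/maf/n route: sign carried by a beta column without a usable se
  reduced <- data.frame(variant = ids, beta = sign(beta), se = NA_real_,
                        p = p, maf = maf, n = n)
  other <- data.frame(variant = ids, beta = c(0.1, 0.1, 0.1), se = 0.05)
  a <- coloc_posteriors(full, other)
  b <- coloc_posteriors(reduced, other)
  expect_equal(unname(a$pp), unname(b$pp), tolerance = 1e-6)
})

test_that("the strong-evidence rule uses a strict 75% threshold", {
  res <- structure(list(pp = c(H0 = 0.01, H1 = 0.02, H2 = 0.02, H3 = 0.026,
                               H4 = 0.924),
                        n_variants = 10L, priors = coloc_priors(),
                        log_abf_1 = numeric(), log_abf_2 = numeric()),
                   class = "coloc_result")
  expect_equal(unname(coloc_classify(res)["H4"]), "strong")
  res$pp <- c(H0 = 0.05, H1 = 0.05, H2 = 0.05, H3 = 0.10, H4 = 0.75)
  expect_equal(unname(coloc_classify(res)["H4"]), "inconclusive")
  res$pp <- c(H0 = 0.2, H1 = 0.2, H2 = 0.2, H3 = 0.2, H4 = 0.2)
  expect_true(all(coloc_classify(res) == "inconclusive"))
})

test_that("simulated shared and distinct causal scenarios are recovered", {
  # reduced-size recovery check; the full calibration runs in the
  # acceptance suite
  h4 <- suppressMessages(coloc_calibration(10, "H4", seed = 201))
  expect_gt(median(h4$H4), 0.75)
  h3 <- suppressMessages(coloc_calibration(10, "H3", seed = 201))
  expect_gt(median(h3$H3 - h3$H4), 0)
})
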