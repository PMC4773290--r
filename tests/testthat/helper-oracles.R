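# Independent brute-force oracles used to check the implementation paths.

# two-pass Pearson r^2 from the textbook formula
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  (num / den)^2
}

# OLS of y on (1, g) via explicit normal equations, se and two-sided t p
oracle_ols <- function(g, y) {
  n <- length(g)
  sxx <- sum(g^2) - sum(g)^2 / n
  sxy <- sum(g * y) - sum(g) * sum(y) / n
  beta <- sxy / sxx
  alpha <- mean(y) - beta * mean(g)
  rss <- sum((y - alpha - beta * g)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- beta / se
  list(beta = beta, se = se, t = t,
       p = 2 * pt(abs(t), n - 2, lower.tail = FALSE))
}

# five-hypothesis posteriors by direct summation over causal configurations
# (raw Bayes factors; only safe for modest log BFs)
oracle_coloc <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  bf1 <- exp(labf1); bf2 <- exp(labf2)
  m <- length(bf1)
  w0 <- 1
  w1 <- p1 * sum(bf1)
  w2 <- p2 * sum(bf2)
  w3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    if (i != j) w3 <- w3 + p1 * p2 * bf1[i] * bf2[j]
  w4 <- p12 * sum(bf1 * bf2)
  w <- c(H0 = w0, H1 = w1, H2 = w2, H3 = w3, H4 = w4)
  w / sum(w)
}

# character-by-character reverse complement
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive O(I) distance scan for one variant against 0-based half-open intervals
oracle_annotation_status <- function(pos, start0, end0, near_bp) {
  if (length(start0) == 0) return(list(status = "none", distance = Inf))
  p0 <- pos - 1
  if (any(start0 <= p0 & p0 < end0))
    return(list(status = "within", distance = 0))
  d <- min(pmax(start0 - p0, p0 - (end0 - 1)))
  list(status = if (d <= near_bp) "near" else "none", distance = d)
}

# one-sample t on paired differences from first principles
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(abs(t), n - 1, lower.tail = FALSE))
}
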