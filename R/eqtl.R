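#' Cis window around a gene/probe anchor
#'
#' @param anchor_pos 1-based anchor position (expression probe or gene).
#' @param chrom chromosome label.
#' @param half_width_bp window half-width; default 200 kb each side.
#' @return list of class `cis_window` with `chrom`, `start`, `end` (1-based
#'   inclusive, start clipped at 1), `anchor_pos`, `half_width_bp`.
#' @export
cis_window <- function(anchor_pos, chrom = "1", half_width_bp = 200000L) {
  if (anchor_pos < 1) stop2("anchor_pos must be >= 1")
  structure(list(chrom = as.character(chrom),
                 start = max(1L, as.integer(anchor_pos - half_width_bp)),
                 end = as.integer(anchor_pos + half_width_bp),
                 anchor_pos = as.integer(anchor_pos),
                 half_width_bp = as.integer(half_width_bp)),
            class = "cis_window")
}

#' Marginal linear regression of a phenotype on allele dosage
#'
#' Ordinary least squares of the phenotype on an intercept plus dosage over
#' pairwise-complete samples; the standard error comes from the residual
#' variance on n-2 degrees of freedom and the two-sided p-value from the
#' Student-t reference.
#'
#' @param dosage per-sample dosage vector.
#' @param phenotype per-sample phenotype vector.
#' @param variant_id,trait_id identifiers carried into the result.
#' @return one-row data.frame with `variant`, `trait`, `beta`, `se`, `z`
#'   (beta/se), `p`, `n`, `maf`, `degenerate` (TRUE when the fit is perfect:
#'   se = 0 and p reported as 0).
#' @export
marginal_regression <- function(dosage, phenotype, variant_id = "variant",
                                trait_id = "trait") {
  ok <- !is.na(dosage) & !is.na(phenotype)
  n <- sum(ok)
  if (n < 3L) stop2("need >= 3 pairwise-complete samples, got %d", n)
  g <- dosage[ok]; y <- phenotype[ok]
  if (stats::var(g) == 0)
    stop2("no test: dosage is monomorphic among complete samples")
  fit <- stats::lm.fit(cbind(1, g), y)
  beta <- unname(fit$coefficients[2L])
  rss <- sum(fit$residuals^2)
  df <- n - 2L
  sxx <- sum((g - mean(g))^2)
  degenerate <- rss <= .Machine$double.eps * sum(y^2)
  if (degenerate) {
    se <- 0; z <- sign(beta) * Inf; p <- 0
  } else {
    se <- sqrt(rss / df / sxx)
    z <- beta / se
    p <- 2 * stats::pt(abs(z), df, lower.tail = FALSE)
  }
  af <- mean(g) / 2
  data.frame(variant = variant_id, trait = trait_id, beta = beta, se = se,
             z = z, p = p, n = n, maf = min(af, 1 - af),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Scan all variants in a cis window against one phenotype
#'
#' Runs [marginal_regression()] for every polymorphic variant whose position
#' falls inside the window, ordered by position. Variants that cannot be
#' tested (monomorphic, too few complete samples) are listed in a skip
#' report attached as attribute `"skipped"`.
#'
#' @param genotypes sample x variant dosage matrix.
#' @param phenotype per-sample phenotype vector (aligned with rows).
#' @param positions 1-based positions, one per genotype column.
#' @param window a [cis_window()], or `NULL` to scan every variant.
#' @param trait_id trait label for the output rows.
#' @return data.frame of association statistics (one row per tested variant),
#'   ordered by position.
#' @export
eqtl_scan <- function(genotypes, phenotype, positions = NULL, window = NULL,
                      trait_id = "expression") {
  vars <- colnames(genotypes)
  if (is.null(positions)) positions <- seq_along(vars)
  stopifnot(length(positions) == length(vars))
  inside <- if (is.null(window)) rep(TRUE, length(vars)) else
    positions >= window$start & positions <= window$end
  if (!any(inside)) {
    warn2("cis window contains no variants")
    return(empty_assoc(trait_id))
  }
  ord <- order(positions)
  ord <- ord[inside[ord]]
  skipped <- character()
  rows <- list()
  for (j in ord) {
    res <- try(marginal_regression(genotypes[, j], phenotype,
                                   variant_id = vars[j],
                                   trait_id = trait_id), silent = TRUE)
    if (inherits(res, "try-error")) {
      skipped <- c(skipped, vars[j])
    } else {
      res$pos <- positions[j]
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_assoc(trait_id)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

empty_assoc <- function(trait_id) {
  data.frame(variant = character(), trait = character(), beta = numeric(),
             se = numeric(), z = numeric(), p = numeric(), n = integer(),
             maf = numeric(), degenerate = logical(), pos = integer(),
             stringsAsFactors = FALSE)
}
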