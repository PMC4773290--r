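#' Call heterozygotes from control-arm B-allele frequencies
#'
#' Genotype classes are read off the non-enriched (control) BAF: samples with
#' control BAF in `[0.5 - delta, 0.5 + delta]` (inclusive) are heterozygous;
#' below the band, homozygous for the A allele; above it, homozygous B.
#'
#' @param control data.frame with `sample` and `baf` columns (control
#'   treatment, one variant).
#' @param delta half-width of the heterozygote BAF band (default 0.15).
#' @return list with character vectors `het`, `hom_a`, `hom_b`.
#' @export
call_heterozygotes <- function(control, delta = 0.15) {
  if (nrow(control) < 1L) stop2("need >= 1 control record")
  b <- control$baf
  list(het = control$sample[b >= 0.5 - delta & b <= 0.5 + delta],
       hom_a = control$sample[b < 0.5 - delta],
       hom_b = control$sample[b > 0.5 + delta])
}

#' Allele-specific chromatin-accessibility imbalance at one variant
#'
#' Pairs the control and FAIRE-enriched BAF of every heterozygote and tests
#' the paired differences `d_i = baf_faire_i - baf_control_i` with a paired
#' two-sided t-test on `n_het - 1` degrees of freedom. The enriched allele is
#' B when mean(d) > 0, else A; the enrichment percentage is the relative
#' change of the enriched allele's mean fraction between arms (an absolute
#' percentage-point mode is available).
#'
#' @param records data.frame with `sample`, `treatment`
#'   (`control`/`faire`), `baf` for one variant (a `variant` column, if
#'   present, must be constant).
#' @param het heterozygous sample ids; defaults to
#'   [call_heterozygotes()] on the control arm with `delta`.
#' @param delta heterozygote band half-width used when `het` is `NULL`.
#' @param mode `"relative"` (default; 0.500 -> 0.602 reads as 20.4%) or
#'   `"absolute"` (percentage points, x100).
#' @return object of class `faire_imbalance`: `variant_id`, `n_het`,
#'   `mean_baf_control`, `mean_baf_faire`, `enriched_allele`,
#'   `enrichment_pct`, `t_stat`, `p`, `df`, `degenerate`.
#' @export
allelic_imbalance <- function(records, het = NULL, delta = 0.15,
                              mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  variant_id <- if ("variant" %in% names(records)) {
    v <- unique(records$variant)
    if (length(v) != 1L) stop2("records span %d variants; supply one", length(v))
    v
  } else "variant"
  ctrl <- records[records$treatment == "control", , drop = FALSE]
  faire <- records[records$treatment == "faire", , drop = FALSE]
  if (is.null(het)) het <- call_heterozygotes(ctrl, delta)$het
  if (length(het) < 2L)
    stop2("need >= 2 heterozygotes for a paired test, got %d", length(het))
  ic <- match(het, ctrl$sample); im <- match(het, faire$sample)
  unpaired <- het[is.na(ic) | is.na(im)]
  if (length(unpaired))
    stop2("heterozygote(s) without a control/FAIRE pair: %s",
          paste(unpaired, collapse = ", "))
  bc <- ctrl$baf[ic]; bf <- faire$baf[im]
  d <- bf - bc
  n <- length(d)
  degenerate <- FALSE
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) { t_stat <- 0; p <- 1 }
    else { t_stat <- sign(mean(d)) * Inf; p <- 0; degenerate <- TRUE }
  } else {
    tt <- stats::t.test(bf, bc, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  enriched <- if (mean(d) > 0) "B" else "A"
  frac <- function(b) if (enriched == "B") b else 1 - b
  mc <- mean(frac(bc)); mf <- mean(frac(bf))
  enrichment_pct <- if (mode == "relative") 100 * abs(mf - mc) / mc
                    else 100 * abs(mf - mc)
  structure(list(variant_id = variant_id, n_het = n,
                 mean_baf_control = mean(bc), mean_baf_faire = mean(bf),
                 enriched_allele = enriched, enrichment_pct = enrichment_pct,
                 t_stat = t_stat, p = p, df = n - 1L,
                 degenerate = degenerate, mode = mode),
            class = "faire_imbalance")
}

#' @export
print.faire_imbalance <- function(x, ...) {
  cat(sprintf("Allele-specific FAIRE imbalance at %s\n", x$variant_id))
  cat(sprintf("  %d heterozygotes; mean BAF %.3f (control) -> %.3f (FAIRE)\n",
              x$n_het, x$mean_baf_control, x$mean_baf_faire))
  cat(sprintf("  %.1f%% %s enrichment of the %s allele; paired t = %.3f, df = %d, p = %.3g\n",
              x$enrichment_pct, x$mode, x$enriched_allele, x$t_stat, x$df, x$p))
  invisible(x)
}

#' Imbalance scan over every variant in a BAF table
#'
#' @param baf data.frame with `sample`, `variant`, `treatment`, `baf`.
#' @param delta heterozygote band half-width.
#' @param mode enrichment mode, see [allelic_imbalance()].
#' @return data.frame with one row per testable variant (variants with < 2
#'   heterozygotes are skipped and listed in attribute `"skipped"`).
#' @export
allelic_imbalance_scan <- function(baf, delta = 0.15, mode = "relative") {
  skipped <- character()
  rows <- list()
  for (v in unique(baf$variant)) {
    res <- try(allelic_imbalance(baf[baf$variant == v, , drop = FALSE],
                                 delta = delta, mode = mode), silent = TRUE)
    if (inherits(res, "try-error")) { skipped <- c(skipped, v); next }
    rows[[length(rows) + 1L]] <- data.frame(
      variant = res$variant_id, n_het = res$n_het,
      mean_baf_control = res$mean_baf_control,
      mean_baf_faire = res$mean_baf_faire,
      enriched_allele = res$enriched_allele,
      enrichment_pct = res$enrichment_pct,
      t_stat = res$t_stat, p = res$p, df = res$df,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(), n_het = integer(),
               mean_baf_control = numeric(), mean_baf_faire = numeric(),
               enriched_allele = character(), enrichment_pct = numeric(),
               t_stat = numeric(), p = numeric(), df = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Reporter-assay ratio test between allele groups
#'
#' Normalises each well's reporter reading to its co-transfected control
#' reading and compares the per-well ratios between the two allele groups
#' with a two-sided two-sample (Welch) t-test.
#'
#' @param wells data.frame with `group`, `reporter`, `control` columns (one
#'   row per well).
#' @return object of class `reporter_assay`: group labels and means, the
#'   per-well ratios, `t_stat`, `df`, `p`.
#' @export
reporter_ratio_test <- function(wells) {
  stopifnot(all(c("group", "reporter", "control") %in% names(wells)))
  if (any(wells$control <= 0))
    stop2("invalid well: control reading <= 0")
  groups <- unique(wells$group)
  if (length(groups) != 2L) stop2("expected exactly 2 groups, got %d",
                                  length(groups))
  ratio <- wells$reporter / wells$control
  g1 <- ratio[wells$group == groups[1L]]
  g2 <- ratio[wells$group == groups[2L]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop2("need >= 2 wells per group for a t-test")
  tt <- stats::t.test(g1, g2)
  structure(list(groups = as.character(groups),
                 group_means = stats::setNames(c(mean(g1), mean(g2)),
                                               as.character(groups)),
                 ratios = split(ratio, wells$group),
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "reporter_assay")
}

#' @export
print.reporter_assay <- function(x, ...) {
  cat(sprintf("Reporter ratio test: %s (mean %.3f) vs %s (mean %.3f)\n",
              x$groups[1L], x$group_means[1L], x$groups[2L],
              x$group_means[2L]))
  cat(sprintf("  Welch t = %.3f, df = %.1f, p = %.3g\n", x$t_stat, x$df, x$p))
  invisible(x)
}
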