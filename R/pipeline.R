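#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML file path or a list, fills in the documented defaults,
#' and rejects unknown keys and out-of-range thresholds. Exactly one of
#' `simulation` (a simulated locus) or `inputs` (paths to VCF/TSV/BED files)
#' drives the run; an empty configuration defaults to a simulated locus.
#'
#' @param config path to a YAML file, or a list of settings.
#' @return normalised list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop2("config file not found: %s", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  stopifnot(is.list(config))
  defaults <- list(
    lead = NULL, anchor_pos = NULL,
    r2_min = 0.8, p_gwas = 5e-8, p_eqtl = NULL,
    window_kb = 500, cis_kb = 200, near_bp = 500,
    coloc_threshold = 0.75, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, w = 0.0225,
    het_delta = 0.15, seed = 1L, out_dir = NULL,
    simulation = NULL, inputs = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop2("unknown config key(s): %s (known: %s)",
          paste(unknown, collapse = ", "),
          paste(names(defaults), collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$p_eqtl)) cfg$p_eqtl <- cfg$p_gwas
  if (!is.null(cfg$simulation) && !is.null(cfg$inputs))
    stop2("config: provide either 'simulation' or 'inputs', not both")
  if (is.null(cfg$simulation) && is.null(cfg$inputs))
    cfg$simulation <- list()
  check_range <- function(field, lo, hi) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || v < lo || v > hi)
      stop2("config field '%s' must lie in [%g, %g]", field, lo, hi)
  }
  check_range("r2_min", 0, 1)
  check_range("p_gwas", 0, 1)
  check_range("p_eqtl", 0, 1)
  check_range("near_bp", 0, Inf)
  check_range("coloc_threshold", 0, 1)
  check_range("het_delta", 0, 0.5)
  for (f in c("p1", "p2", "p12", "w")) check_range(f, 1e-300, 1)
  if (!is.null(cfg$inputs)) {
    need <- c("vcf", "gwas", "eqtl")
    miss <- setdiff(need, names(cfg$inputs))
    if (length(miss))
      stop2("config inputs missing required path(s): %s",
            paste(miss, collapse = ", "))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full localisation pipeline
#'
#' Executes the staged workflow on a simulated or file-based locus:
#' data acquisition, LD with the lead SNP, candidate selection by the union
#' rule, trait-expression colocalisation, regulatory-annotation overlap, and
#' allele-specific FAIRE imbalance; then consolidates everything into a
#' per-variant prioritisation report with a tier per variant
#' (`candidate` < `regulatory` < `functional-evidence`). Stage artifacts are
#' written to `out_dir` when given. Deterministic given the config seed.
#'
#' @param config a [validate_config()] result, list, or YAML path.
#' @param out_dir output directory for stage artifacts; `NULL` writes none.
#' @return object of class `prioritisation_report`: a per-candidate
#'   data.frame plus the locus-level colocalisation result, counts and
#'   configuration as attributes.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  dat <- stage("acquire", acquire_locus_data(cfg))
  lead <- cfg$lead %||% dat$gwas$variant[which.min(dat$gwas$p)]

  ld <- stage("ld", ld_with_lead(dat$genotypes, lead))
  candidates <- stage("candidates", select_candidates(
    ld, dat$gwas, dat$eqtl, r2_min = cfg$r2_min, p_gwas = cfg$p_gwas,
    p_eqtl = cfg$p_eqtl, locus_window_bp = cfg$window_kb * 1000,
    gene_anchor_pos = cfg$anchor_pos))

  coloc <- stage("coloc", coloc_posteriors(
    dat$gwas, dat$eqtl,
    coloc_priors(p1 = cfg$p1, p2 = cfg$p2, p12 = cfg$p12,
                 w1 = cfg$w, w2 = cfg$w)))
  coloc_label <- coloc_classify(coloc, cfg$coloc_threshold)

  ann <- NULL
  if (!is.null(dat$annotations) && nrow(dat$annotations) > 0) {
    ann <- stage("annotate", build_annotation_matrix(
      dat$variants, dat$annotations, near_bp = cfg$near_bp))
  }
  imb <- NULL
  if (!is.null(dat$baf) && nrow(dat$baf) > 0) {
    imb <- stage("faire", allelic_imbalance_scan(dat$baf,
                                                 delta = cfg$het_delta))
  }

  report <- stage("report", build_report(candidates, ann, imb))
  attr(report, "coloc") <- coloc
  attr(report, "coloc_label") <- coloc_label
  attr(report, "lead") <- lead
  attr(report, "config") <- cfg

  if (!is.null(out_dir)) {
    utils::write.table(as.data.frame(candidates),
                       file.path(out_dir, "candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(pp = as.list(coloc$pp), n_variants = coloc$n_variants,
           priors = unclass(coloc$priors), label = as.list(coloc_label)),
      file.path(out_dir, "coloc.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(ann))
      write_annotation_matrix(ann, file.path(out_dir, "annotation_matrix.tsv"))
    if (!is.null(imb))
      utils::write.table(imb, file.path(out_dir, "imbalance.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(report),
                       file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  report
}

# turn config into a uniform locus dataset: variants, genotypes, gwas/eqtl
# summary stats, annotation intervals, BAF records
acquire_locus_data <- function(cfg) {
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    spec <- locus_spec(n_variants = sim$n_variants %||% 60L,
                       n_founders = sim$n_founders %||% 4L,
                       recomb_prob = sim$recomb_prob %||% 0.1,
                       mutation_prob = sim$mutation_prob %||% 0.01,
                       seed = cfg$seed)
    scen <- sim$scenario %||% "H4"
    nv <- spec$n_variants
    cc <- causal_config(
      scenario = scen,
      trait_causal = sim$trait_causal %||%
        (if (scen %in% c("H1", "H3", "H4")) nv %/% 2L else NA_integer_),
      expr_causal = sim$expr_causal %||%
        (if (scen == "H4") nv %/% 2L
         else if (scen == "H2") nv %/% 2L
         else if (scen == "H3") max(1L, nv %/% 6L) else NA_integer_),
      beta_trait = sim$beta_trait %||% 0.4,
      beta_expr = sim$beta_expr %||% 0.4,
      noise_sd = sim$noise_sd %||% 1,
      n_samples = sim$n_samples %||% 2000L,
      seed = cfg$seed)
    bundle <- simulate_locus(spec, cc,
                             fraction_within = sim$fraction_within %||% 0.2,
                             fraction_near = sim$fraction_near %||% 0.1,
                             faire_shift = sim$faire_shift %||% 0.1,
                             baf_noise_sd = sim$baf_noise_sd %||% 0.02,
                             seed = cfg$seed)
    pos <- bundle$variants$pos
    list(variants = bundle$variants, genotypes = bundle$genotypes,
         gwas = eqtl_scan(bundle$genotypes, bundle$trait, pos,
                          trait_id = "trait"),
         eqtl = eqtl_scan(bundle$genotypes, bundle$expression, pos,
                          trait_id = "expression"),
         annotations = bundle$annotations, baf = bundle$baf,
         bundle = bundle)
  } else {
    geno <- read_genotypes_vcf(cfg$inputs$vcf)
    list(variants = geno$variants, genotypes = geno$genotypes,
         gwas = read_assoc_tsv(cfg$inputs$gwas),
         eqtl = read_assoc_tsv(cfg$inputs$eqtl),
         annotations = if (!is.null(cfg$inputs$bed))
           read_bed(cfg$inputs$bed) else NULL,
         baf = if (!is.null(cfg$inputs$baf))
           read_baf_tsv(cfg$inputs$baf) else NULL,
         bundle = NULL)
  }
}

build_report <- function(candidates, ann, imb) {
  rep <- as.data.frame(candidates)
  rep$annotation <- if (is.null(ann)) NA_character_ else
    unname(attr(ann, "summary")[rep$variant])
  if (is.null(imb) || nrow(imb) == 0) {
    rep$imbalance_p <- NA_real_
    rep$enrichment_pct <- NA_real_
  } else {
    i <- match(rep$variant, imb$variant)
    rep$imbalance_p <- imb$p[i]
    rep$enrichment_pct <- imb$enrichment_pct[i]
  }
  regulatory <- !is.na(rep$annotation) & rep$annotation %in% c("within", "near")
  functional <- regulatory & !is.na(rep$imbalance_p) & rep$imbalance_p < 0.05
  rep$tier <- ifelse(functional, "functional-evidence",
                     ifelse(regulatory, "regulatory", "candidate"))
  class(rep) <- c("prioritisation_report", "data.frame")
  rep
}

#' @export
print.prioritisation_report <- function(x, ...) {
  n <- nrow(x)
  n_reg <- sum(x$tier %in% c("regulatory", "functional-evidence"))
  n_fun <- sum(x$tier == "functional-evidence")
  cat("Variant prioritisation funnel\n")
  cat(sprintf("  lead SNP: %s\n", attr(x, "lead")))
  cat(sprintf("  candidates: %d -> regulatory: %d -> functional evidence: %d\n",
              n, n_reg, n_fun))
  lab <- attr(x, "coloc_label")
  if (!is.null(lab)) {
    strong <- names(lab)[lab == "strong"]
    cat(sprintf("  colocalisation: %s\n",
                if (length(strong)) paste("strong evidence for", strong)
                else "inconclusive"))
  }
  if (n_fun > 0)
    cat(sprintf("  top-tier variant(s): %s\n",
                paste(x$variant[x$tier == "functional-evidence"],
                      collapse = ", ")))
  invisible(x)
}
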