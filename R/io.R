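# Readers and writers for the pipeline's plain-text interchange formats:
# GT-only VCFv4.2, 4-column BED, summary-statistic TSV, BAF TSV, FASTA.

#' Write genotypes as a minimal GT-only VCFv4.2 file
#'
#' @param variants data.frame with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes sample x variant dosage matrix (columns match
#'   `variants$id`); dosage d is emitted as 0/0, 0/1 or 1/1.
#' @param path output path. Sites are written sorted by position.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  stopifnot(identical(colnames(genotypes), variants$id))
  ord <- order(variants$chrom, variants$pos)
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  # fixed columns + one genotype string per sample
  body <- vapply(ord, function(j) {
    gts <- ifelse(is.na(genotypes[, j]), "./.", gt_code[genotypes[, j] + 1L])
    paste(c(variants$chrom[j], variants$pos[j], variants$id[j],
            variants$ref[j], variants$alt[j], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' @param path VCF path (plain text or bgzipped).
#' @return list with `variants` (data.frame `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`) and `genotypes` (sample x variant dosage matrix, `NA` for
#'   missing calls).
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop2("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  # count alt alleles per call; "." -> NA
  dosage <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0L)
  })
  dosage <- t(dosage)   # samples x variants
  colnames(dosage) <- fix[, "ID"]
  af <- colMeans(dosage, na.rm = TRUE) / 2
  variants <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         maf = pmin(af, 1 - af),
                         stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  list(variants = variants, genotypes = dosage)
}

#' Write association summary statistics in the pipeline TSV schema
#'
#' Columns: `variant chrom pos ref alt beta se p n maf trait`.
#'
#' @param stats association table (from [eqtl_scan()] or compatible).
#' @param variants variant table supplying chrom/ref/alt for each id.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(stats, variants, path) {
  i <- match(stats$variant, variants$id)
  out <- data.frame(variant = stats$variant, chrom = variants$chrom[i],
                    pos = variants$pos[i], ref = variants$ref[i],
                    alt = variants$alt[i], beta = stats$beta, se = stats$se,
                    p = stats$p, n = stats$n, maf = stats$maf,
                    trait = stats$trait, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association summary statistics TSV
#'
#' @param path TSV with at least `variant` and `p`, ideally the full schema
#'   written by [write_assoc_tsv()].
#' @return data.frame.
#' @export
read_assoc_tsv <- function(path) {
  if (!file.exists(path)) stop2("summary-stat TSV not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(variant = "character", chrom = "character"))
}

#' Write annotation intervals as 4-column BED
#'
#' @param intervals data.frame with `chrom`, `start` (0-based), `end`
#'   (exclusive), `track`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("chrom", "start", "end", "track")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a 4-column BED of annotation intervals
#'
#' @param path BED path (0-based half-open; 4th column = track label).
#' @return data.frame with `chrom`, `start`, `end`, `track`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop2("BED not found: %s", path)
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,   # back to BED 0-based
             end = GenomicRanges::end(gr),
             track = if (!is.null(gr$name)) gr$name else "track",
             stringsAsFactors = FALSE)
}

#' Read a B-allele-frequency TSV
#'
#' @param path TSV with header `sample variant treatment baf`.
#' @return data.frame.
#' @export
read_baf_tsv <- function(path) {
  if (!file.exists(path)) stop2("BAF TSV not found: %s", path)
  baf <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "variant", "treatment", "baf")
  if (!all(need %in% names(baf)))
    stop2("BAF TSV must have columns: %s", paste(need, collapse = " "))
  baf
}

#' Write a complete simulated bundle to disk as pipeline input files
#'
#' Emits `locus.vcf`, `annotations.bed`, `gwas.tsv` and `eqtl.tsv` (marginal
#' summary statistics recomputed from the simulated genotypes and
#' phenotypes), `baf.tsv` (if BAF data present), `reference.fa` (random
#' genomic background carrying each variant's reference allele at its
#' position) and `truth.json`, a ground-truth sidecar for tests that is
#' never read by the pipeline itself.
#'
#' @param bundle a `truth_bundle` from [simulate_locus()] or
#'   [simulate_traits()].
#' @param out_dir output directory (created if missing).
#' @return named character vector of the files written.
#' @export
write_fixture_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "truth_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  files <- c(vcf = p("locus.vcf"), gwas = p("gwas.tsv"), eqtl = p("eqtl.tsv"),
             fasta = p("reference.fa"), truth = p("truth.json"))
  write_vcf(bundle$variants, bundle$genotypes, files[["vcf"]])
  pos <- bundle$variants$pos
  gwas <- eqtl_scan(bundle$genotypes, bundle$trait, pos, trait_id = "trait")
  eqtl <- eqtl_scan(bundle$genotypes, bundle$expression, pos,
                    trait_id = "expression")
  write_assoc_tsv(gwas, bundle$variants, files[["gwas"]])
  write_assoc_tsv(eqtl, bundle$variants, files[["eqtl"]])
  if (!is.null(bundle$annotations)) {
    files[["bed"]] <- p("annotations.bed")
    write_bed(bundle$annotations, files[["bed"]])
  }
  if (!is.null(bundle$baf)) {
    files[["baf"]] <- p("baf.tsv")
    utils::write.table(bundle$baf, files[["baf"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  seed <- if (!is.null(bundle$spec)) bundle$spec$seed else 1L
  ref <- with_seed(seed + 17L, {
    len <- max(pos) + 200L
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    s[pos] <- bundle$variants$ref
    paste(s, collapse = "")
  })
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(ref, bundle$variants$chrom[1L])),
    files[["fasta"]])
  truth <- list(causal = unclass(bundle$causal_truth),
                annotation_truth = as.list(bundle$annotation_truth),
                imbalance_truth = as.list(bundle$imbalance_truth))
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  files
}
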