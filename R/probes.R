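#' Design allele-specific double-stranded EMSA probes
#'
#' Builds the forward probe for each allele as `flank_bp` bases of genomic
#' context on each side of the variant with the allele substituted at the
#' centre (probe length `2 * flank_bp + 1`), plus the reverse complement of
#' each forward strand for annealing.
#'
#' @param reference genomic context: a character string, `Biostrings::DNAString`
#'   or single-sequence `DNAStringSet`.
#' @param variant list or one-row data.frame with `id`, `pos` (1-based within
#'   the reference, offset by `ref_start`), `ref`, `alt` (single-base
#'   alleles).
#' @param flank_bp context on each side of the variant (default 15).
#' @param ref_start 1-based genomic coordinate of the first reference base
#'   (default 1), so `variant$pos` may be genomic.
#' @return object of class `probe_design` with `variant_id`, `flank_bp`,
#'   `forward_ref`, `forward_alt`, `reverse_ref`, `reverse_alt`.
#' @export
design_emsa_probes <- function(reference, variant, flank_bp = 15L,
                               ref_start = 1L) {
  seq <- toupper(as.character(reference))
  if (length(seq) != 1L) stop2("reference must be a single sequence")
  ref <- toupper(variant$ref); alt <- toupper(variant$alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop2("unsupported variant: only single-base SNVs can be assayed")
  idx <- variant$pos - ref_start + 1L
  if (idx - flank_bp < 1L || idx + flank_bp > nchar(seq))
    stop2("insufficient flank: need %d bp each side of position %d",
          flank_bp, variant$pos)
  context <- substr(seq, idx - flank_bp, idx + flank_bp)
  centre <- substr(context, flank_bp + 1L, flank_bp + 1L)
  if (!centre %in% c(ref, alt))
    warn2("reference base '%s' at %s matches neither allele (%s/%s); using declared alleles",
          centre, variant$id, ref, alt)
  with_allele <- function(a) {
    p <- context
    substr(p, flank_bp + 1L, flank_bp + 1L) <- a
    p
  }
  fwd_ref <- with_allele(ref); fwd_alt <- with_allele(alt)
  for (p in c(fwd_ref, fwd_alt))
    if (grepl("[^ACGT]", p))
      stop2("probe contains non-ACGT bases: %s", p)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  structure(list(variant_id = variant$id, flank_bp = as.integer(flank_bp),
                 forward_ref = fwd_ref, forward_alt = fwd_alt,
                 reverse_ref = rc(fwd_ref), reverse_alt = rc(fwd_alt)),
            class = "probe_design")
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("EMSA probes for %s (%d bp flanks, %d-mer):\n",
              x$variant_id, x$flank_bp, 2L * x$flank_bp + 1L))
  cat(sprintf("  forward ref: 5'-%s-3'\n", x$forward_ref))
  cat(sprintf("  forward alt: 5'-%s-3'\n", x$forward_alt))
  cat(sprintf("  reverse ref: 5'-%s-3'\n", x$reverse_ref))
  cat(sprintf("  reverse alt: 5'-%s-3'\n", x$reverse_alt))
  invisible(x)
}

#' Write a set of probe designs as TSV and FASTA
#'
#' @param designs a `probe_design` or list of them.
#' @param tsv,fasta output paths (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
write_probes <- function(designs, tsv = NULL, fasta = NULL) {
  if (inherits(designs, "probe_design")) designs <- list(designs)
  tab <- do.call(rbind, lapply(designs, function(d)
    data.frame(variant = d$variant_id, flank_bp = d$flank_bp,
               forward_ref = d$forward_ref, forward_alt = d$forward_alt,
               reverse_ref = d$reverse_ref, reverse_alt = d$reverse_alt,
               stringsAsFactors = FALSE)))
  if (!is.null(tsv))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    seqs <- unlist(lapply(designs, function(d) stats::setNames(
      c(d$forward_ref, d$forward_alt, d$reverse_ref, d$reverse_alt),
      paste(d$variant_id, c("forward_ref", "forward_alt",
                            "reverse_ref", "reverse_alt"), sep = "_"))))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta)
  }
  invisible(list(tsv = tsv, fasta = fasta))
}
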