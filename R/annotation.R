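#' Classify one variant position against a track's intervals
#'
#' Coordinates follow the field conventions: the variant position is 1-based
#' (VCF), intervals are 0-based half-open (BED). The 1-based position is
#' converted once (`p0 = pos - 1`); a variant is "within" when any interval
#' satisfies `start <= p0 < end`, "near" when the bp gap to the nearest
#' interval edge is <= `near_bp` (inclusive), otherwise "none".
#'
#' @param pos 1-based variant position.
#' @param intervals data.frame with 0-based `start`, exclusive `end` (one
#'   track, the variant's chromosome).
#' @param near_bp inclusive proximity threshold in bp (default 500).
#' @return list with `status` (`within`/`near`/`none`) and `distance` (0 when
#'   within, bp to nearest edge otherwise, `Inf` with no intervals).
#' @export
annotate_variant <- function(pos, intervals, near_bp = 500L) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(list(status = "none", distance = Inf))
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  q <- IRanges::IRanges(start = pos, end = pos)
  if (length(IRanges::findOverlaps(q, ir)) > 0L)
    return(list(status = "within", distance = 0))
  hit <- IRanges::distanceToNearest(q, ir)
  gap <- S4Vectors::mcols(hit)$distance + 1L   # IRanges gap -> edge distance
  list(status = if (gap <= near_bp) "near" else "none",
       distance = as.numeric(gap))
}

#' Build a variant x track annotation status matrix
#'
#' @param variants data.frame with `id`, `pos` (1-based) and optionally
#'   `chrom`.
#' @param tracks named list of interval data.frames (`chrom`, `start`, `end`
#'   in BED convention), one entry per track label; or a single data.frame
#'   with a `track` column, which is split by label.
#' @param near_bp inclusive proximity threshold in bp.
#' @return object of class `annotation_matrix`: a character matrix of
#'   `within`/`near`/`none` with variant ids as rows and track labels as
#'   columns; `near_bp` and the per-variant summary status (within beats
#'   near beats none across tracks) attached as attributes.
#' @export
build_annotation_matrix <- function(variants, tracks, near_bp = 500L) {
  if (is.data.frame(tracks)) {
    if (!"track" %in% names(tracks))
      stop2("a single interval table must carry a 'track' column")
    tracks <- split(tracks, tracks$track)
  }
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop2("tracks must be a named list; known labels look like %s",
          "promoter_histone/enhancer_histone/dnase/faire/protein_bound")
  m <- matrix("none", nrow = nrow(variants), ncol = length(tracks),
              dimnames = list(variants$id, names(tracks)))
  for (tr in names(tracks)) {
    iv <- tracks[[tr]]
    for (i in seq_len(nrow(variants))) {
      sub <- if ("chrom" %in% names(iv) && "chrom" %in% names(variants))
        iv[iv$chrom == variants$chrom[i], , drop = FALSE] else iv
      m[i, tr] <- annotate_variant(variants$pos[i], sub, near_bp)$status
    }
  }
  as_annotation_matrix(m, near_bp)
}

as_annotation_matrix <- function(m, near_bp) {
  summary_status <- apply(m, 1L, function(row) {
    if (any(row == "within")) "within"
    else if (any(row == "near")) "near"
    else "none"
  })
  structure(m, near_bp = as.integer(near_bp), summary = summary_status,
            class = c("annotation_matrix", class(m)))
}

#' @export
print.annotation_matrix <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Annotation matrix: %d variants x %d tracks (near_bp=%d)\n",
              nrow(x), ncol(x), attr(x, "near_bp")))
  cat(sprintf("  summary: %d within / %d near / %d none\n",
              sum(s == "within"), sum(s == "near"), sum(s == "none")))
  invisible(x)
}

#' Read an annotation matrix from the X / (X) table notation
#'
#' Parses a TSV whose first column is the variant id and whose remaining
#' cells use the printed-table notation: `X` = variant within the regulatory
#' site, `(X)` = close to it, empty/`.` = neither.
#'
#' @param path TSV file path.
#' @param near_bp proximity threshold recorded on the result.
#' @return an `annotation_matrix`.
#' @export
read_annotation_matrix <- function(path, near_bp = 500L) {
  tab <- utils::read.delim(path, check.names = FALSE, na.strings = NULL,
                           colClasses = "character")
  ids <- tab[[1L]]
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  m <- matrix("none", nrow = nrow(cells), ncol = ncol(cells),
              dimnames = list(ids, colnames(cells)))
  m[trimws(cells) == "X"] <- "within"
  m[trimws(cells) == "(X)"] <- "near"
  as_annotation_matrix(m, near_bp)
}

#' Write an annotation matrix as TSV in both human and machine notation
#'
#' @param x an `annotation_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_matrix <- function(x, path) {
  human <- ifelse(x == "within", "X", ifelse(x == "near", "(X)", "."))
  out <- data.frame(variant = rownames(x), human,
                    stats::setNames(as.data.frame(unclass(x)[, , drop = FALSE]),
                                    paste0(colnames(x), "_status")),
                    summary = attr(x, "summary"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain candidates located within or near a regulatory annotation
#'
#' @param matrix an `annotation_matrix` covering the candidates.
#' @param candidates a `candidate_set` or character vector of variant ids.
#' @return data.frame with `variant`, `status` (`within`/`near`) for the
#'   retained candidates, in candidate order.
#' @export
filter_regulatory <- function(matrix, candidates) {
  ids <- if (is.data.frame(candidates)) candidates$variant else candidates
  missing <- setdiff(ids, rownames(matrix))
  if (length(missing))
    stop2("annotation matrix does not cover candidate(s): %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  s <- attr(matrix, "summary")[ids]
  keep <- s %in% c("within", "near")
  data.frame(variant = ids[keep], status = unname(s[keep]),
             stringsAsFactors = FALSE)
}

#' Count annotation statuses overall and per track
#'
#' @param matrix an `annotation_matrix`.
#' @return list with `n_within`, `n_near`, `n_none` (per-variant summary
#'   status counts), `n_annotated` (within + near) and `per_track`, a
#'   track x status count table.
#' @export
summarize_counts <- function(matrix) {
  s <- attr(matrix, "summary")
  per_track <- t(apply(matrix, 2L, function(col)
    c(within = sum(col == "within"), near = sum(col == "near"),
      none = sum(col == "none"))))
  list(n_within = sum(s == "within"), n_near = sum(s == "near"),
       n_none = sum(s == "none"),
       n_annotated = sum(s %in% c("within", "near")),
       per_track = per_track)
}
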