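#' Alignment scoring parameters
#'
#' Defaults: match +2, mismatch -3, gap open -5, gap extend -2 (a gap of
#' length L costs `open + extend * L`).
#'
#' @param match,mismatch,gap_open,gap_extend Scoring values; penalties are
#'   given as positive magnitudes.
#' @return Named list of scoring parameters.
#' @export
align_scoring <- function(match = 2, mismatch = 3, gap_open = 5, gap_extend = 2) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

new_alignment_result <- function(aligned_ref, aligned_qry, score,
                                 ref_start_rotation = 0L, strand = "+") {
  stopifnot(nchar(aligned_ref) == nchar(aligned_qry))
  structure(list(aligned_ref = aligned_ref, aligned_qry = aligned_qry,
                 score = score, ref_start_rotation = as.integer(ref_start_rotation),
                 strand = strand),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d columns, score %d, strand %s\n",
              nchar(x$aligned_ref), x$score, x$strand))
  invisible(x)
}

#' Normalize the orientation of a circular query
#'
#' Circular assemblies have an arbitrary start and strand. This rotates
#' (and if needed reverse-complements) the query so that it begins at the
#' position matching the reference start, by locating the reference's
#' first k-mer exactly in the query or its reverse complement; on failure
#' k shrinks by 2 down to 11.
#'
#' @param ref,qry [circular_genome] objects (query must be circular).
#' @param k Anchor k-mer length (default 21).
#' @return The normalized query [circular_genome], with attributes
#'   `"rotation"` (offset applied) and `"strand"` (`"+"` or `"-"`).
#' @export
normalize_orientation <- function(ref, qry, k = 21L) {
  ref <- if (inherits(ref, "circular_genome")) ref else circular_genome(ref)
  qry <- if (inherits(qry, "circular_genome")) qry else circular_genome(qry)
  if (!qry$circular) stop("query is not circular; align it directly instead")
  rlen <- nchar(ref$seq$bases); qlen <- nchar(qry$seq$bases)
  if (k >= min(rlen, qlen)) stop("anchor k must be shorter than both sequences")
  fwd <- qry$seq$bases
  rev <- revcomp(fwd)
  # doubled strings so the anchor can straddle the origin
  dbl_f <- paste0(fwd, substr(fwd, 1L, min(k, qlen) - 1L))
  dbl_r <- paste0(rev, substr(rev, 1L, min(k, qlen) - 1L))
  for (kk in seq(from = as.integer(k), to = 11L, by = -2L)) {
    anchor <- substr(ref$seq$bases, 1L, kk)
    hit <- regexpr(anchor, dbl_f, fixed = TRUE)
    if (hit > 0L) {
      out <- rotate(qry, as.integer(hit) - 1L)
      attr(out, "rotation") <- as.integer(hit) - 1L
      attr(out, "strand") <- "+"
      return(out)
    }
    hit <- regexpr(anchor, dbl_r, fixed = TRUE)
    if (hit > 0L) {
      out <- rotate(revcomp(qry), as.integer(hit) - 1L)
      attr(out, "rotation") <- as.integer(hit) - 1L
      attr(out, "strand") <- "-"
      return(out)
    }
  }
  stop("no exact anchor match at k >= 11; fall back to aligning both strands ",
       "of the unrotated query")
}

#' Global pairwise alignment
#'
#' End-to-end (Needleman-Wunsch) alignment under affine gap penalties, with
#' deterministic tie-breaking: a mismatch is preferred over a gap, a gap in
#' the query over a gap in the reference, and gap runs are kept maximal.
#' Indel events are additionally left-normalized downstream, so event
#' coordinates are deterministic.
#'
#' @param ref,qry [nuc_seq] objects (or coercibles); orientation-normalized
#'   beforehand for circular comparisons.
#' @param scoring An [align_scoring] list.
#' @return An `alignment_result`: gapped `aligned_ref` / `aligned_qry`
#'   strings of equal length (no column is gap-in-both), and `score`.
#' @export
global_align <- function(ref, qry, scoring = align_scoring()) {
  ref <- as_nuc_seq(ref, id = "ref"); qry <- as_nuc_seq(qry, id = "qry")
  res <- .nw_affine(ref$bases, qry$bases, scoring$match, -scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend)
  new_alignment_result(res$aligned_ref, res$aligned_qry, res$score)
}

aln_cols <- function(aln) {
  list(ref = chars(aln$aligned_ref), qry = chars(aln$aligned_qry))
}

#' p-distance of an alignment
#'
#' Proportion of differing sites among comparable columns (both bases
#' present). Gap columns are excluded (pairwise-deletion convention), so
#' indel-only discrepancies contribute zero distance.
#'
#' @param aln An `alignment_result`.
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(aln) {
  cc <- aln_cols(aln)
  both <- cc$ref != "-" & cc$qry != "-"
  if (!any(both)) stop("no comparable (gap-free) columns")
  sum(cc$ref[both] != cc$qry[both]) / sum(both)
}

#' Completeness of the query relative to the reference
#'
#' Fraction of reference positions aligned to a query base (not a gap);
#' 1.0 for a full-length query, below 1 for partial assemblies.
#'
#' @param aln An `alignment_result`.
#' @return Fraction in `(0, 1]` for a non-empty query.
#' @export
completeness <- function(aln) {
  cc <- aln_cols(aln)
  refpos <- cc$ref != "-"
  sum(refpos & cc$qry != "-") / sum(refpos)
}
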