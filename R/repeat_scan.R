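divisors_below <- function(k) Filter(function(d) k %% d == 0L, seq_len(k - 1L))

is_primitive <- function(motif) {
  k <- nchar(motif)
  for (d in divisors_below(k)) {
    if (motif == strrep(substr(motif, 1L, d), k %/% d)) return(FALSE)
  }
  TRUE
}

smallest_period <- function(motif) {
  k <- nchar(motif)
  for (d in divisors_below(k)) {
    if (motif == strrep(substr(motif, 1L, d), k %/% d)) return(d)
  }
  k
}

empty_hits <- function() {
  data.frame(start = integer(), motif = character(), motif_len = integer(),
             copies = numeric(), span = integer(), consensus = character(),
             stringsAsFactors = FALSE)
}

#' Find perfect microsatellites
#'
#' Maximal perfect tandem arrays with motif length in
#' `[min_motif, max_motif]` and at least `min_copies` copies (possibly
#' fractional, from a trailing partial copy). The reported motif is the
#' leftmost primitive motif; the same array is never reported again under a
#' rotated or repeated motif (e.g. a homopolymer run is not also a
#' dinucleotide hit).
#'
#' @param s A [nuc_seq], [circular_genome] or character scalar.
#' @param min_motif,max_motif Motif length bounds (defaults 1 and 6).
#' @param min_copies Minimum copy number (default 3, the lower end of
#'   copy numbers typically reported for control-region dinucleotide
#'   microsatellites).
#' @return Data.frame of hits sorted by start: `start` (1-based), `motif`,
#'   `motif_len`, `copies` (span/motif_len, 1 decimal), `span`, `consensus`
#'   (equal to `motif` for perfect arrays).
#' @export
find_microsatellites <- function(s, min_motif = 1L, max_motif = 6L,
                                 min_copies = 3) {
  s <- as_nuc_seq(s)$bases
  n <- nchar(s)
  cs <- chars(s)
  hits <- list()
  for (k in seq(min_motif, max_motif)) {
    if (n < 2L * k) next
    e <- cs[seq_len(n - k)] == cs[seq_len(n - k) + k]
    r <- rle(e)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      run <- r$lengths[i]
      span <- run + k
      if (span / k < min_copies) next
      a <- starts[i]
      motif <- substr(s, a, a + k - 1L)
      if (!is_primitive(motif)) next  # reported at the primitive period
      hits[[length(hits) + 1L]] <- data.frame(
        start = a, motif = motif, motif_len = k,
        copies = round(span / k, 1L), span = span, consensus = motif,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty_hits())
  out <- do.call(rbind, hits)
  out[order(out$start, out$motif_len), , drop = FALSE]
}

# maximal segments of `e` (logical) whose FALSE fraction stays <= frac.
# Segments are anchored on runs of >= min_anchor consecutive matches and
# merged greedily across mismatch gaps; short leading/trailing match runs
# (chance matches in flanking sequence) never extend a segment boundary.
mismatch_tolerant_segments <- function(e, frac, min_anchor = 5L) {
  r <- rle(e)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  idx <- which(r$values & r$lengths >= min_anchor)
  if (length(idx) == 0L) return(data.frame(a = integer(), b = integer(), mism = integer()))
  # mismatches between two anchors = total FALSE bases strictly between them
  false_cum <- cumsum(ifelse(r$values, 0L, r$lengths))
  segs <- list()
  a <- starts[idx[1L]]; b <- ends[idx[1L]]; b_run <- idx[1L]; mism <- 0L
  if (length(idx) > 1L) for (j in idx[-1L]) {
    gap <- false_cum[j - 1L] - false_cum[b_run]
    newlen <- ends[j] - a + 1L
    if ((mism + gap) / newlen <= frac) {
      mism <- mism + gap
      b <- ends[j]; b_run <- j
    } else {
      segs[[length(segs) + 1L]] <- c(a, b, mism)
      a <- starts[j]; b <- ends[j]; b_run <- j; mism <- 0L
    }
  }
  segs[[length(segs) + 1L]] <- c(a, b, mism)
  out <- do.call(rbind, segs)
  data.frame(a = out[, 1L], b = out[, 2L], mism = out[, 3L])
}

#' Find approximate tandem repeats
#'
#' Simplified tandem-repeat finder: candidate periods are scanned by
#' self-comparison at each lag, arrays are extended while the mismatch
#' fraction stays at or below `max_mismatch_frac`, and the consensus is the
#' per-column majority across copies. Copy number is span/period, reported
#' to one decimal. `min_align` (minimum matched self-alignment length)
#' guards against chance hits in random sequence.
#'
#' @param s A [nuc_seq], [circular_genome] or character scalar longer than
#'   `2 * min_period`.
#' @param min_period,max_period Period bounds (defaults 7 and 30; shorter
#'   motifs belong to [find_microsatellites()]).
#' @param min_copies Minimum (fractional) copy number, default 1.8.
#' @param max_mismatch_frac Maximum mismatch fraction in the self-alignment,
#'   default 0.2.
#' @param min_align Minimum matched length of the lagged self-alignment
#'   (default 20).
#' @return Data.frame of hits sorted by start: `start`, `motif`
#'   (= consensus), `motif_len` (period), `copies`, `span`, `consensus`.
#' @export
find_tandem_repeats <- function(s, min_period = 7L, max_period = 30L,
                                min_copies = 1.8, max_mismatch_frac = 0.2,
                                min_align = 20L) {
  s <- as_nuc_seq(s)$bases
  n <- nchar(s)
  if (n <= 2L * min_period) stop("sequence shorter than twice the minimum period")
  cs <- chars(s)
  hits <- list()
  for (p in seq(min_period, min(max_period, n - 1L))) {
    if (n - p < min_align) break
    e <- cs[seq_len(n - p)] == cs[seq_len(n - p) + p]
    segs <- mismatch_tolerant_segments(e, max_mismatch_frac)
    for (i in seq_len(nrow(segs))) {
      L <- segs$b[i] - segs$a[i] + 1L
      if (L < max(ceiling((min_copies - 1) * p), min_align)) next
      span <- L + p
      a <- segs$a[i]
      cons <- repeat_consensus(cs, a, span, p)
      if (smallest_period(cons) < p) next  # power of a shorter motif
      hits[[length(hits) + 1L]] <- data.frame(
        start = a, motif = cons, motif_len = p,
        copies = round(span / p, 1L), span = span, consensus = cons,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty_hits())
  out <- do.call(rbind, hits)
  out <- out[order(out$motif_len, out$start), , drop = FALSE]
  # suppress re-detections of an accepted array at a longer period
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    ai <- out$start[i]; bi <- ai + out$span[i] - 1L
    ok <- TRUE
    for (j in which(keep)) {
      aj <- out$start[j]; bj <- aj + out$span[j] - 1L
      ov <- max(0L, min(bi, bj) - max(ai, aj) + 1L)
      if (ov > 0.5 * min(out$span[i], out$span[j])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

repeat_consensus <- function(cs, start, span, period) {
  region <- cs[start:(start + span - 1L)]
  cons <- character(period)
  for (col in seq_len(period)) {
    col_chars <- region[seq(col, span, by = period)]
    tab <- sort(table(col_chars), decreasing = TRUE)
    cons[col] <- names(tab)[1L]
  }
  collapse(cons)
}
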