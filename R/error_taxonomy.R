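ERROR_CATEGORIES <- c("homopolymer_insertion", "homopolymer_deletion",
                      "simple_substitution", "single_insertion",
                      "short_insertion", "single_deletion", "short_deletion")

MULTIPLICITY_LABELS <- c("single", "double", "triple", "quadruple",
                         "quintuple", "sextuple", "septuple", "gt7")

multiplicity_label <- function(size) {
  ifelse(size > 7L, "gt7", MULTIPLICITY_LABELS[pmin(size, 8L)])
}

empty_events <- function() {
  data.frame(type = character(), ref_pos = integer(), size = integer(),
              ref_bases = character(), qry_bases = character(),
              category = character(), multiplicity = character(),
              homopolymer_base = character(), tandem_duplication = logical(),
              stringsAsFactors = FALSE)
}

#' Extract discrepancy events from an alignment
#'
#' Maximal runs of contiguous gap columns on one side become a single indel
#' event; each mismatch column becomes one substitution event of size 1
#' (there is no multi-base substitution category). Coordinates are 1-based
#' on the reference; for an insertion, `ref_pos` is the reference position
#' immediately 5' of the inserted bases (0 if at the start).
#'
#' @param aln An `alignment_result`.
#' @return A data.frame of unclassified events with columns `type`
#'   (`substitution`/`insertion`/`deletion`), `ref_pos`, `size`,
#'   `ref_bases`, `qry_bases`.
#' @export
extract_events <- function(aln) {
  cc <- aln_cols(aln)
  rg <- cc$ref == "-"; qg <- cc$qry == "-"
  if (any(rg & qg)) stop("alignment has a gap-in-both column")
  state <- ifelse(rg, "I", ifelse(qg, "D", ifelse(cc$ref != cc$qry, "S", "M")))
  refpos <- cumsum(!rg)  # reference coordinate of each non-insertion column
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (v == "M") next
    a <- starts[i]; b <- ends[i]
    if (v == "S") {
      for (j in a:b) {
        out[[length(out) + 1L]] <- data.frame(
          type = "substitution", ref_pos = refpos[j], size = 1L,
          ref_bases = cc$ref[j], qry_bases = cc$qry[j],
          stringsAsFactors = FALSE)
      }
    } else if (v == "D") {
      out[[length(out) + 1L]] <- data.frame(
        type = "deletion", ref_pos = refpos[a], size = b - a + 1L,
        ref_bases = collapse(cc$ref[a:b]), qry_bases = "",
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        type = "insertion", ref_pos = if (a == 1L) 0L else refpos[a - 1L],
        size = b - a + 1L, ref_bases = "",
        qry_bases = collapse(cc$qry[a:b]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_events()[, 1:5])
  do.call(rbind, out)
}

#' Left-normalize indel events
#'
#' Shifts each indel to its leftmost equivalent placement on the reference
#' (VCF-style normalization), so events inside homopolymers and repeats get
#' deterministic coordinates regardless of where the aligner put the gap.
#'
#' @param events Data.frame from [extract_events()].
#' @param ref Reference [nuc_seq] (or coercible).
#' @return The events with updated `ref_pos`/`ref_bases`/`qry_bases`,
#'   re-sorted by `ref_pos`.
#' @export
left_normalize_events <- function(events, ref) {
  ref <- as_nuc_seq(ref, "ref")$bases
  if (nrow(events) == 0L) return(events)
  for (i in seq_len(nrow(events))) {
    if (events$type[i] == "deletion") {
      a <- events$ref_pos[i]; L <- events$size[i]
      while (a > 1L && substr(ref, a - 1L, a - 1L) == substr(ref, a + L - 1L, a + L - 1L))
        a <- a - 1L
      events$ref_pos[i] <- a
      events$ref_bases[i] <- substr(ref, a, a + L - 1L)
    } else if (events$type[i] == "insertion") {
      p <- events$ref_pos[i]; s <- events$qry_bases[i]; L <- events$size[i]
      while (p >= 1L && substr(s, L, L) == substr(ref, p, p)) {
        s <- paste0(substr(ref, p, p), substr(s, 1L, L - 1L))
        p <- p - 1L
      }
      events$ref_pos[i] <- p
      events$qry_bases[i] <- s
    }
  }
  events[order(events$ref_pos, events$type), , drop = FALSE]
}

run_length_at <- function(ref, pos, base, dir) {
  # length of the run of `base` starting at ref position `pos`, extending
  # in direction dir (+1 forward / -1 backward); 0 if out of range
  n <- nchar(ref); len <- 0L
  while (pos >= 1L && pos <= n && substr(ref, pos, pos) == base) {
    len <- len + 1L
    pos <- pos + dir
  }
  len
}

#' Classify discrepancy events
#'
#' Applies the nanopore-oriented error taxonomy. An insertion or deletion is
#' a homopolymer event iff all its bases are one base X and it is adjacent,
#' on either reference flank, to a run of X at least `min_run` long; its
#' multiplicity label maps size 1..7 to single..septuple (larger events get
#' `gt7`). Mixed-base indels never count as homopolymer events. Remaining
#' indels of size 1 are single insertions/deletions, size >= 2 short
#' insertions/deletions. An insertion equal to the reference substring of
#' the same length on either flank is flagged `tandem_duplication` (the
#' category is unchanged and the event still counts once). Mismatch columns
#' are simple substitutions.
#'
#' @param events Data.frame from [extract_events()], ideally after
#'   [left_normalize_events()].
#' @param ref Reference [nuc_seq] (or coercible).
#' @param min_run Minimum flanking run length for homopolymer context
#'   (default 2).
#' @return The events data.frame with `category`, `multiplicity`,
#'   `homopolymer_base` and `tandem_duplication` columns filled in.
#' @export
classify_events <- function(events, ref, min_run = 2L) {
  ref <- as_nuc_seq(ref, "ref")$bases
  n <- nrow(events)
  events$category <- character(n)
  events$multiplicity <- rep(NA_character_, n)
  events$homopolymer_base <- rep(NA_character_, n)
  events$tandem_duplication <- rep(FALSE, n)
  if (n == 0L) return(events)
  rlen <- nchar(ref)
  for (i in seq_len(n)) {
    type <- events$type[i]; size <- events$size[i]
    pos <- events$ref_pos[i]
    if (pos < 0L || pos > rlen) stop("event ", i, " outside the reference")
    if (type == "substitution") {
      events$category[i] <- "simple_substitution"
      next
    }
    seg <- if (type == "insertion") events$qry_bases[i] else events$ref_bases[i]
    segc <- chars(seg)
    uniform <- length(unique(segc)) == 1L
    X <- segc[1L]
    if (type == "insertion") {
      left <- run_length_at(ref, pos, X, -1L)
      right <- run_length_at(ref, pos + 1L, X, +1L)
    } else {
      left <- run_length_at(ref, pos - 1L, X, -1L)
      right <- run_length_at(ref, pos + size, X, +1L)
    }
    if (uniform && max(left, right) >= min_run) {
      events$category[i] <- if (type == "insertion") "homopolymer_insertion"
                            else "homopolymer_deletion"
      events$multiplicity[i] <- multiplicity_label(size)
      events$homopolymer_base[i] <- X
      next
    }
    if (type == "insertion") {
      events$category[i] <- if (size == 1L) "single_insertion" else "short_insertion"
      # tandem duplication: inserted bases equal the reference substring of
      # the same length on either flank (left-normalization shifts a
      # duplication to just before its template copy)
      prec <- if (pos - size + 1L >= 1L) substr(ref, pos - size + 1L, pos) else ""
      foll <- if (pos + size <= rlen) substr(ref, pos + 1L, pos + size) else ""
      events$tandem_duplication[i] <- identical(seg, prec) || identical(seg, foll)
    } else {
      events$category[i] <- if (size == 1L) "single_deletion" else "short_deletion"
    }
  }
  events
}

#' Tally classified events
#'
#' @param events Data.frame of classified events.
#' @return Object of class `error_summary`: `by_category` (named integer
#'   vector over all seven categories), `by_multiplicity` (data.frame of
#'   homopolymer counts per multiplicity label), `n_tandem_duplication`,
#'   and `total_errors` (= number of events).
#' @export
summarize_events <- function(events) {
  by_cat <- setNames(integer(length(ERROR_CATEGORIES)), ERROR_CATEGORIES)
  tab <- table(events$category)
  by_cat[names(tab)] <- as.integer(tab)
  hp <- events[events$category %in% c("homopolymer_insertion", "homopolymer_deletion"), ]
  by_mult <- expand.grid(category = c("homopolymer_insertion", "homopolymer_deletion"),
                         multiplicity = MULTIPLICITY_LABELS,
                         stringsAsFactors = FALSE)
  by_mult$n <- mapply(function(cat, m) sum(hp$category == cat & hp$multiplicity == m),
                      by_mult$category, by_mult$multiplicity)
  structure(list(by_category = by_cat,
                 by_multiplicity = by_mult[by_mult$n > 0L | TRUE, , drop = FALSE],
                 n_tandem_duplication = sum(events$tandem_duplication %||% FALSE),
                 total_errors = nrow(events)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> total %d\n", x$total_errors))
  nz <- x$by_category[x$by_category > 0L]
  for (nm in names(nz)) cat(sprintf("  %-22s %d\n", nm, nz[[nm]]))
  if (x$n_tandem_duplication > 0L)
    cat(sprintf("  (%d flagged tandem_duplication)\n", x$n_tandem_duplication))
  invisible(x)
}

junction_pick_rotation <- function(events, rlen) {
  # rotation offset maximizing distance from known events (midpoint of the
  # largest event-free arc), so the re-alignment anchor region is clean
  pos <- sort(unique(pmax(events$ref_pos, 1L)))
  if (length(pos) == 0L) return(rlen %/% 2L)
  gaps <- diff(c(pos, pos[1L] + rlen))
  k <- which.max(gaps)
  as.integer((pos[k] + gaps[k] %/% 2L - 1L) %% rlen)
}

benchmark_pair <- function(ref, qry, circular = TRUE, normalize = TRUE,
                           scoring = align_scoring(), min_run = 2L,
                           junction_slack = 100L, coverage = NA_real_,
                           anchor_k = 21L) {
  ref <- if (inherits(ref, "circular_genome")) ref else circular_genome(ref, circular = circular)
  qry <- if (inherits(qry, "circular_genome")) qry else circular_genome(qry, circular = circular)
  rlen <- nchar(ref$seq$bases)
  strand <- "+"; rotation <- 0L

  nq <- qry
  if (normalize && qry$circular) {
    nq <- tryCatch(normalize_orientation(ref, qry, k = anchor_k),
                   error = function(e) {
                     warning("orientation normalization failed (", conditionMessage(e),
                             "); aligning the query as-is")
                     qry
                   })
    rotation <- attr(nq, "rotation") %||% 0L
    strand <- attr(nq, "strand") %||% "+"
  }

  run_one <- function(r, q) {
    aln <- global_align(r$seq, q$seq, scoring = scoring)
    ev <- extract_events(aln)
    ev <- left_normalize_events(ev, r$seq)
    ev <- classify_events(ev, r$seq, min_run = min_run)
    list(aln = aln, events = ev)
  }

  first <- run_one(ref, nq)
  chosen <- first

  near_seam <- function(ev) {
    nrow(ev) > 0L && any(ev$ref_pos <= junction_slack |
                         (ev$ref_pos + ev$size - 1L) >= rlen - junction_slack)
  }
  if (ref$circular && nq$circular && near_seam(first$events)) {
    # events near the linearization seam may be artifacts of cutting the
    # circle: re-rotate through an event-free arc, re-align, keep the
    # better-scoring event set
    off <- junction_pick_rotation(first$events, rlen)
    ref2 <- rotate(ref, off)
    nq2 <- tryCatch(normalize_orientation(ref2, nq, k = anchor_k),
                    error = function(e) NULL)
    if (!is.null(nq2)) {
      second <- run_one(ref2, nq2)
      if (second$aln$score > first$aln$score ||
          (second$aln$score == first$aln$score &&
           nrow(second$events) < nrow(first$events))) {
        # map event coordinates back to the original reference frame
        if (nrow(second$events) > 0L) {
          second$events$ref_pos <-
            as.integer((second$events$ref_pos - 1L + off) %% rlen + 1L)
          second$events <- second$events[order(second$events$ref_pos), , drop = FALSE]
        }
        chosen <- second
      }
    }
  }

  summary <- summarize_events(chosen$events)
  structure(list(
    query_id = qry$seq$id,
    n_contigs = 1L,
    total_length = nchar(qry$seq$bases),
    mean_coverage = coverage,
    p_distance = p_distance(chosen$aln),
    completeness = completeness(chosen$aln),
    circular = qry$circular,
    strand = strand,
    rotation = rotation,
    alignment_score = chosen$aln$score,
    error_summary = summary,
    events = chosen$events,
    alignment = chosen$aln),
    class = "accuracy_report")
}

#' Benchmark a query assembly against a reference
#'
#' The full accuracy pipeline: orientation/rotation normalization of a
#' circular query, end-to-end global alignment, p-distance and completeness,
#' and classification of every discrepancy into the error taxonomy. Events
#' within `junction_slack` of the linearization seam trigger a re-alignment
#' after rotating through an event-free arc; the better-scoring event set is
#' kept, which suppresses spurious end gaps at the circular seam.
#'
#' @param ref Reference: FASTA path, [circular_genome] or [nuc_seq].
#' @param qry Query: FASTA path (possibly multi-contig), [circular_genome]
#'   or [nuc_seq].
#' @param circular Are the assemblies circular? (default TRUE; used when
#'   coercing paths/sequences).
#' @param normalize Normalize query orientation first (default TRUE).
#' @param scoring [align_scoring] parameters.
#' @param min_run Homopolymer context threshold (default 2).
#' @param junction_slack Seam window in bases (default 100).
#' @param coverage Mean read coverage, pass-through metadata for reports.
#' @param anchor_k Anchor k-mer length for orientation normalization.
#' @return An `accuracy_report` (single query contig) or a list of them
#'   (multi-contig query FASTA).
#' @export
benchmark <- function(ref, qry, circular = TRUE, normalize = TRUE,
                      scoring = align_scoring(), min_run = 2L,
                      junction_slack = 100L, coverage = NA_real_,
                      anchor_k = 21L) {
  if (is.character(ref) && length(ref) == 1L && file.exists(ref)) {
    rseqs <- read_fasta(ref)
    if (length(rseqs) != 1L) stop("reference FASTA must contain exactly one contig")
    ref <- circular_genome(rseqs[[1L]], circular = circular)
  }
  qlist <- NULL
  if (is.character(qry) && length(qry) == 1L && file.exists(qry)) {
    qseqs <- read_fasta(qry)
    if (length(qseqs) == 0L) stop("no query contigs")
    qlist <- lapply(qseqs, circular_genome, circular = circular)
  } else {
    qlist <- list(if (inherits(qry, "circular_genome")) qry
                  else circular_genome(qry, circular = circular))
  }
  reports <- lapply(qlist, function(q)
    benchmark_pair(ref, q, circular = circular, normalize = normalize,
                   scoring = scoring, min_run = min_run,
                   junction_slack = junction_slack, coverage = coverage,
                   anchor_k = anchor_k))
  if (length(reports) == 1L) reports[[1L]] else reports
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %s\n", x$query_id))
  cat(sprintf("  contigs %d  length %d  coverage %s  circular %s\n",
              x$n_contigs, x$total_length,
              ifelse(is.na(x$mean_coverage), "NA", format(x$mean_coverage)),
              x$circular))
  cat(sprintf("  p-distance %.6f  completeness %.4f  errors %d\n",
              x$p_distance, x$completeness, x$error_summary$total_errors))
  invisible(x)
}

#' One-row data.frame view of an accuracy report
#'
#' Columns match the published benchmark-table layout: contig status,
#' length, coverage, p-distance, errors.
#'
#' @param x An `accuracy_report`.
#' @param ... Unused.
#' @return One-row data.frame.
#' @export
as.data.frame.accuracy_report <- function(x, ...) {
  data.frame(query = x$query_id,
             contig = if (x$circular) "Circular" else "Partial",
             length = x$total_length,
             coverage = x$mean_coverage,
             p_distance = x$p_distance,
             completeness = x$completeness,
             errors = x$error_summary$total_errors,
             stringsAsFactors = FALSE)
}

#' Write an accuracy report to TSV/JSON
#'
#' @param report An `accuracy_report` or list of them.
#' @param tsv,json,events Optional output paths: one-row-per-query summary
#'   TSV, full JSON, and per-event TSV (columns `ref_pos`, `category`,
#'   `multiplicity`, `size`, `ref_bases`, `qry_bases`, `homopolymer_base`,
#'   `tandem_duplication`).
#' @return The summary data.frame, invisibly.
#' @export
write_report <- function(report, tsv = NULL, json = NULL, events = NULL) {
  reports <- if (inherits(report, "accuracy_report")) list(report) else report
  df <- do.call(rbind, lapply(reports, as.data.frame))
  if (!is.null(tsv))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(events)) {
    ev <- do.call(rbind, lapply(reports, function(r) {
      if (nrow(r$events) == 0L) return(NULL)
      cbind(query = r$query_id,
            r$events[, c("ref_pos", "category", "multiplicity", "size",
                          "ref_bases", "qry_bases", "homopolymer_base",
                          "tandem_duplication")])
    }))
    if (is.null(ev)) ev <- cbind(query = character(),
                                 empty_events()[, c("ref_pos", "category",
                                                     "multiplicity", "size",
                                                     "ref_bases", "qry_bases",
                                                     "homopolymer_base",
                                                     "tandem_duplication")])
    write.table(ev, events, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    payload <- lapply(reports, function(r) {
      list(query = r$query_id,
           contig = if (r$circular) "Circular" else "Partial",
           length = r$total_length, coverage = r$mean_coverage,
           p_distance = r$p_distance, completeness = r$completeness,
           errors = r$error_summary$total_errors,
           by_category = as.list(r$error_summary$by_category),
           events = r$events)
    })
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(df)
}
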