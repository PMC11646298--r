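#' Synthetic mitogenome specification
#'
#' Describes a circular, A+T-rich mitogenome with planted homopolymer runs
#' and a control-region-like segment carrying dinucleotide microsatellites
#' and longer tandem repeats. Defaults emulate a teleost mitogenome:
#' ~16.5 kb, A+T around 55%, a long (11 bp) T homopolymer and a 5 bp A
#' homopolymer, and an ~850 bp CR at the end of the molecule holding
#' AT-rich dinucleotide microsatellites (3-5 copies) plus 17- and 20-bp
#' tandem repeats at fractional copy numbers.
#'
#' @param length Genome length in bases (default 16500).
#' @param at_fraction Target A+T fraction (default 0.55; realized within
#'   +/- 1%).
#' @param homopolymer_runs Data.frame with columns `base`, `length`, `at`
#'   (approximate 1-based position); `NULL` for the default plants.
#' @param cr_spec List with `length` (CR length, default 850),
#'   `microsatellites` (data.frame `motif`, `copies`) and `tandem_repeats`
#'   (data.frame `motif`, `copies`); `NULL` for defaults.
#' @param seed RNG seed.
#' @return Object of class `genome_spec`.
#' @export
genome_spec <- function(length = 16500L, at_fraction = 0.55,
                        homopolymer_runs = NULL, cr_spec = NULL, seed = 42L) {
  length <- as.integer(length)
  stopifnot(length >= 500L, at_fraction > 0, at_fraction < 1)
  if (is.null(homopolymer_runs)) {
    homopolymer_runs <- data.frame(
      base = c("T", "A"), length = c(11L, 5L),
      at = as.integer(c(0.45, 0.25) * length), stringsAsFactors = FALSE)
  }
  if (is.null(cr_spec)) {
    cr_spec <- list(
      length = 850L,
      microsatellites = data.frame(motif = c("AT", "TA", "CA"),
                                   copies = c(4, 5, 3),
                                   stringsAsFactors = FALSE),
      tandem_repeats = data.frame(
        motif = c("ACATATATGTATTATCA", "ATACATTAATAGTAATCAAC"),
        copies = c(5.4, 4.7), stringsAsFactors = FALSE))
  }
  cr_spec$length <- as.integer(cr_spec$length %||% 850L)
  cr_spec$microsatellites <- cr_spec$microsatellites %||%
    data.frame(motif = character(), copies = numeric())
  cr_spec$tandem_repeats <- cr_spec$tandem_repeats %||%
    data.frame(motif = character(), copies = numeric())
  structure(list(length = length, at_fraction = at_fraction,
                 homopolymer_runs = homopolymer_runs, cr_spec = cr_spec,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

sample_bases <- function(n, at) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

other_base <- function(avoid) {
  pool <- setdiff(c("A", "C", "G", "T"), avoid)
  if (length(pool) == 0L) stop("no base available")
  if (length(pool) == 1L) pool else sample(pool, 1L)
}

array_string <- function(motif, copies) {
  span <- round(copies * nchar(motif))
  substr(strrep(motif, ceiling(copies) + 1L), 1L, span)
}

#' Generate a synthetic circular mitogenome
#'
#' Seeded and fully reproducible. Plants every requested homopolymer run
#' (flanked by non-run bases so run lengths are exact) and lays the CR
#' repeat arrays end-to-end with random spacers inside the CR segment at
#' the end of the molecule; flanking bases are chosen to break each array
#' so planted period and copy numbers are maximal. Background composition
#' is nudged (by flipping bases at non-feature positions) until the
#' realized A+T fraction is within +/- 1% of target. The first 30 bases are
#' kept feature-free so the reference start anchor used in orientation
#' normalization stays unambiguous.
#'
#' @param spec A [genome_spec].
#' @return Object of class `synthetic_genome`: `genome` (a
#'   [circular_genome]) and `manifest` (data.frame of planted features with
#'   1-based `start`/`end`: homopolymers, microsatellites, tandem repeats,
#'   and the CR segment itself).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  n <- spec$length
  cr <- spec$cr_spec
  cr_start <- n - cr$length + 1L
  if (cr_start <= 60L) stop("CR does not fit in the genome")

  local_seed(spec$seed, {
    b <- sample_bases(n, spec$at_fraction)
    feature <- logical(n)
    feature[seq_len(30L)] <- TRUE  # reserved anchor region, left as background
    manifest <- list()

    put_array <- function(b, feature, manifest, seq_str, period, start, label, copies) {
      span <- nchar(seq_str)
      end <- start + span - 1L
      if (start < 2L || end > n - 1L) stop("planted feature does not fit")
      if (any(feature[(start - 1L):(end + 1L)]))
        stop("planted features overlap: ", label)
      b[start:end] <- chars(seq_str)
      # break the array at both flanks so period/copies are maximal
      b[start - 1L] <- other_base(c(b[start + period - 1L], b[start]))
      b[end + 1L] <- other_base(c(b[end - period + 1L], b[end]))
      feature[(start - 1L):(end + 1L)] <- TRUE
      manifest[[length(manifest) + 1L]] <- data.frame(
        feature = label, motif = if (period == 1L) substr(seq_str, 1L, 1L)
                                 else substr(seq_str, 1L, period),
        period = period, copies = copies, start = start, end = end,
        stringsAsFactors = FALSE)
      list(b = b, feature = feature, manifest = manifest)
    }

    # homopolymer runs
    hp <- spec$homopolymer_runs
    if (!is.null(hp) && nrow(hp)) for (i in seq_len(nrow(hp))) {
      st <- as.integer(hp$at[i])
      res <- put_array(b, feature, manifest,
                       strrep(hp$base[i], hp$length[i]), 1L, st,
                       "homopolymer", hp$length[i])
      b <- res$b; feature <- res$feature; manifest <- res$manifest
    }

    # CR segment: AT-rich background, then arrays laid out with spacers
    b[cr_start:n] <- sample_bases(cr$length, min(spec$at_fraction + 0.07, 0.9))
    arrays <- rbind(
      if (nrow(cr$microsatellites))
        data.frame(label = "microsatellite", motif = cr$microsatellites$motif,
                   copies = cr$microsatellites$copies, stringsAsFactors = FALSE),
      if (nrow(cr$tandem_repeats))
        data.frame(label = "tandem_repeat", motif = cr$tandem_repeats$motif,
                   copies = cr$tandem_repeats$copies, stringsAsFactors = FALSE))
    if (!is.null(arrays) && nrow(arrays)) {
      seqs <- mapply(array_string, arrays$motif, arrays$copies)
      spans <- nchar(seqs)
      k <- nrow(arrays)
      slack <- cr$length - 10L - sum(spans) - 2L * k
      if (slack < 0L) stop("CR repeat arrays do not fit in the CR")
      # random partition of the slack into k+1 spacer gaps
      gaps <- as.integer(floor(slack * diff(sort(c(0, runif(k), 1)))))
      pos <- cr_start + 5L
      for (i in seq_len(k)) {
        pos <- pos + gaps[i] + 2L
        res <- put_array(b, feature, manifest, seqs[i], nchar(arrays$motif[i]),
                         pos, arrays$label[i], arrays$copies[i])
        b <- res$b; feature <- res$feature; manifest <- res$manifest
        pos <- pos + spans[i]
      }
    }
    manifest[[length(manifest) + 1L]] <- data.frame(
      feature = "CR", motif = NA_character_, period = NA_integer_,
      copies = NA_real_, start = cr_start, end = n, stringsAsFactors = FALSE)

    # nudge background composition toward the A+T target
    free <- which(!feature & seq_len(n) < cr_start)
    for (iter in 1:8) {
      at_now <- mean(b %in% c("A", "T"))
      diff <- spec$at_fraction - at_now
      if (abs(diff) <= 0.0025) break
      k <- min(length(free), ceiling(abs(diff) * n))
      if (diff > 0) {
        cand <- free[b[free] %in% c("C", "G")]
        flip <- sample(cand, min(k, length(cand)))
        b[flip] <- sample(c("A", "T"), length(flip), replace = TRUE)
      } else {
        cand <- free[b[free] %in% c("A", "T")]
        flip <- sample(cand, min(k, length(cand)))
        b[flip] <- sample(c("C", "G"), length(flip), replace = TRUE)
      }
    }

    manifest <- do.call(rbind, manifest)
    genome <- circular_genome(nuc_seq(collapse(b), id = sprintf("synthetic_mt_%d", spec$seed)))
    structure(list(genome = genome, manifest = manifest),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  print(x$genome)
  cat(sprintf("  %d planted features\n", nrow(x$manifest)))
  invisible(x)
}

#' Error-injection profile
#'
#' Exact per-category counts of discrepancies to plant in an assembly copy.
#' Homopolymer counts are given per multiplicity: element i of
#' `homopolymer_insertion`/`homopolymer_deletion` is the number of events
#' of size i (1 = single ... 7 = septuple); a bare scalar means that many
#' single (size-1) events.
#'
#' @param simple_substitution,single_insertion,single_deletion Counts of
#'   size-1 events.
#' @param short_insertion,short_deletion Counts of multi-base (mixed-base)
#'   indels; sizes drawn uniformly from `short_size_range`.
#' @param homopolymer_insertion,homopolymer_deletion Integer vector of
#'   counts by multiplicity (length up to 7), or a scalar count of singles.
#' @param tandem_duplication Count of tandem-duplication insertions of
#'   `tandem_motif_len` bases.
#' @param tandem_motif_len Motif length for tandem duplications (default 14).
#' @param short_size_range Size range for short indels (default 2:5).
#' @param seed RNG seed for site selection.
#' @return Object of class `error_profile`.
#' @export
error_profile <- function(simple_substitution = 0L, single_insertion = 0L,
                          short_insertion = 0L, single_deletion = 0L,
                          short_deletion = 0L, homopolymer_insertion = 0L,
                          homopolymer_deletion = 0L, tandem_duplication = 0L,
                          tandem_motif_len = 14L, short_size_range = 2:5,
                          seed = 42L) {
  as_mult <- function(x) {
    x <- as.integer(x)
    if (length(x) == 1L) x <- c(x, integer(6L))
    if (length(x) > 7L) stop("homopolymer multiplicities go up to 7 here")
    c(x, integer(7L - length(x)))
  }
  p <- structure(list(
    simple_substitution = as.integer(simple_substitution),
    single_insertion = as.integer(single_insertion),
    short_insertion = as.integer(short_insertion),
    single_deletion = as.integer(single_deletion),
    short_deletion = as.integer(short_deletion),
    homopolymer_insertion = as_mult(homopolymer_insertion),
    homopolymer_deletion = as_mult(homopolymer_deletion),
    tandem_duplication = as.integer(tandem_duplication),
    tandem_motif_len = as.integer(tandem_motif_len),
    short_size_range = as.integer(short_size_range),
    seed = as.integer(seed)), class = "error_profile")
  counts <- unlist(p[c("simple_substitution", "single_insertion",
                       "short_insertion", "single_deletion", "short_deletion",
                       "homopolymer_insertion", "homopolymer_deletion",
                       "tandem_duplication")])
  if (any(counts < 0L)) stop("error counts must be non-negative")
  p$total <- sum(counts)
  p
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("<error_profile> %d events (seed %d)\n", x$total, x$seed))
  invisible(x)
}

#' Expected per-category summary of a profile
#'
#' The `error_summary` (as produced by [summarize_events()]) that a perfect
#' benchmark run should recover after injecting `profile` (tandem
#' duplications count as short or single insertions, flagged).
#'
#' @param profile An [error_profile].
#' @return An `error_summary`.
#' @export
profile_expected_summary <- function(profile) {
  ev <- profile_truth_template(profile)
  summarize_events(ev)
}

profile_truth_template <- function(p) {
  rows <- list()
  add <- function(category, mult = NA_character_, n = 1L, tandem = FALSE) {
    if (n <= 0L) return()
    for (i in seq_len(n))
      rows[[length(rows) + 1L]] <<- data.frame(
        category = category, multiplicity = mult,
        tandem_duplication = tandem, stringsAsFactors = FALSE)
  }
  add("simple_substitution", n = p$simple_substitution)
  add("single_insertion", n = p$single_insertion)
  add("short_insertion", n = p$short_insertion)
  add("single_deletion", n = p$single_deletion)
  add("short_deletion", n = p$short_deletion)
  for (m in 1:7) {
    add("homopolymer_insertion", MULTIPLICITY_LABELS[m], p$homopolymer_insertion[m])
    add("homopolymer_deletion", MULTIPLICITY_LABELS[m], p$homopolymer_deletion[m])
  }
  add(if (p$tandem_motif_len == 1L) "single_insertion" else "short_insertion",
      n = p$tandem_duplication, tandem = TRUE)
  if (length(rows) == 0L) return(empty_events())
  do.call(rbind, rows)
}

#' Inject a known error profile into a genome
#'
#' Produces a mutated copy of `g` containing exactly the requested events,
#' together with a truth table in canonical (left-normalized) coordinates.
#' Sites are chosen by a seeded RNG under placement rules that keep truth
#' classification unambiguous: events sit at least `min_sep` bases apart,
#' outside planted repeat arrays and the CR, away from the molecule ends
#' (seam region) and the orientation anchor; substitution/indel bases are
#' picked so no planted event can be reinterpreted as a different category.
#' Homopolymer events use runs actually present in the genome (insertions
#' need a run of at least 2, a deletion of multiplicity m needs a run of at
#' least m + 2 so homopolymer context survives the deletion).
#'
#' @param g A [circular_genome] or `synthetic_genome` (whose manifest is
#'   then used to mask repeat regions).
#' @param profile An [error_profile].
#' @param min_sep Minimum separation between events (default 15).
#' @return Object of class `injected_genome`: `genome` (mutated
#'   [circular_genome]) and `truth` (classified event data.frame as
#'   [classify_events()] would produce).
#' @export
inject_errors <- function(g, profile, min_sep = 15L) {
  stopifnot(inherits(profile, "error_profile"))
  manifest <- NULL
  if (inherits(g, "synthetic_genome")) {
    manifest <- g$manifest
    g <- g$genome
  }
  stopifnot(inherits(g, "circular_genome"))
  b <- chars(g$seq$bases)
  n <- length(b)
  mask <- logical(n)
  mask[seq_len(min(35L, n))] <- TRUE        # orientation anchor
  mask[max(1L, n - 35L):n] <- TRUE          # linearization seam
  if (!is.null(manifest) && nrow(manifest)) {
    # repeat arrays and the CR are off-limits (truth would be ambiguous
    # there); planted homopolymer runs stay available for homopolymer events
    arr <- manifest[manifest$feature %in%
                    c("microsatellite", "tandem_repeat", "CR"), , drop = FALSE]
    for (i in seq_len(nrow(arr))) {
      a <- max(1L, arr$start[i] - 2L)
      z <- min(n, arr$end[i] + 2L)
      mask[a:z] <- TRUE
    }
  }

  local_seed(profile$seed, {
    truth <- list()
    unmet <- character()

    occupy <- function(a, z) {
      mask[max(1L, a - min_sep):min(n, z + min_sep)] <<- TRUE
    }
    pick <- function(cand) if (length(cand) == 0L) NA_integer_
                           else if (length(cand) == 1L) cand
                           else sample(cand, 1L)
    free_span <- function(a, z) a >= 1L && z <= n && !any(mask[a:z])

    runs_df <- function() {
      r <- rle(b)
      ends <- cumsum(r$lengths)
      data.frame(base = r$values, len = r$lengths,
                 start = ends - r$lengths + 1L, end = ends,
                 stringsAsFactors = FALSE)
    }

    add_truth <- function(type, ref_pos, size, ref_bases, qry_bases, category,
                          mult = NA_character_, hp = NA_character_,
                          tandem = FALSE) {
      truth[[length(truth) + 1L]] <<- data.frame(
        type = type, ref_pos = as.integer(ref_pos), size = as.integer(size),
        ref_bases = ref_bases, qry_bases = qry_bases, category = category,
        multiplicity = mult, homopolymer_base = hp, tandem_duplication = tandem,
        stringsAsFactors = FALSE)
    }

    # --- homopolymer deletions (largest multiplicities first) ---
    for (m in 7:1) for (k in seq_len(profile$homopolymer_deletion[m])) {
      rr <- runs_df()
      ok <- which(rr$len >= m + 2L &
                  vapply(seq_len(nrow(rr)),
                         function(i) free_span(rr$start[i] - 1L, rr$end[i] + 1L),
                         TRUE))
      i <- pick(ok)
      if (is.na(i)) { unmet <- c(unmet, sprintf("homopolymer_deletion x%d", m)); next }
      a <- rr$start[i]
      add_truth("deletion", a, m, strrep(rr$base[i], m), "",
                "homopolymer_deletion", MULTIPLICITY_LABELS[m], rr$base[i])
      occupy(rr$start[i] - 1L, rr$end[i] + 1L)
    }

    # --- homopolymer insertions ---
    for (m in 7:1) for (k in seq_len(profile$homopolymer_insertion[m])) {
      rr <- runs_df()
      ok <- which(rr$len >= 2L &
                  vapply(seq_len(nrow(rr)),
                         function(i) free_span(rr$start[i] - 1L, rr$end[i] + 1L),
                         TRUE))
      i <- pick(ok)
      if (is.na(i)) { unmet <- c(unmet, sprintf("homopolymer_insertion x%d", m)); next }
      add_truth("insertion", rr$start[i] - 1L, m, "", strrep(rr$base[i], m),
                "homopolymer_insertion", MULTIPLICITY_LABELS[m], rr$base[i])
      occupy(rr$start[i] - 1L, rr$end[i] + 1L)
    }

    # draw from a precomputed candidate set, re-checking the occupancy mask
    # (spanned by span_fn) lazily at pick time
    pick_site <- function(cand, span_fn, tries = 500L) {
      if (length(cand) == 0L) return(NA_integer_)
      for (t in seq_len(min(tries, 4L * length(cand)))) {
        x <- cand[sample.int(length(cand), 1L)]
        sp <- span_fn(x)
        if (free_span(sp[1L], sp[2L])) return(x)
      }
      NA_integer_
    }

    gs <- collapse(b)
    sub_at <- function(pos) b[pos]  # b never changes during selection

    # --- tandem duplications ---
    L <- profile$tandem_motif_len
    if (profile$tandem_duplication > 0L) {
      p_all <- seq(max(2L * L, L + 2L), n - L)
      motif <- substring(gs, p_all - L + 1L, p_all)
      cand <- p_all[motif != strrep(substring(gs, p_all - L + 1L, p_all - L + 1L), L) &
                    b[p_all] != b[p_all - L] &
                    motif != substring(gs, p_all - 2L * L + 1L, p_all - L) &
                    motif != substring(gs, p_all + 1L, p_all + L)]
      for (k in seq_len(profile$tandem_duplication)) {
        p <- pick_site(cand, function(p) c(p - 2L * L + 1L, p + L))
        if (is.na(p)) { unmet <- c(unmet, "tandem_duplication"); next }
        m <- substr(gs, p - L + 1L, p)
        # canonical (left-normalized) placement is just before the template
        add_truth("insertion", p - L, L, "", m,
                  if (L == 1L) "single_insertion" else "short_insertion",
                  tandem = TRUE)
        occupy(p - 2L * L + 1L, p + L)
      }
    }

    # --- short deletions ---
    for (k in seq_len(profile$short_deletion)) {
      s <- if (length(profile$short_size_range) == 1L) profile$short_size_range
           else sample(profile$short_size_range, 1L)
      a_all <- seq(s + 2L, n - s)
      seg <- substring(gs, a_all, a_all + s - 1L)
      cand <- a_all[seg != strrep(substring(gs, a_all, a_all), s) &
                    b[a_all - 1L] != b[a_all + s - 1L] &
                    seg != substring(gs, a_all - s, a_all - 1L) &
                    seg != substring(gs, a_all + s, a_all + 2L * s - 1L)]
      a <- pick_site(cand, function(a) c(a - 1L, a + s))
      if (is.na(a)) { unmet <- c(unmet, "short_deletion"); next }
      add_truth("deletion", a, s, substr(gs, a, a + s - 1L), "",
                "short_deletion")
      occupy(a - 1L, a + s)
    }

    # --- short insertions ---
    for (k in seq_len(profile$short_insertion)) {
      s <- if (length(profile$short_size_range) == 1L) profile$short_size_range
           else sample(profile$short_size_range, 1L)
      cand <- seq(s + 2L, n - s - 1L)
      p <- pick_site(cand, function(p) c(p, p + 1L))
      if (is.na(p)) { unmet <- c(unmet, "short_insertion"); next }
      repeat {
        st <- sample(c("A", "C", "G", "T"), s, replace = TRUE)
        if (length(unique(st)) < 2L) next
        if (st[s] == b[p]) next                     # would left-shift
        sts <- collapse(st)
        if (sts == substr(gs, p - s + 1L, p)) next
        if (sts == substr(gs, p + 1L, p + s)) next
        break
      }
      add_truth("insertion", p, s, "", collapse(st), "short_insertion")
      occupy(p, p + 1L)
    }

    # --- single deletions ---
    {
      a_all <- seq(3L, n - 2L)
      sd_cand <- a_all[b[a_all] != b[a_all - 1L] & b[a_all] != b[a_all + 1L]]
      for (k in seq_len(profile$single_deletion)) {
        a <- pick_site(sd_cand, function(a) c(a - 1L, a + 1L))
        if (is.na(a)) { unmet <- c(unmet, "single_deletion"); next }
        add_truth("deletion", a, 1L, b[a], "", "single_deletion")
        occupy(a - 1L, a + 1L)
      }
    }

    # --- single insertions ---
    {
      p_all <- seq(2L, n - 1L)
      si_cand <- p_all[b[p_all] != b[p_all + 1L]]
      for (k in seq_len(profile$single_insertion)) {
        p <- pick_site(si_cand, function(p) c(p, p + 1L))
        if (is.na(p)) { unmet <- c(unmet, "single_insertion"); next }
        y <- other_base(c(b[p], b[p + 1L]))
        add_truth("insertion", p, 1L, "", y, "single_insertion")
        occupy(p, p + 1L)
      }
    }

    # --- simple substitutions ---
    for (k in seq_len(profile$simple_substitution)) {
      a <- pick_site(seq(2L, n - 1L), function(a) c(a, a))
      if (is.na(a)) { unmet <- c(unmet, "simple_substitution"); next }
      y <- other_base(b[a])
      add_truth("substitution", a, 1L, b[a], y, "simple_substitution")
      occupy(a, a)
    }

    if (length(unmet))
      stop("profile unsatisfiable on this genome; unmet: ",
           paste(unmet, collapse = ", "))

    truth <- if (length(truth)) do.call(rbind, truth) else empty_events()
    truth <- truth[order(truth$ref_pos, truth$type), , drop = FALSE]
    rownames(truth) <- NULL

    # apply events right-to-left so earlier coordinates stay valid
    mb <- b
    if (nrow(truth)) {
      ord <- order(-truth$ref_pos)
      for (i in ord) {
        tp <- truth$type[i]; a <- truth$ref_pos[i]; s <- truth$size[i]
        if (tp == "substitution") {
          mb[a] <- truth$qry_bases[i]
        } else if (tp == "deletion") {
          mb <- mb[-(a:(a + s - 1L))]
        } else {
          mb <- append(mb, chars(truth$qry_bases[i]), after = a)
        }
      }
    }
    mut <- circular_genome(nuc_seq(collapse(mb),
                                   id = paste0(g$seq$id, "_mut")),
                           circular = g$circular)
    structure(list(genome = mut, truth = truth), class = "injected_genome")
  })
}

#' @export
print.injected_genome <- function(x, ...) {
  print(x$genome)
  cat(sprintf("  %d injected events\n", nrow(x$truth)))
  invisible(x)
}

#' Read-simulation specification
#'
#' ONT-like reads: lengths from a lognormal body clipped to
#' `[min_len, max_len]`, start positions uniform on the circle (reads wrap
#' the origin), i.i.d. per-base substitution/insertion/deletion errors, and
#' Gaussian-jittered Phred qualities around `mean_q`.
#'
#' @param depth Fold coverage of the template to simulate (default 30).
#' @param min_len,max_len Read length window (defaults 1000 and 20000).
#' @param meanlog,sdlog Lognormal length parameters (defaults log(8000),
#'   0.6).
#' @param sub_rate,ins_rate,del_rate Per-base error rates (defaults 0.02,
#'   0.005, 0.005).
#' @param mean_q,q_sd Phred quality model (defaults 12 and 3).
#' @param rc_fraction Fraction of reads drawn from the reverse strand
#'   (default 0.5).
#' @param seed RNG seed.
#' @return Object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(depth = 30, min_len = 1000L, max_len = 20000L,
                          meanlog = log(8000), sdlog = 0.6, sub_rate = 0.02,
                          ins_rate = 0.005, del_rate = 0.005, mean_q = 12,
                          q_sd = 3, rc_fraction = 0.5, seed = 42L) {
  stopifnot(depth > 0, min_len >= 1L, min_len <= max_len,
            sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1, rc_fraction >= 0, rc_fraction <= 1)
  structure(list(depth = depth, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), meanlog = meanlog,
                 sdlog = sdlog, sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, mean_q = mean_q, q_sd = q_sd,
                 rc_fraction = rc_fraction, seed = as.integer(seed)),
            class = "read_sim_spec")
}

mutate_template <- function(tmpl, spec) {
  ch <- chars(tmpl)
  L <- length(ch)
  u <- runif(L)
  del <- u < spec$del_rate
  sub <- !del & u < spec$del_rate + spec$sub_rate
  if (any(sub)) {
    ch[sub] <- vapply(ch[sub], other_base, "")
  }
  keep <- which(!del)
  ch <- ch[keep]
  ins <- runif(length(ch)) < spec$ins_rate
  if (any(ins)) {
    cnt <- 1L + as.integer(ins)
    out <- rep(ch, times = cnt)
    slots <- cumsum(cnt)[ins]
    out[slots] <- sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE)
    ch <- out
  }
  collapse(ch)
}

#' Simulate ONT-like reads from a circular genome
#'
#' Start positions are uniform on the circle with wraparound; with zero
#' error rates every forward read is an exact substring of the doubled
#' genome string. Reads are generated until total bases reach
#' `depth * genome length`. Deterministic for a given (genome, spec).
#'
#' @param g A [circular_genome] (or `synthetic_genome`).
#' @param spec A [read_sim_spec].
#' @return List of [read_record] objects.
#' @export
simulate_reads <- function(g, spec) {
  if (inherits(g, "synthetic_genome")) g <- g$genome
  stopifnot(inherits(g, "circular_genome"), inherits(spec, "read_sim_spec"))
  gseq <- g$seq$bases
  n <- nchar(gseq)
  target <- spec$depth * n
  local_seed(spec$seed, {
    reads <- list()
    total <- 0
    i <- 0L
    while (total < target) {
      i <- i + 1L
      len <- as.integer(round(rlnorm(1L, spec$meanlog, spec$sdlog)))
      len <- min(max(len, spec$min_len), spec$max_len)
      start <- sample.int(n, 1L)
      tmpl <- substr(strrep(gseq, (start + len - 1L) %/% n + 1L),
                     start, start + len - 1L)
      strand <- if (runif(1L) < spec$rc_fraction) "-" else "+"
      if (strand == "-") tmpl <- revcomp(tmpl)
      bases <- mutate_template(tmpl, spec)
      lo <- nchar(bases)
      quals <- pmin(pmax(as.integer(round(rnorm(lo, spec$mean_q, spec$q_sd))), 1L), 40L)
      reads[[i]] <- read_record(sprintf("read_%05d_%s%d", i, strand, start),
                                bases, quals)
      total <- total + lo
    }
    reads
  })
}
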