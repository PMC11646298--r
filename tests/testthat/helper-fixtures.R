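# shared fixtures: desk-scale genomes, random error profiles, and an
# independent affine-gap alignment score oracle

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(BASES, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else mitobench:::local_seed(seed, draw())
}

# small synthetic mitogenome: scaled-down CR, one tandem repeat, one
# microsatellite, plus homopolymer runs long enough for deletion events
small_genome <- function(seed, length = 3000L, extra_runs = NULL) {
  runs <- data.frame(
    base = c("T", "A", "C"), length = c(11L, 5L, 4L),
    at = as.integer(c(0.45, 0.25, 0.6) * length), stringsAsFactors = FALSE)
  if (!is.null(extra_runs)) runs <- rbind(runs, extra_runs)
  make_genome(genome_spec(
    length = length, at_fraction = 0.55, homopolymer_runs = runs,
    cr_spec = list(length = 350L,
                   microsatellites = data.frame(motif = "AT", copies = 4),
                   tandem_repeats = data.frame(motif = "ACATATATGTATTATCA",
                                               copies = 3.4)),
    seed = seed))
}

# random error profile with total events in [1, max_total]; homopolymer
# multiplicities capped so a desk-scale genome can host them
random_profile <- function(seed, max_total = 60L) {
  mitobench:::local_seed(seed, {
    total <- sample.int(max_total, 1L)
    alloc <- as.integer(rmultinom(1L, total,
                                  c(sub = 4, si = 3, shi = 2, sd = 3, shd = 2,
                                    hpi = 3, hpd = 2, td = 1)))
    alloc[8L] <- min(alloc[8L], 2L)   # tandem dups have a big footprint
    hp_split <- function(k, maxm) {
      v <- integer(7L)
      if (k > 0L) for (m in sample(seq_len(maxm), k, replace = TRUE))
        v[m] <- v[m] + 1L
      v
    }
    error_profile(
      simple_substitution = alloc[1L], single_insertion = alloc[2L],
      short_insertion = alloc[3L], single_deletion = alloc[4L],
      short_deletion = alloc[5L],
      homopolymer_insertion = hp_split(min(alloc[6L], 6L), 7L),
      homopolymer_deletion = hp_split(min(alloc[7L], 5L), 6L),
      tandem_duplication = alloc[8L],
      seed = seed + 1L) })
}

# genome able to host a given profile: plant one run per homopolymer
# deletion (length multiplicity + 3) and per insertion (length 2-4)
genome_for_profile <- function(profile, seed, length = 4000L) {
  del_m <- rep(1:7, profile$homopolymer_deletion)
  ins_n <- sum(profile$homopolymer_insertion)
  need <- c(del_m + 3L, rep(3L, ins_n))
  runs <- data.frame(
    base = rep(c("T", "A", "G", "C"), length.out = max(length(need), 1L)),
    length = if (length(need)) need else 11L,
    stringsAsFactors = FALSE)
  lo <- as.integer(0.05 * length); hi <- as.integer(0.75 * length)
  runs$at <- as.integer(seq(lo, hi, length.out = nrow(runs)))
  make_genome(genome_spec(length = length, homopolymer_runs = runs,
                          cr_spec = list(length = 300L,
                                         microsatellites = data.frame(),
                                         tandem_repeats = data.frame()),
                          seed = seed))
}

# independent plain-R affine-gap global alignment score (three-state DP,
# no traceback); used as oracle for tiny sequences
score_oracle <- function(ref, qry, match = 2, mismatch = -3,
                         go = 5, ge = 2) {
  n <- nchar(qry); m <- nchar(ref)
  r <- strsplit(ref, "")[[1]]; q <- strsplit(qry, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in seq_len(m)) X[1, j + 1] <- -go - ge * j
  for (i in seq_len(n)) Y[i + 1, 1] <- -go - ge * i
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (q[i] == r[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, X[i + 1, j] - ge,
                           Y[i + 1, j] - go - ge)
    Y[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - go - ge,
                           Y[i, j + 1] - ge)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

expect_same_summary <- function(report, truth) {
  exp <- summarize_events(truth)
  got <- report$error_summary
  expect_identical(got$by_category, exp$by_category)
  expect_identical(got$by_multiplicity$n, exp$by_multiplicity$n)
  expect_identical(got$total_errors, exp$total_errors)
  expect_identical(got$n_tandem_duplication, exp$n_tandem_duplication)
}

# is `a` a cyclic rotation of `b`?
is_rotation <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, strrep(b, 2), fixed = TRUE)
}
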