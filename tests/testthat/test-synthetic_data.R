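test_that("genome synthesis is seeded, on-composition, and manifest-complete", {
  spec <- genome_spec(seed = 101)
  a <- make_genome(spec)
  b <- make_genome(spec)
  expect_identical(a$genome$seq$bases, b$genome$seq$bases)
  expect_identical(length(a$genome), 16500L)

  at <- nucleotide_usage(a$genome)$at_pct / 100
  expect_lte(abs(at - 0.55), 0.01)

  man <- a$manifest
  t_run <- man[man$feature == "homopolymer" & man$motif == "T", ]
  expect_identical(t_run$copies, 11)
  run <- substr(a$genome$seq$bases, t_run$start, t_run$end)
  expect_identical(run, strrep("T", 11))
  # run is exact: flanks are not T
  expect_false(substr(a$genome$seq$bases, t_run$start - 1, t_run$start - 1) == "T")
  expect_false(substr(a$genome$seq$bases, t_run$end + 1, t_run$end + 1) == "T")
  expect_true("CR" %in% man$feature)
})

test_that("infeasible genome specs are rejected", {
  expect_error(make_genome(genome_spec(length = 900,
                                       cr_spec = list(length = 850))),
               "CR")
  spec <- genome_spec(length = 2000,
                      cr_spec = list(length = 500, tandem_repeats =
                        data.frame(motif = strrep("ACGT", 10), copies = 20)))
  expect_error(make_genome(spec), "fit")
})

test_that("error injection accounts for length and yields exact truth", {
  sg <- small_genome(111)
  n <- length(sg$genome)

  # empty profile -> identity
  inj <- inject_errors(sg, error_profile(seed = 1))
  expect_identical(inj$genome$seq$bases, sg$genome$seq$bases)
  expect_identical(nrow(inj$truth), 0L)

  # single homopolymer deletion in the planted 11-bp T run region -> -1 bp
  inj <- inject_errors(sg, error_profile(homopolymer_deletion = 1, seed = 2))
  expect_identical(length(inj$genome), n - 1L)
  expect_identical(inj$truth$category, "homopolymer_deletion")

  # tandem duplication of a 14-bp motif -> +14 bp
  inj <- inject_errors(sg, error_profile(tandem_duplication = 1, seed = 3))
  expect_identical(length(inj$genome), n + 14L)
  expect_true(inj$truth$tandem_duplication)

  # general accounting: insertions minus deletions
  prof <- error_profile(simple_substitution = 4, single_insertion = 2,
                        short_insertion = 2, single_deletion = 3,
                        short_deletion = 1, seed = 4)
  inj <- inject_errors(sg, prof)
  ins <- sum(inj$truth$size[inj$truth$type == "insertion"])
  del <- sum(inj$truth$size[inj$truth$type == "deletion"])
  expect_identical(length(inj$genome), n + ins - del)
  expect_identical(nrow(inj$truth), 12L)
})

test_that("unsatisfiable profiles report the unmet categories", {
  flat <- circular_genome(strrep("ACGT", 500))  # no runs of length >= 2
  expect_error(inject_errors(flat, error_profile(homopolymer_insertion = 1,
                                                 seed = 5)),
               "homopolymer_insertion")
})

test_that("read simulation covers the circle and respects the error model", {
  g <- make_genome(genome_spec(length = 4000, seed = 121))$genome
  spec <- read_sim_spec(depth = 20, min_len = 200, max_len = 2000,
                        meanlog = log(600), sub_rate = 0, ins_rate = 0,
                        del_rate = 0, rc_fraction = 0.3, seed = 122)
  reads <- simulate_reads(g, spec)
  total <- sum(vapply(reads, function(r) nchar(r$bases), 0L))
  expect_gte(total, 20 * 4000)
  expect_lt(total, 20 * 4000 + 2000)

  # zero error rates: every read is a substring of the doubled genome
  # (or of its reverse complement for reverse-strand reads)
  dbl <- strrep(g$seq$bases, 2)
  rdbl <- revcomp(dbl)
  for (r in reads[1:25]) {
    expect_true(grepl(r$bases, dbl, fixed = TRUE) ||
                grepl(r$bases, rdbl, fixed = TRUE))
  }

  again <- simulate_reads(g, spec)
  expect_identical(vapply(again, `[[`, "", "bases"),
                   vapply(reads, `[[`, "", "bases"))
})

test_that("simulated substitution rate matches the configured rate", {
  g <- make_genome(genome_spec(length = 16500, seed = 131))$genome
  spec <- read_sim_spec(depth = 60, min_len = 2000, max_len = 20000,
                        sub_rate = 0.01, ins_rate = 0, del_rate = 0,
                        rc_fraction = 0, seed = 132)
  reads <- simulate_reads(g, spec)
  dbl <- strrep(g$seq$bases, 3)
  mism <- 0L; tot <- 0L
  for (r in reads) {
    start <- as.integer(sub(".*_\\+?(\\d+)$", "\\1", r$id))
    tmpl <- substr(dbl, start, start + nchar(r$bases) - 1L)
    a <- strsplit(r$bases, "")[[1]]; b <- strsplit(tmpl, "")[[1]]
    mism <- mism + sum(a != b); tot <- tot + length(a)
  }
  rate <- mism / tot
  expect_gte(tot, 9e5)
  expect_gte(rate, 0.008); expect_lte(rate, 0.012)
})

test_that("expected profile summaries mirror the injected truth", {
  prof <- error_profile(simple_substitution = 2, homopolymer_insertion = c(1, 1),
                        tandem_duplication = 1, seed = 141)
  s <- profile_expected_summary(prof)
  expect_identical(s$total_errors, 5L)
  expect_identical(s$by_category[["short_insertion"]], 1L)
  expect_identical(s$n_tandem_duplication, 1L)
})
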