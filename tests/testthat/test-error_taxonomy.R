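aln <- function(r, q) mitobench:::new_alignment_result(r, q, 0L)

test_that("event extraction groups gap runs and splits mismatch runs", {
  expect_identical(nrow(extract_events(aln("ACGT", "ACGT"))), 0L)

  # one 2-column deletion plus two separate substitutions
  ev <- extract_events(aln("AACCGGTT", "AA--GGAA"))
  expect_identical(ev$type, c("deletion", "substitution", "substitution"))
  expect_identical(ev$size, c(2L, 1L, 1L))
  expect_identical(ev$ref_pos, c(3L, 7L, 8L))
  expect_identical(ev$ref_bases[1], "CC")

  # insertion coordinates point at the reference base 5' of the event
  ev <- extract_events(aln("AC--GT", "ACTAGT"))
  expect_identical(ev$type, "insertion")
  expect_identical(ev$ref_pos, 2L)
  expect_identical(ev$qry_bases, "TA")

  expect_error(extract_events(aln("A-C", "A-C")), "gap-in-both")
})

test_that("homopolymer indels are recognized with multiplicity labels", {
  # deletion of one T adjacent to an 11-bp T run
  ref <- paste0("ACGCG", strrep("T", 11), "GCGCA")
  ev <- data.frame(type = "deletion", ref_pos = 6L, size = 1L,
                   ref_bases = "T", qry_bases = "")
  cl <- classify_events(ev, ref)
  expect_identical(cl$category, "homopolymer_deletion")
  expect_identical(cl$multiplicity, "single")
  expect_identical(cl$homopolymer_base, "T")

  # insertion of one A adjacent to a 5-bp A run
  ref <- paste0("GCGCG", strrep("A", 5), "CGCGC")
  ev <- data.frame(type = "insertion", ref_pos = 5L, size = 1L,
                   ref_bases = "", qry_bases = "A")
  expect_identical(classify_events(ev, ref)$category, "homopolymer_insertion")

  # multiplicity labels across sizes, either flank qualifies
  ref <- paste0("GC", strrep("T", 8), "AC")
  labels <- c("single", "double", "triple", "quadruple", "quintuple",
              "sextuple", "septuple", "gt7")
  for (s in 1:8) {
    ev <- data.frame(type = "insertion", ref_pos = 2L, size = s,
                     ref_bases = "", qry_bases = strrep("T", s))
    cl <- classify_events(ev, ref)
    expect_identical(cl$category, "homopolymer_insertion")
    expect_identical(cl$multiplicity, labels[s])
  }

  # mixed-base indels never count as homopolymer events
  ev <- data.frame(type = "insertion", ref_pos = 2L, size = 2L,
                   ref_bases = "", qry_bases = "TA")
  expect_identical(classify_events(ev, ref)$category, "short_insertion")
})

test_that("run-length threshold separates homopolymer from short indels", {
  # GG inserted next to a single G (run length 1 < 2)
  ref <- "ACTGTCA"
  ev <- data.frame(type = "insertion", ref_pos = 4L, size = 2L,
                   ref_bases = "", qry_bases = "GG")
  cl <- classify_events(ev, ref)
  expect_identical(cl$category, "short_insertion")
  expect_false(cl$tandem_duplication)
  # with min_run = 1 the same event is a homopolymer insertion
  expect_identical(classify_events(ev, ref, min_run = 1L)$category,
                   "homopolymer_insertion")
})

test_that("a duplicated motif insertion is flagged as a tandem duplication", {
  motif <- "AATGTTCTGGTGGG"  # the duplicated 14-mer reported for the 25x assembly
  lead <- "CCAGCTACGAGCAA"
  ref <- paste0(lead, motif, "CTACAATCCA")
  # inserted immediately after the identical reference substring
  ev <- data.frame(type = "insertion", ref_pos = nchar(lead) + 14L, size = 14L,
                   ref_bases = "", qry_bases = motif)
  cl <- classify_events(ev, ref)
  expect_identical(cl$category, "short_insertion")
  expect_true(cl$tandem_duplication)

  # and through the whole pipeline: qry carries two copies of the motif
  qry <- paste0(lead, motif, motif, "CTACAATCCA")
  a <- global_align(ref, qry)
  ev <- classify_events(left_normalize_events(extract_events(a), ref), ref)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$tandem_duplication)
  expect_identical(ev$size, 14L)
})

test_that("classification after left-normalization is idempotent", {
  sg <- small_genome(61)
  inj <- inject_errors(sg, error_profile(homopolymer_insertion = c(1, 1),
                                         homopolymer_deletion = 2,
                                         short_deletion = 2, seed = 62))
  a <- global_align(sg$genome$seq, inj$genome$seq)
  ev1 <- classify_events(left_normalize_events(extract_events(a), sg$genome$seq),
                         sg$genome$seq)
  ev2 <- classify_events(left_normalize_events(ev1, sg$genome$seq), sg$genome$seq)
  expect_identical(ev1, ev2)
})

test_that("summaries tally categories, multiplicities, and totals", {
  s <- summarize_events(mitobench:::empty_events())
  expect_identical(s$total_errors, 0L)
  expect_true(all(s$by_category == 0L))

  sg <- small_genome(63)
  prof <- error_profile(simple_substitution = 3, homopolymer_insertion = 2,
                        seed = 64)
  inj <- inject_errors(sg, prof)
  s <- summarize_events(inj$truth)
  expect_identical(s$total_errors, 5L)
  expect_identical(s$by_category[["simple_substitution"]], 3L)
  expect_identical(s$by_category[["homopolymer_insertion"]], 2L)
  expect_identical(sum(s$by_category), s$total_errors)
  expect_identical(s$by_multiplicity$n[
    s$by_multiplicity$category == "homopolymer_insertion" &
    s$by_multiplicity$multiplicity == "single"], 2L)
})

test_that("benchmark on an identical query reports a perfect assembly", {
  sg <- small_genome(65)
  rep <- benchmark(sg$genome, rotate(sg$genome, 777))
  expect_identical(rep$error_summary$total_errors, 0L)
  expect_equal(rep$p_distance, 0)
  expect_equal(rep$completeness, 1)
  expect_identical(rep$total_length, length(sg$genome))
})

test_that("benchmark recovers an injected profile through files and rotation", {
  sg <- small_genome(67)
  prof <- error_profile(simple_substitution = 2, single_insertion = 1,
                        short_deletion = 1, homopolymer_deletion = c(0, 1),
                        tandem_duplication = 1, seed = 68)
  inj <- inject_errors(sg, prof)
  ref_fa <- withr::local_tempfile(fileext = ".fasta")
  qry_fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sg$genome, ref_fa)
  write_fasta(rotate(inj$genome, 900), qry_fa)
  rep <- benchmark(ref_fa, qry_fa)
  expect_same_summary(rep, inj$truth)
  ev_tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- write_report(rep, events = ev_tsv)
  expect_identical(df$errors, 6L)
  ev <- read.delim(ev_tsv)
  expect_identical(nrow(ev), 6L)
  expect_identical(sum(ev$tandem_duplication), 1L)
})
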