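test_that("microsatellite scan finds embedded dinucleotide arrays", {
  s <- paste0(random_seq(80, seed = 1), strrep("AT", 4), random_seq(80, seed = 2))
  hits <- find_microsatellites(s, min_motif = 2)
  # flanking bases may chance-extend the array, shifting the phase to TA
  at <- hits[hits$motif %in% c("AT", "TA"), ]
  expect_identical(nrow(at), 1L)
  expect_gte(at$copies, 4)
  expect_identical(at$span, as.integer(round(at$copies * 2)))
})

test_that("motif primitivity suppresses homopolymers and rotated duplicates", {
  s <- paste0("GC", strrep("A", 6), "GC")
  expect_identical(nrow(find_microsatellites(s, min_motif = 2)), 0L)
  hits <- find_microsatellites(s, min_motif = 1)
  expect_identical(hits$motif, "A")
  expect_equal(hits$copies, 6)
  # an AT array must not be re-reported as ATAT (period 4)
  s <- paste0("GC", strrep("AT", 5), "GC")
  hits <- find_microsatellites(s, min_motif = 2, max_motif = 6)
  expect_identical(hits$motif, "AT")
  for (h in seq_len(nrow(hits))) {
    m <- hits$motif[h]
    expect_true(mitobench:::is_primitive(m))
  }
})

test_that("planted CR microsatellites are recovered with exact copy numbers", {
  for (seed in c(11, 12, 13)) {
    sg <- make_genome(genome_spec(length = 4000, seed = seed))
    man <- sg$manifest[sg$manifest$feature == "microsatellite", ]
    hits <- find_microsatellites(sg$genome$seq, min_motif = 2)
    for (i in seq_len(nrow(man))) {
      hit <- hits[hits$start == man$start[i], ]
      expect_identical(nrow(hit), 1L)
      expect_identical(hit$motif, man$motif[i])
      expect_equal(hit$copies, man$copies[i])
    }
  }
})

test_that("tandem repeat scan recovers printed CR arrays exactly", {
  # 17-mer repeated 5.4 times, as reported for one control region
  m17 <- "ACATATATGTATTATCA"
  s <- paste0(random_seq(150, seed = 21), mitobench:::array_string(m17, 5.4),
              "GG", random_seq(150, seed = 22))
  hits <- find_tandem_repeats(s)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$motif_len, 17L)
  # flank bases that chance-continue the array shift the phase, so the
  # consensus is pinned up to cyclic rotation
  expect_true(is_rotation(hits$consensus, m17))
  expect_lte(abs(hits$copies - 5.4), 0.1)

  # 23-mer repeated 2.3 times
  m23 <- "CAAATTAGAGTATAATAATTAAA"
  s <- paste0(random_seq(120, seed = 23), mitobench:::array_string(m23, 2.3),
              "CC", random_seq(120, seed = 24))
  hits <- find_tandem_repeats(s)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$motif_len, 23L)
  expect_lte(abs(hits$copies - 2.3), 0.1)
})

test_that("consensus is the per-column majority across copies", {
  m17 <- "ACATATATGTATTATCA"
  arr <- mitobench:::array_string(m17, 4.4)
  # mutate one base in the second copy; majority should restore the motif
  substr(arr, 20, 20) <- "G"
  s <- paste0(random_seq(100, seed = 31), arr, "GG", random_seq(100, seed = 32))
  hits <- find_tandem_repeats(s)
  expect_identical(nrow(hits), 1L)
  expect_true(is_rotation(hits$consensus, m17))
})

test_that("random sequence rarely triggers tandem-repeat hits", {
  n_hit <- 0L
  for (seed in 1:100) {
    s <- random_seq(800, seed = 4000 + seed)
    if (nrow(find_tandem_repeats(s)) > 0L) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit, 5L)
})

test_that("repeat hits are sorted, in range, and planted arrays dominate", {
  sg <- make_genome(genome_spec(seed = 41))
  cr <- sg$manifest[sg$manifest$feature == "CR", ]
  crseq <- substr(sg$genome$seq$bases, cr$start, cr$end)
  hits <- find_tandem_repeats(crseq)
  expect_true(all(diff(hits$start) >= 0))
  expect_true(all(hits$start + hits$span - 1L <= nchar(crseq)))
  man <- sg$manifest[sg$manifest$feature == "tandem_repeat", ]
  for (i in seq_len(nrow(man))) {
    period <- man$period[i]
    hit <- hits[hits$motif_len == period, ]
    expect_identical(nrow(hit), 1L)
    expect_lte(abs(hit$copies - man$copies[i]), 0.1)
  }
})
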