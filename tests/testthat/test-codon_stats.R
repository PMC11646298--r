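test_that("codon counting pools CDSs and drops partial codons with a warning", {
  t <- count_codons(list("CTACTA"))
  expect_identical(t$counts[["CTA"]], 2L)
  expect_identical(t$total, 2L)

  expect_warning(t <- count_codons(list("CTACT")), "trailing")
  expect_identical(t$counts[["CTA"]], 1L)

  # random CDS set vs a direct 3-mer stride oracle
  cds <- lapply(1:5, function(i) random_seq(3 * (20 + i), seed = 70 + i))
  t <- count_codons(cds)
  oracle <- table(unlist(lapply(cds, function(s) {
    n <- nchar(s) %/% 3
    substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  })))
  for (cod in names(oracle))
    expect_identical(t$counts[[cod]], as.integer(oracle[[cod]]))
  expect_identical(t$total, sum(vapply(cds, nchar, 0L)) %/% 3L)
  expect_error(count_codons(list()), "no coding")
})

test_that("RSCU reflects uniform and extreme usage and conserves family sums", {
  # two-codon family with equal counts -> both 1.0
  t <- count_codons(list(strrep("TTT", 10), strrep("TTC", 10)))
  r <- rscu(t)
  expect_equal(r$rscu[r$codon %in% c("TTT", "TTC")], c(1, 1))

  # all Leu usage on one codon -> that codon gets the family size
  t <- count_codons(list(strrep("CTA", 12)))
  r <- rscu(t)
  leu <- r[r$aa == "L", ]
  expect_equal(leu$rscu[leu$codon == "CTA"], nrow(leu))
  expect_equal(sum(leu$rscu[leu$codon != "CTA"]), 0)

  # conservation: sum of RSCU over each used family equals the family size
  for (seed in 1:10) {
    cds <- random_seq(3 * 400, seed = 90 + seed)
    r <- rscu(count_codons(list(cds)))
    for (a in setdiff(unique(r$aa), attr(r, "zero_families"))) {
      fam <- r[r$aa == a, ]
      expect_equal(sum(fam$rscu), nrow(fam))
    }
  }
})

test_that("the vertebrate mitochondrial code drives family definitions", {
  code <- Biostrings::getGeneticCode("2")
  t <- count_codons(list("CTACTA"))
  r <- rscu(t)
  # AGA/AGG are terminators in this code, so they sit outside RSCU families
  expect_false(any(c("AGA", "AGG") %in% r$codon))
  expect_identical(sort(unique(r$aa)), sort(unique(code[code != "*"])))
  r2 <- rscu(t, exclude_stop = FALSE)
  expect_true(all(c("AGA", "AGG") %in% r2$codon))
})

test_that("annotation summary reproduces the standard vertebrate layout", {
  anns <- read_annotations(system.file("extdata", "vertebrate_mito_gene_order.tsv",
                                       package = "mitobench"))
  s <- annotation_summary(anns, 16502)
  expect_identical(s$by_kind[["PCG"]], 13L)
  expect_identical(s$by_kind[["tRNA"]], 22L)
  expect_identical(s$by_kind[["rRNA"]], 2L)
  expect_identical(s$by_kind[["CR"]], 1L)
  expect_identical(as.integer(s$by_strand["tRNA", "-"]), 8L)
  expect_identical(as.integer(s$by_strand["PCG", "-"]), 1L)
  expect_identical(anns$name[anns$kind == "PCG" & anns$strand == "-"], "nad6")
  expect_setequal(s$cr_flanks, c("trnP", "trnF"))
  # strand counts partition the gene set
  expect_identical(sum(s$by_strand), nrow(anns))
})

test_that("annotation edge cases: empty table, origin wrap, bad coordinates", {
  s <- annotation_summary(data.frame(name = character(), kind = character(),
                                     strand = character(), start = integer(),
                                     end = integer()), 1000)
  expect_true(all(s$by_kind == 0L))

  wrap <- data.frame(name = "CR", kind = "CR", strand = "+",
                     start = 950L, end = 50L)
  s <- annotation_summary(wrap, 1000)
  expect_identical(s$genes$length, 101L)

  bad <- data.frame(name = "x", kind = "PCG", strand = "+",
                    start = 0L, end = 10L)
  expect_error(annotation_summary(bad, 1000), "coordinates")
})

test_that("GFF3 annotations are ingested through rtracklayer", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrM\ttest\tgene\t1\t900\t.\t+\t.\tID=nad1;Name=nad1",
    "chrM\ttest\ttRNA\t901\t970\t.\t-\t.\tID=trnQ;Name=trnQ",
    "chrM\ttest\trRNA\t971\t1900\t.\t+\t.\tID=rrnS;Name=rrnS"), f)
  anns <- read_annotations(f)
  expect_identical(anns$kind, c("PCG", "tRNA", "rRNA"))
  expect_identical(anns$strand, c("+", "-", "+"))
  s <- annotation_summary(anns, 2000)
  expect_identical(s$by_kind[["tRNA"]], 1L)
})
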