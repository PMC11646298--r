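ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

#' Count codons across coding sequences
#'
#' Pools codon counts over a set of protein-coding gene sequences. Genes on
#' the negative strand must be reverse-complemented upstream (coding-strand
#' input expected). A trailing partial codon is dropped with a warning.
#'
#' @param cds_list List of [nuc_seq] objects (or character scalars), one per
#'   CDS.
#' @param code_id Genetic code id as understood by
#'   [Biostrings::getGeneticCode()]; default `"2"`, the vertebrate
#'   mitochondrial code.
#' @return Object of class `codon_usage_table`: named integer vector
#'   `counts` over all 64 codons, `total` (codons read), and `code_id`.
#' @export
count_codons <- function(cds_list, code_id = "2") {
  if (inherits(cds_list, c("nuc_seq", "character")) && !is.list(cds_list))
    cds_list <- as.list(cds_list)
  if (length(cds_list) == 0L) stop("no coding sequences supplied")
  counts <- setNames(integer(64L), ALL_CODONS)
  dropped <- 0L
  for (s in cds_list) {
    b <- as_nuc_seq(s)$bases
    n <- nchar(b)
    rem <- n %% 3L
    if (rem != 0L) dropped <- dropped + rem
    ncod <- n %/% 3L
    if (ncod == 0L) next
    codons <- substring(b, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    codons <- codons[!grepl("N", codons, fixed = TRUE)]
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  if (dropped > 0L)
    warning(dropped, " trailing base(s) did not form complete codons and were dropped")
  structure(list(counts = counts, total = sum(counts), code_id = code_id),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> %d codons (genetic code %s)\n",
              x$total, x$code_id))
  top <- sort(x$counts[x$counts > 0L], decreasing = TRUE)
  show <- head(top, 5L)
  for (nm in names(show)) cat(sprintf("  %s %d\n", nm, show[[nm]]))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' For codon i in synonymous family F:
#' `RSCU_i = count_i * |F| / sum_{j in F} count_j`, i.e. the observed count
#' divided by the expectation under uniform usage within the family. Sums
#' over each used family equal the family size exactly. Stop codons are
#' excluded by default (families are amino-acid families); families with
#' zero total get RSCU 0 for all members and are flagged in the
#' `"zero_families"` attribute.
#'
#' @param t A `codon_usage_table` from [count_codons()].
#' @param exclude_stop Drop stop codons from families (default TRUE).
#' @return Data.frame with columns `codon`, `aa`, `count`, `rscu`, plus a
#'   `"zero_families"` attribute listing amino acids with no observed
#'   codons.
#' @export
rscu <- function(t, exclude_stop = TRUE) {
  stopifnot(inherits(t, "codon_usage_table"))
  code <- Biostrings::getGeneticCode(t$code_id)
  df <- data.frame(codon = names(code), aa = unname(code),
                   stringsAsFactors = FALSE)
  if (exclude_stop) df <- df[df$aa != "*", , drop = FALSE]
  df$count <- as.integer(t$counts[df$codon])
  df$rscu <- NA_real_
  zero <- character()
  for (a in unique(df$aa)) {
    idx <- df$aa == a
    fam_total <- sum(df$count[idx])
    if (fam_total == 0L) {
      df$rscu[idx] <- 0
      zero <- c(zero, a)
    } else {
      df$rscu[idx] <- df$count[idx] * sum(idx) / fam_total
    }
  }
  rownames(df) <- NULL
  attr(df, "zero_families") <- zero
  df
}

GENE_KINDS <- c("PCG", "tRNA", "rRNA", "CR")

#' Read a gene annotation table
#'
#' Accepts GFF3 (via rtracklayer; feature types `CDS`/`gene` map to PCG,
#' `tRNA`, `rRNA`, `D_loop`/`region` named like a control region to CR) or
#' a minimal tab-separated table with columns `name`, `kind`, `strand`,
#' `start`, `end` (1-based inclusive; a gene wrapping the circular origin
#' has `end < start`). MITOS-style tables use the same minimal columns.
#'
#' @param path Annotation file path.
#' @return Data.frame with columns `name`, `kind`, `strand`, `start`, `end`.
#' @export
read_annotations <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  if (grepl("^##gff", first) || grepl("\\.gff3?$", path)) {
    g <- rtracklayer::readGFF(path)
    type <- as.character(g$type)
    kind <- rep(NA_character_, length(type))
    kind[type %in% c("CDS", "gene", "mRNA")] <- "PCG"
    kind[type %in% c("tRNA")] <- "tRNA"
    kind[type %in% c("rRNA")] <- "rRNA"
    kind[type %in% c("D_loop", "D-loop", "region", "misc_feature")] <- "CR"
    name <- g$Name %||% g$ID
    if (is.null(name)) name <- paste0(type, "_", seq_along(type))
    df <- data.frame(name = as.character(name), kind = kind,
                     strand = as.character(g$strand),
                     start = as.integer(g$start), end = as.integer(g$end),
                     stringsAsFactors = FALSE)
    df <- df[!is.na(df$kind), , drop = FALSE]
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("name", "kind", "strand", "start", "end")
    if (!all(need %in% names(df)))
      stop("annotation table must have columns: ", paste(need, collapse = ", "))
    df <- df[, need]
  }
  bad <- setdiff(unique(df$kind), GENE_KINDS)
  if (length(bad)) stop("unknown gene kinds: ", paste(bad, collapse = ", "))
  df
}

gene_length <- function(start, end, genome_len) {
  ifelse(end >= start, end - start + 1L, genome_len - start + 1L + end)
}

#' Summarize a gene annotation
#'
#' Counts by kind and strand, per-gene lengths, and the genes flanking the
#' control region. Genes wrapping the circular origin (`end < start`) are
#' handled with modular arithmetic.
#'
#' @param anns Annotation data.frame (see [read_annotations()]).
#' @param genome_len Genome length in bases.
#' @return Object of class `annotation_summary`: `by_kind` (named counts),
#'   `by_strand` (kind x strand table), `genes` (with `length` column),
#'   `cr_flanks` (names of the genes adjacent to the CR), `genome_len`.
#' @export
annotation_summary <- function(anns, genome_len) {
  stopifnot(is.data.frame(anns), genome_len > 0)
  genome_len <- as.integer(genome_len)
  if (nrow(anns) > 0L) {
    if (any(anns$start < 1L | anns$start > genome_len |
            anns$end < 1L | anns$end > genome_len))
      stop("annotation coordinates outside [1, genome_len]")
    anns$length <- gene_length(anns$start, anns$end, genome_len)
  } else {
    anns$length <- integer()
  }
  by_kind <- setNames(integer(length(GENE_KINDS)), GENE_KINDS)
  tab <- table(anns$kind)
  by_kind[names(tab)] <- as.integer(tab)
  by_strand <- table(factor(anns$kind, GENE_KINDS),
                     factor(anns$strand, c("+", "-")))
  cr_flanks <- character()
  cr <- which(anns$kind == "CR")
  if (length(cr) >= 1L && nrow(anns) > 1L) {
    cr1 <- cr[1L]
    others <- setdiff(seq_len(nrow(anns)), cr)
    # circular distance from each gene's end to the CR start, and from the
    # CR end to each gene's start
    before <- (anns$start[cr1] - 1L - anns$end[others]) %% genome_len
    after <- (anns$start[others] - 1L - anns$end[cr1]) %% genome_len
    cr_flanks <- c(anns$name[others[which.min(before)]],
                   anns$name[others[which.min(after)]])
  }
  structure(list(by_kind = by_kind, by_strand = by_strand, genes = anns,
                 cr_flanks = cr_flanks, genome_len = genome_len),
            class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("<annotation_summary> %d features on %d bp\n",
              nrow(x$genes), x$genome_len))
  cat("  by kind: ", paste(names(x$by_kind), x$by_kind, sep = "=",
                           collapse = "  "), "\n", sep = "")
  if (length(x$cr_flanks))
    cat("  CR flanked by: ", paste(x$cr_flanks, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Canonical vertebrate mitochondrial gene order
#'
#' The standard vertebrate arrangement: 13 PCGs, 22 tRNAs, 2 rRNAs and one
#' control region between tRNA-Pro and tRNA-Phe; nad6 and 8 tRNAs (Gln,
#' Ala, Asn, Cys, Tyr, Ser-UCN, Glu, Pro) on the negative strand.
#' Coordinates are laid out contiguously with typical teleost gene lengths,
#' scaled so the control region ends at `genome_len`. The same table ships
#' as `extdata/vertebrate_mito_gene_order.tsv`.
#'
#' @param genome_len Genome length the coordinates should span
#'   (default 16502).
#' @return Annotation data.frame (`name`, `kind`, `strand`, `start`, `end`).
#' @export
standard_gene_order <- function(genome_len = 16502L) {
  g <- list(
    c("trnF", "tRNA", "+", 68), c("rrnS", "rRNA", "+", 950),
    c("trnV", "tRNA", "+", 72), c("rrnL", "rRNA", "+", 1667),
    c("trnL2", "tRNA", "+", 74), c("nad1", "PCG", "+", 975),
    c("trnI", "tRNA", "+", 71), c("trnQ", "tRNA", "-", 71),
    c("trnM", "tRNA", "+", 69), c("nad2", "PCG", "+", 1046),
    c("trnW", "tRNA", "+", 71), c("trnA", "tRNA", "-", 69),
    c("trnN", "tRNA", "-", 73), c("trnC", "tRNA", "-", 66),
    c("trnY", "tRNA", "-", 70), c("cox1", "PCG", "+", 1551),
    c("trnS2", "tRNA", "-", 71), c("trnD", "tRNA", "+", 69),
    c("cox2", "PCG", "+", 691), c("trnK", "tRNA", "+", 74),
    c("atp8", "PCG", "+", 168), c("atp6", "PCG", "+", 684),
    c("cox3", "PCG", "+", 786), c("trnG", "tRNA", "+", 69),
    c("nad3", "PCG", "+", 349), c("trnR", "tRNA", "+", 69),
    c("nad4l", "PCG", "+", 297), c("nad4", "PCG", "+", 1381),
    c("trnH", "tRNA", "+", 69), c("trnS1", "tRNA", "+", 68),
    c("trnL1", "tRNA", "+", 73), c("nad5", "PCG", "+", 1839),
    c("nad6", "PCG", "-", 522), c("trnE", "tRNA", "-", 69),
    c("cob", "PCG", "+", 1141), c("trnT", "tRNA", "+", 72),
    c("trnP", "tRNA", "-", 71))
  df <- data.frame(name = vapply(g, `[`, "", 1L),
                   kind = vapply(g, `[`, "", 2L),
                   strand = vapply(g, `[`, "", 3L),
                   len = as.integer(vapply(g, `[`, "", 4L)),
                   stringsAsFactors = FALSE)
  coding <- sum(df$len)
  cr_len <- genome_len - coding
  if (cr_len < 100L) stop("genome_len too short for the standard gene order")
  df$end <- cumsum(df$len)
  df$start <- df$end - df$len + 1L
  out <- rbind(df[, c("name", "kind", "strand", "start", "end")],
               data.frame(name = "CR", kind = "CR", strand = "+",
                          start = coding + 1L, end = genome_len,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
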