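#' Sequencing read with per-base qualities
#'
#' @param id Read identifier.
#' @param bases Character scalar.
#' @param quals Integer vector of Phred scores, one per base.
#' @return Object of class `read_record`.
#' @export
read_record <- function(id, bases, quals) {
  bases <- normalize_bases(bases, id = id)
  quals <- as.integer(quals)
  if (nchar(bases) != length(quals))
    stop("read '", id, "': ", length(quals), " qualities for ",
         nchar(bases), " bases")
  if (any(quals < 0L)) stop("read '", id, "': negative Phred score")
  structure(list(id = as.character(id), bases = bases, quals = quals),
            class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat(sprintf("<read_record> %s (%d bp, mean Q %.1f)\n",
              x$id, nchar(x$bases), mean_qscore(x)))
  invisible(x)
}

#' Read a FASTQ file
#'
#' Four-line records, Phred+33, gzip-transparent.
#'
#' @param path Path to FASTQ (optionally `.gz`).
#' @return List of [read_record] objects.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  if (length(set) == 0L) stop("no FASTQ records in '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  qstrings <- as.character(S4Vectors::mcols(set)$qualities)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- read_record(ids[i], as.character(set[[i]]),
                            utf8ToInt(qstrings[i]) - 33L)
  }
  out
}

#' Write reads to FASTQ
#'
#' @param reads List of [read_record] objects.
#' @param path Output path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (inherits(reads, "read_record")) reads <- list(reads)
  set <- Biostrings::DNAStringSet(vapply(reads, `[[`, "", "bases"))
  names(set) <- vapply(reads, `[[`, "", "id")
  quals <- Biostrings::BStringSet(vapply(
    reads, function(r) intToUtf8(pmin(r$quals, 93L) + 33L), ""))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Mean read quality score
#'
#' Read-level Q is the Phred score of the mean per-base error probability
#' (`-10 log10(mean(10^(-q/10)))`), the convention used by ONT tooling and
#' fastp -- not the arithmetic mean of Phred values.
#'
#' @param r A [read_record], or a numeric vector of Phred scores.
#' @return Numeric quality value.
#' @examples
#' mean_qscore(c(10, 20))  # ~12.60
#' @export
mean_qscore <- function(r) {
  q <- if (inherits(r, "read_record")) r$quals else as.numeric(r)
  if (length(q) == 0L) stop("cannot compute mean Q of an empty read")
  -10 * log10(mean(10^(-q / 10)))
}

#' Filter reads by quality and length
#'
#' Retains reads with mean Q at or above `min_q` and length inside the
#' (inclusive) window `[min_len, max_len]`. Order is preserved and the
#' operation is idempotent. Counts removed per criterion are attached as
#' the `"summary"` attribute (quality is tested first; length counts refer
#' to reads that passed the quality test).
#'
#' @param reads List of [read_record] objects.
#' @param min_q Minimum mean Q (default 6); `NULL` disables.
#' @param min_len,max_len Length window in bases; `NULL` disables a bound.
#' @return Filtered list with a `"summary"` attribute (data.frame with
#'   `n_input`, `removed_q`, `removed_short`, `removed_long`, `n_kept`).
#' @export
filter_reads <- function(reads, min_q = 6, min_len = NULL, max_len = NULL) {
  stopifnot(is.list(reads))
  if (!is.null(min_len) && !is.null(max_len) && min_len > max_len)
    stop("min_len exceeds max_len")
  if (!is.null(min_q) && min_q < 0) stop("min_q must be non-negative")
  n <- length(reads)
  lens <- vapply(reads, function(r) nchar(r$bases), 0L)
  keep_q <- if (is.null(min_q)) rep(TRUE, n)
            else vapply(reads, mean_qscore, 0) >= min_q
  short <- if (is.null(min_len)) rep(FALSE, n) else lens < min_len
  long <- if (is.null(max_len)) rep(FALSE, n) else lens > max_len
  keep <- keep_q & !short & !long
  out <- reads[keep]
  attr(out, "summary") <- data.frame(
    n_input = n,
    removed_q = sum(!keep_q),
    removed_short = sum(keep_q & short),
    removed_long = sum(keep_q & !short & long),
    n_kept = sum(keep))
  out
}

#' Subsampling specification
#'
#' Target fold-coverage of a genome of `genome_size` bases. The default
#' genome size of 1e9 matches the convention of quoting nanopore run depth
#' against an assumed 1-Gb fish nuclear genome.
#'
#' @param target_depth Fold coverage (e.g. 1, 3, 5).
#' @param genome_size Genome size in bases (default 1e9).
#' @param seed RNG seed for the shuffle (default 42).
#' @return Object of class `subsample_spec`.
#' @export
subsample_spec <- function(target_depth, genome_size = 1e9, seed = 42L) {
  stopifnot(target_depth > 0, genome_size > 0)
  structure(list(target_depth = target_depth, genome_size = genome_size,
                 seed = as.integer(seed)),
            class = "subsample_spec")
}

#' Subsample reads to a target depth
#'
#' Shuffle-then-accumulate semantics (as in Rasusa): reads are shuffled by a
#' seeded RNG and taken in shuffled order until the cumulative base count
#' reaches `target_depth * genome_size`. The same seed always yields the
#' same selection; removing the last selected read would drop the total
#' below target. If the input holds fewer bases than the target, all reads
#' are returned with a warning.
#'
#' @param reads Non-empty list of [read_record] objects.
#' @param spec A [subsample_spec].
#' @return Subset of `reads` (in shuffled order), with attribute
#'   `"total_bases"`.
#' @export
subsample_to_depth <- function(reads, spec) {
  stopifnot(inherits(spec, "subsample_spec"))
  if (length(reads) == 0L) stop("cannot subsample an empty read set")
  target <- spec$target_depth * spec$genome_size
  lens <- vapply(reads, function(r) nchar(r$bases), 0L)
  if (sum(lens) < target) {
    warning(sprintf("input holds %.0f bases < target %.0f; returning all reads",
                    sum(lens), target))
    out <- reads
    attr(out, "total_bases") <- sum(lens)
    return(out)
  }
  ord <- local_seed(spec$seed, sample.int(length(reads)))
  cum <- cumsum(lens[ord])
  k <- which(cum >= target)[1L]
  out <- reads[ord[seq_len(k)]]
  attr(out, "total_bases") <- cum[k]
  out
}

#' Summarize a read set
#'
#' @param reads List of [read_record] objects.
#' @return One-row data.frame: read count, total bases, length range,
#'   mean length, mean read Q.
#' @export
read_set_summary <- function(reads) {
  lens <- vapply(reads, function(r) nchar(r$bases), 0L)
  data.frame(n_reads = length(reads), total_bases = sum(lens),
             min_len = if (length(lens)) min(lens) else NA_integer_,
             max_len = if (length(lens)) max(lens) else NA_integer_,
             mean_len = if (length(lens)) mean(lens) else NA_real_,
             mean_q = if (length(reads)) mean(vapply(reads, mean_qscore, 0)) else NA_real_)
}
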