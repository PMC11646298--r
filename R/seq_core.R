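IUPAC_EXTRA <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Nucleotide sequence
#'
#' Lightweight container for a named DNA sequence over the alphabet
#' `{A,C,G,T,N}`. Input is normalized: lowercase is uppercased and `U`
#' becomes `T`. IUPAC ambiguity codes other than `N` are converted to `N`
#' (assemblies are normally N-free but raw reads need not be); any other
#' character is an error.
#'
#' @param bases Character scalar, the sequence.
#' @param id Character scalar label.
#' @return An object of class `nuc_seq` with fields `id` and `bases`.
#' @examples
#' s <- nuc_seq("acgtu", id = "x")
#' s$bases  # "ACGTT"
#' @export
nuc_seq <- function(bases, id = "seq") {
  stopifnot(is.character(bases), length(bases) == 1L, !is.na(bases))
  bases <- normalize_bases(bases, id = id)
  if (nchar(bases) < 1L) stop("sequence '", id, "' is empty")
  structure(list(id = as.character(id), bases = bases), class = "nuc_seq")
}

normalize_bases <- function(bases, id = "seq") {
  bases <- toupper(bases)
  bases <- chartr("U", "T", bases)
  extra <- paste(IUPAC_EXTRA, collapse = "")
  bases <- chartr(extra, strrep("N", nchar(extra)), bases)
  bad <- gsub("[ACGTN]", "", bases)
  if (nchar(bad) > 0L) {
    stop("record '", id, "' contains non-IUPAC characters: ",
         paste(unique(chars(bad)), collapse = ", "))
  }
  bases
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- nchar(x$bases)
  cat(sprintf("<nuc_seq> %s (%d bp)\n", x$id, n))
  cat(substr(x$bases, 1L, 60L), if (n > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.nuc_seq <- function(x) nchar(x$bases)

as_nuc_seq <- function(x, id = "seq") {
  if (inherits(x, "nuc_seq")) return(x)
  if (inherits(x, "circular_genome")) return(x$seq)
  nuc_seq(as.character(x), id = id)
}

#' Circular genome
#'
#' A [nuc_seq] plus a circularity flag. Rotation is only defined for
#' circular sequences.
#'
#' @param seq A [nuc_seq] (or character scalar, coerced).
#' @param circular Logical flag.
#' @param id Label used when coercing a character `seq`.
#' @return An object of class `circular_genome` with fields `seq` and
#'   `circular`.
#' @export
circular_genome <- function(seq, circular = TRUE, id = "genome") {
  seq <- as_nuc_seq(seq, id = id)
  stopifnot(is.logical(circular), length(circular) == 1L, !is.na(circular))
  structure(list(seq = seq, circular = circular), class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s (%d bp, %s)\n", x$seq$id,
              nchar(x$seq$bases), if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.circular_genome <- function(x) nchar(x$seq$bases)

#' Read a FASTA file
#'
#' Multi-record, wrapped or unwrapped, gzip-transparent (via Biostrings).
#' Bases are normalized as in [nuc_seq()].
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @return List of [nuc_seq] objects, input order preserved.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    b <- as.character(set[[i]])
    if (nchar(b) == 0L) stop("record '", ids[i], "' has no sequence")
    out[[i]] <- nuc_seq(b, id = ids[i])
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A [nuc_seq], [circular_genome], or list of either.
#' @param path Output path (`.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, c("nuc_seq", "circular_genome"))) seqs <- list(seqs)
  seqs <- lapply(seqs, as_nuc_seq)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "bases"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. An involution:
#' `revcomp(revcomp(x))` equals `x`.
#'
#' @param s A [nuc_seq], [circular_genome] or character scalar.
#' @return Same class as the input (character in, character out).
#' @export
revcomp <- function(s) {
  if (inherits(s, "circular_genome")) {
    g <- s
    g$seq <- revcomp(g$seq)
    return(g)
  }
  if (inherits(s, "nuc_seq")) {
    s$bases <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s$bases)))
    return(s)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(normalize_bases(s))))
}

#' Rotate a circular genome
#'
#' Moves the sequence origin: the result starts at base `offset + 1` of the
#' input. Offsets are reduced modulo the length, so
#' `rotate(rotate(g, k), len - k)` restores `g`.
#'
#' @param g A [circular_genome]; rotating a linear sequence is an error.
#' @param offset Integer rotation.
#' @return Rotated [circular_genome].
#' @export
rotate <- function(g, offset) {
  stopifnot(inherits(g, "circular_genome"))
  if (!g$circular) stop("cannot rotate a non-circular sequence")
  n <- nchar(g$seq$bases)
  offset <- as.integer(offset %% n)
  if (offset == 0L) return(g)
  g$seq$bases <- paste0(substr(g$seq$bases, offset + 1L, n),
                        substr(g$seq$bases, 1L, offset))
  g
}

#' Nucleotide usage of a sequence
#'
#' Percentages of A, T, C and G over non-N positions, plus the combined
#' A+T percentage, as reported for whole mitogenomes, rRNA genes and
#' control regions.
#'
#' @param s A [nuc_seq], [circular_genome] or character scalar.
#' @return A [composition_table].
#' @export
nucleotide_usage <- function(s) {
  s <- as_nuc_seq(s)
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(s$bases))
  counts <- f[c("A", "T", "C", "G")]
  denom <- sum(counts)
  if (denom == 0L) stop("sequence '", s$id, "' has no A/C/G/T bases")
  pct <- 100 * counts / denom
  composition_table(a_pct = pct[["A"]], t_pct = pct[["T"]],
                    c_pct = pct[["C"]], g_pct = pct[["G"]],
                    length = nchar(s$bases))
}

#' Composition table
#'
#' Holds base percentages for a sequence; `at_pct` is always derived as
#' `a_pct + t_pct`, the arithmetic used in published nucleotide-usage
#' tables. Percentages must sum to 100 within a rounding tolerance of 0.02
#' (so tables rounded to 2 decimals are accepted).
#'
#' @param a_pct,t_pct,c_pct,g_pct Percentages of each base.
#' @param length Sequence length in bases.
#' @return Object of class `composition_table` with fields `a_pct`, `t_pct`,
#'   `c_pct`, `g_pct`, `at_pct`, `length`.
#' @export
composition_table <- function(a_pct, t_pct, c_pct, g_pct, length) {
  tot <- a_pct + t_pct + c_pct + g_pct
  if (abs(tot - 100) > 0.02)
    stop(sprintf("base percentages sum to %.4f, not 100 (tolerance 0.02)", tot))
  if (length <= 0) stop("length must be positive")
  structure(list(a_pct = a_pct, t_pct = t_pct, c_pct = c_pct, g_pct = g_pct,
                 at_pct = a_pct + t_pct, length = as.integer(length)),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("A%% %.2f  T%% %.2f  C%% %.2f  G%% %.2f  A+T%% %.2f  length %d\n",
              x$a_pct, x$t_pct, x$c_pct, x$g_pct, x$at_pct, x$length))
  invisible(x)
}

#' @export
as.data.frame.composition_table <- function(x, ...) {
  data.frame(a_pct = round(x$a_pct, 2), t_pct = round(x$t_pct, 2),
             c_pct = round(x$c_pct, 2), g_pct = round(x$g_pct, 2),
             at_pct = round(x$at_pct, 2), length = x$length)
}
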