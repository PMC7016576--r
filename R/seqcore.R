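#' Nucleotide sequence with topology
#'
#' The universal currency of the package: an uppercase DNA string over
#' `{A,C,G,T,N}` together with an identifier and a topology flag. Genomes
#' and reads are linear; plasmids and cloning vectors are circular.
#' Topology is fixed at construction.
#'
#' @param seq Character scalar; case is folded to upper.
#' @param id Identifier; defaults to `"seq"`.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `dna_seq` (a list with elements `id`, `seq`,
#'   `topology`).
#' @examples
#' s <- dna_seq("ggatcc", id = "x")
#' gc_content(s)
#' @export
dna_seq <- function(seq, id = "seq", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  bad <- regmatches(seq, regexpr("[^ACGTN]", seq))
  if (length(bad) && nzchar(bad)) {
    pos <- regexpr("[^ACGTN]", seq)
    stop(sprintf("invalid character '%s' at position %d in sequence '%s'",
                 bad, pos, id), call. = FALSE)
  }
  structure(list(id = as.character(id), seq = seq, topology = topology),
            class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  n <- nchar(x$seq)
  head <- substr(x$seq, 1, 60)
  cat(sprintf("<dna_seq> %s  %d bp  %s\n  %s%s\n", x$id, n, x$topology,
              head, if (n > 60) "..." else ""))
  invisible(x)
}

#' @export
length.dna_seq <- function(x) nchar(x$seq)

# Coerce a character scalar or dna_seq to dna_seq.
as_dna_seq <- function(x, id = "seq", topology = "linear") {
  if (inherits(x, "dna_seq")) x else dna_seq(x, id = id, topology = topology)
}

seq_chr <- function(x) if (inherits(x, "dna_seq")) x$seq else x

#' GC content of a sequence
#'
#' Percentage of informative bases that are G or C. `N` bases are excluded
#' from both the numerator and the denominator.
#'
#' @param s A [dna_seq] or character scalar.
#' @return Percent in `[0, 100]`.
#' @export
gc_content <- function(s) {
  x <- seq_chr(as_dna_seq(s))
  counts <- base_counts(x)
  informative <- sum(counts[c("A", "C", "G", "T")])
  if (informative == 0L) stop("no informative bases", call. = FALSE)
  100 * sum(counts[c("G", "C")]) / informative
}

#' AT content of a sequence
#'
#' Complement of [gc_content()] on informative bases.
#' @inheritParams gc_content
#' @return Percent in `[0, 100]`.
#' @export
at_content <- function(s) 100 - gc_content(s)

base_counts <- function(x) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  tab <- table(factor(v, levels = c("A", "C", "G", "T", "N")))
  setNames(as.integer(tab), names(tab))
}

#' Reverse complement
#'
#' @param s A [dna_seq] or character scalar. The complement of `N` is `N`.
#' @return Same type as the input (topology and id preserved for `dna_seq`).
#' @export
reverse_complement <- function(s) {
  was_chr <- !inherits(s, "dna_seq")
  d <- as_dna_seq(s)
  rc <- revcomp_chr(d$seq)
  if (was_chr) rc else dna_seq(rc, id = d$id, topology = d$topology)
}

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# ---- FASTA / FASTQ I/O (Biostrings-backed) --------------------------------

#' Read a FASTA file
#'
#' Multi-line records are accepted and sequences are folded to upper case.
#' The full header line (id plus any description) is kept as the id.
#'
#' @param path File path.
#' @param topology Topology to stamp on every record.
#' @return List of [dna_seq].
#' @export
read_fasta <- function(path, topology = "linear") {
  set <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop(sprintf(
                    "malformed FASTA '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  lapply(seq_along(set), function(i) {
    dna_seq(toupper(as.character(set[[i]])), id = names(set)[i],
            topology = topology)
  })
}

#' Write sequences to FASTA
#'
#' Lines are wrapped at 70 columns.
#' @param seqs List of [dna_seq] (or character vector, optionally named).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    seqs <- Map(dna_seq, seqs, ids)
  }
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$seq, ""))
  names(set) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Qualities (Sanger Phred+33) are parsed and preserved as an attribute but
#' are not used by the identification pipeline.
#'
#' @inheritParams read_fasta
#' @return List of [dna_seq]; each element carries a `qual` attribute.
#' @export
read_fastq <- function(path, topology = "linear") {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': %d lines (not a multiple of 4)",
                 path, length(lines)), call. = FALSE)
  n <- length(lines) / 4L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    base <- (i - 1L) * 4L
    hdr <- lines[base + 1L]
    if (!startsWith(hdr, "@"))
      stop(sprintf("malformed FASTQ '%s' at line %d: header must start with '@'",
                   path, base + 1L), call. = FALSE)
    sq <- lines[base + 2L]; ql <- lines[base + 4L]
    if (nchar(sq) != nchar(ql))
      stop(sprintf("malformed FASTQ '%s' at line %d: sequence and quality lengths differ",
                   path, base + 4L), call. = FALSE)
    d <- dna_seq(sq, id = sub("^@", "", hdr), topology = topology)
    attr(d, "qual") <- ql
    out[[i]] <- d
  }
  out
}

#' Write sequences to FASTQ (Sanger Phred+33)
#'
#' Records without a `qual` attribute get a constant quality of `I` (Q40).
#' @inheritParams write_fasta
#' @export
write_fastq <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    q <- attr(s, "qual")
    if (is.null(q)) q <- strrep("I", nchar(s$seq))
    writeLines(c(paste0("@", s$id), s$seq, "+", q), con)
  }
  invisible(path)
}
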