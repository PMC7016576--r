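STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_split <- function(chr) {
  n <- (nchar(chr) %/% 3) * 3
  if (n == 0) return(character())
  substring(chr, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Translate a nucleotide sequence
#'
#' Uses the bacterial/archaeal genetic code (NCBI translation table 11)
#' by default. A terminal stop codon is trimmed; an internal stop is an
#' error. With `start_codon_rule`, an initial GTG/TTG/ATG is rendered as
#' M (table 11 initiation behaviour).
#'
#' @param s [dna_seq] or character; length must be divisible by 3.
#' @param table Genetic code id passed to
#'   [Biostrings::getGeneticCode()].
#' @param start_codon_rule Render an alternative initiation codon as M.
#' @return Amino-acid string.
#' @export
translate_dna <- function(s, table = "11", start_codon_rule = FALSE) {
  chr <- seq_chr(as_dna_seq(s))
  if (nchar(chr) %% 3 != 0)
    stop("sequence length not divisible by 3", call. = FALSE)
  code <- Biostrings::getGeneticCode(table)
  codons <- codon_split(chr)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  if (length(aa) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]; codons <- codons[-length(codons)]
  }
  if (any(aa == "*"))
    stop(sprintf("internal stop codon at codon %d", which(aa == "*")[1]),
         call. = FALSE)
  if (start_codon_rule && length(aa) &&
      codons[1] %in% c("ATG", "GTG", "TTG")) aa[1] <- "M"
  paste(aa, collapse = "")
}

orf_frame_scan <- function(chr, frame, min_len, start_codons,
                           allow_truncated) {
  codons <- codon_split(substr(chr, frame, nchar(chr)))
  nc <- length(codons)
  if (nc == 0) return(NULL)
  is_stop <- codons %in% STOP_CODONS
  is_start <- codons %in% start_codons
  stops <- which(is_stop)
  out <- NULL
  region_start <- 1L  # first codon index after the previous stop
  for (st in stops) {
    cand <- which(is_start[seq_len(nc)])
    cand <- cand[cand >= region_start & cand < st]
    if (length(cand)) {
      a <- cand[1]
      out <- rbind(out, data.frame(codon_start = a, codon_end = st,
                                   truncated = "none",
                                   stringsAsFactors = FALSE))
    } else if (allow_truncated && region_start == 1L && frame <= 3 &&
               st > region_start && region_start == 1L) {
      # open at the 5' end: reading runs in from the sequence edge
      out <- rbind(out, data.frame(codon_start = region_start,
                                   codon_end = st, truncated = "5prime",
                                   stringsAsFactors = FALSE))
    }
    region_start <- st + 1L
  }
  if (allow_truncated && region_start <= nc) {
    cand <- which(is_start); cand <- cand[cand >= region_start]
    if (length(cand)) {
      out <- rbind(out, data.frame(codon_start = cand[1], codon_end = nc,
                                   truncated = "3prime",
                                   stringsAsFactors = FALSE))
    } else if (region_start == 1L) {
      out <- rbind(out, data.frame(codon_start = 1L, codon_end = nc,
                                   truncated = "both",
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(NULL)
  out$frame <- frame
  out
}

#' Six-frame ORF prediction
#'
#' A complete ORF runs from the first start codon after the previous
#' in-frame stop to the next in-frame stop (stop included in the length).
#' With `allow_truncated`, open reading runs hitting a sequence end are
#' reported with a `truncated` flag (`5prime`, `3prime` or `both`). ORFs
#' shorter than `min_len` nucleotides are dropped. Coordinates are
#' 1-based inclusive on the forward strand; `frame` is 1-3 on the ORF's
#' own strand.
#'
#' @param s Linear [dna_seq].
#' @param min_len Minimum ORF length in nt, stop codon included
#'   (default 150).
#' @param start_codons Set of start codons; `alt_starts` adds GTG and
#'   TTG.
#' @param allow_truncated Report edge-truncated open reading runs.
#' @param alt_starts Convenience flag adding GTG/TTG to the start set.
#' @return data.frame of ORF records: `seq_id`, `start`, `end`, `strand`,
#'   `frame`, `length_nt`, `truncated`, `protein`.
#' @export
find_orfs <- function(s, min_len = 150L, start_codons = "ATG",
                      allow_truncated = TRUE, alt_starts = FALSE) {
  s <- as_dna_seq(s)
  stopifnot(min_len >= 3)
  if (alt_starts) start_codons <- union(start_codons, c("GTG", "TTG"))
  L <- nchar(s$seq)
  rows <- NULL
  for (strand in c("+", "-")) {
    chr <- if (strand == "+") s$seq else revcomp_chr(s$seq)
    for (frame in 1:3) {
      sc <- orf_frame_scan(chr, frame, min_len, start_codons,
                           allow_truncated)
      if (is.null(sc)) next
      for (i in seq_len(nrow(sc))) {
        nt_start <- frame + 3L * (sc$codon_start[i] - 1L)  # on chr
        nt_end <- frame + 3L * sc$codon_end[i] - 1L
        len <- nt_end - nt_start + 1L
        if (len < min_len) next
        if (strand == "+") { a <- nt_start; b <- nt_end }
        else { a <- L - nt_end + 1L; b <- L - nt_start + 1L }
        coding <- substr(chr, nt_start,
                         if (sc$truncated[i] %in% c("none", "5prime"))
                           nt_end - 3L else nt_end)
        prot <- tryCatch(
          translate_dna(coding, start_codon_rule = TRUE),
          error = function(e) NA_character_)
        rows <- rbind(rows, data.frame(
          seq_id = s$id, start = a, end = b, strand = strand,
          frame = frame, length_nt = len, truncated = sc$truncated[i],
          protein = prot, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(rows))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), length_nt = integer(),
                      truncated = character(), protein = character(),
                      stringsAsFactors = FALSE))
  rows <- rows[order(rows$start, rows$strand, rows$frame), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Annotation hit filter
#'
#' Post-hoc filter applied to externally produced tabular homology hits:
#' keep rows with `evalue < max_evalue` and
#' `identity_pct > min_identity_pct` (both strict).
#'
#' @param max_evalue Strict upper bound on the E-value (default 1e-30).
#' @param min_identity_pct Strict lower bound on percent identity
#'   (default 30).
#' @return A `hit_filter`.
#' @export
hit_filter <- function(max_evalue = 1e-30, min_identity_pct = 30) {
  stopifnot(max_evalue > 0, min_identity_pct >= 0, min_identity_pct <= 100)
  structure(list(max_evalue = max_evalue,
                 min_identity_pct = min_identity_pct),
            class = "hit_filter")
}

#' Filter a table of homology hits
#'
#' @param hits A data.frame or TSV path with columns `query`, `subject`,
#'   `evalue`, `identity_pct` (extra columns such as `description` are
#'   kept).
#' @param f A [hit_filter()].
#' @return The kept rows.
#' @export
filter_hits <- function(hits, f = hit_filter()) {
  if (is.character(hits)) {
    hits <- read.table(hits, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, comment.char = "#",
                       colClasses = NA)
  }
  need <- c("query", "subject", "evalue", "identity_pct")
  if (!all(need %in% names(hits)))
    stop("hit table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ev <- suppressWarnings(as.numeric(hits$evalue))
  idp <- suppressWarnings(as.numeric(hits$identity_pct))
  bad <- which(is.na(ev) | is.na(idp))
  if (length(bad))
    stop(sprintf("malformed hit table row %d: non-numeric evalue or identity",
                 bad[1]), call. = FALSE)
  hits[ev < f$max_evalue & idp > f$min_identity_pct, , drop = FALSE]
}

#' Write ORF records to GFF3
#' @param orfs data.frame from [find_orfs()].
#' @param path Output path.
#' @export
write_orf_gff3 <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(orfs))) {
    r <- orfs[i, ]
    writeLines(sprintf(
      "%s\tclonetag\tORF\t%d\t%d\t.\t%s\t.\tID=orf%d;frame=%d;truncated=%s",
      r$seq_id, r$start, r$end, r$strand, i, r$frame, r$truncated), con)
  }
  invisible(path)
}

#' Write translated ORFs to protein FASTA
#' @param orfs data.frame from [find_orfs()].
#' @param path Output path.
#' @export
write_orf_proteins <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(orfs))) {
    r <- orfs[i, ]
    if (is.na(r$protein)) next
    writeLines(c(sprintf(">%s_orf%d %d-%d(%s) %s", r$seq_id, i, r$start,
                         r$end, r$strand, r$truncated),
                 r$protein), con)
  }
  invisible(path)
}
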