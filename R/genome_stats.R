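#' Download a nucleotide record from GenBank as FASTA
#'
#' Fetches the sequence for an accession via the NCBI E-utilities efetch
#' endpoint. Requires network access.
#'
#' @param accession GenBank accession (e.g. a complete-genome accession).
#' @param dest Destination FASTA path.
#' @param timeout Download timeout in seconds.
#' @return `dest`, invisibly.
#' @export
fetch_genbank_fasta <- function(accession, dest,
                                timeout = 300) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", accession,
                "&rettype=fasta&retmode=text")
  old <- options(timeout = timeout)
  on.exit(options(old))
  status <- tryCatch(download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) ||
      file.info(dest)$size < 100)
    stop(sprintf("could not download accession %s from NCBI", accession),
         call. = FALSE)
  invisible(dest)
}

#' Total length and GC content of a genome FASTA
#'
#' Sums record lengths and computes the GC percent over all informative
#' bases of all records (Ns excluded).
#'
#' @param path FASTA path.
#' @return List with `length_bp` and `gc_pct`.
#' @export
genome_stats <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  freq <- colSums(Biostrings::alphabetFrequency(set))
  informative <- sum(freq[c("A", "C", "G", "T")])
  if (informative == 0) stop("no informative bases", call. = FALSE)
  list(length_bp = sum(Biostrings::width(set)),
       gc_pct = 100 * sum(freq[c("G", "C")]) / informative)
}
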