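#' Restriction enzyme
#'
#' A named recognition site in IUPAC code with the cut offset on the top
#' strand: `cut_offset` is the 0-based index, within the site, of the first
#' base 3' of the cut. Sau3AI (`^GATC`) has offset 0; BamHI (`G^GATCC`)
#' offset 1.
#'
#' @param name Enzyme name.
#' @param site Recognition site (IUPAC codes, length >= 4).
#' @param cut_offset Integer in `[0, nchar(site)]`.
#' @return An `enzyme` object.
#' @export
enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  stopifnot(nchar(site) >= 4, cut_offset >= 0, cut_offset <= nchar(site))
  if (grepl("[^ACGTRYSWKMBDHVN]", site))
    stop("site contains non-IUPAC characters", call. = FALSE)
  structure(list(name = name, site = site, cut_offset = as.integer(cut_offset)),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s  %s^%s\n", x$name,
              substr(x$site, 1, x$cut_offset),
              substr(x$site, x$cut_offset + 1, nchar(x$site))))
  invisible(x)
}

#' Default enzyme catalogue
#'
#' The enzymes used in small-insert library work with a pUC118-like vector:
#' Sau3AI for partial digestion, BamHI for the cloning site, and the
#' linearization candidates HindIII, XbaI and EcoRI.
#' @return List of [enzyme] objects.
#' @export
default_enzymes <- function() {
  list(enzyme("Sau3AI",  "GATC",   0L),
       enzyme("BamHI",   "GGATCC", 1L),
       enzyme("HindIII", "AAGCTT", 1L),
       enzyme("XbaI",    "TCTAGA", 1L),
       enzyme("EcoRI",   "GAATTC", 1L))
}

#' Read an enzyme catalogue from TSV
#'
#' Columns: `name`, `site`, `cut_offset`.
#' @param path File path.
#' @return List of [enzyme] objects.
#' @export
read_enzyme_catalogue <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  stopifnot(all(c("name", "site", "cut_offset") %in% names(df)))
  lapply(seq_len(nrow(df)),
         function(i) enzyme(df$name[i], df$site[i], df$cut_offset[i]))
}

iupac_revcomp <- function(site) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", site)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# 0-based start positions of IUPAC site matches on a plain string
iupac_match_starts <- function(site, subject) {
  if (nchar(subject) < nchar(site)) return(integer())
  m <- Biostrings::matchPattern(site, Biostrings::DNAString(subject),
                                fixed = "subject")
  IRanges::start(m) - 1L
}

#' Scan a sequence for the cut positions of an enzyme
#'
#' Circular sequences are scanned across the origin (a site may span the
#' end/start junction) and cut positions are reported modulo the length.
#' Palindromic sites are scanned once on the top strand; non-palindromic
#' sites are scanned on both strands and bottom-strand cuts are mapped to
#' top-strand coordinates.
#'
#' @param s A [dna_seq].
#' @param e An [enzyme].
#' @return A `cut_map`: list with `enzyme`, sorted 0-based `positions`,
#'   `topology` and `seq_length`.
#' @export
find_sites <- function(s, e) {
  s <- as_dna_seq(s)
  L <- nchar(s$seq)
  k <- nchar(e$site)
  subject <- if (s$topology == "circular" && L >= k) {
    paste0(s$seq, substr(s$seq, 1, k - 1))
  } else s$seq
  starts <- iupac_match_starts(e$site, subject)
  cuts <- starts + e$cut_offset
  rc_site <- iupac_revcomp(e$site)
  if (rc_site != e$site) {
    starts2 <- iupac_match_starts(rc_site, subject)
    cuts <- c(cuts, starts2 + (k - e$cut_offset))
  }
  if (s$topology == "circular") cuts <- cuts %% L
  cuts <- sort(unique(cuts[cuts >= 0 & cuts <= L]))
  structure(list(enzyme = e, positions = as.integer(cuts),
                 topology = s$topology, seq_length = L),
            class = "cut_map")
}

#' @export
print.cut_map <- function(x, ...) {
  cat(sprintf("<cut_map> %s on %s %d bp: %d cut(s) [%s]\n",
              x$enzyme$name, x$topology, x$seq_length, length(x$positions),
              paste(utils::head(x$positions, 10), collapse = ", ")))
  invisible(x)
}

#' Enzymes that cut a circular plasmid exactly once
#'
#' @param plasmid Circular [dna_seq].
#' @param catalogue List of [enzyme] objects.
#' @return Sub-list of `catalogue` with exactly one cut each.
#' @export
single_cutters <- function(plasmid, catalogue = default_enzymes()) {
  plasmid <- as_dna_seq(plasmid)
  if (plasmid$topology != "circular")
    stop("single-cutter selection is defined on circular plasmids",
         call. = FALSE)
  keep <- vapply(catalogue,
                 function(e) length(find_sites(plasmid, e)$positions) == 1L,
                 logical(1))
  catalogue[keep]
}

#' Minimal enzyme panel linearizing every plasmid
#'
#' Chooses a minimum-cardinality set of enzymes such that every plasmid is
#' cut exactly once by at least one panel member (so all plasmids can be
#' linearized for pooled long-read sequencing), plus a per-plasmid enzyme
#' assignment. The search is exact (subsets enumerated by increasing size,
#' in catalogue order) for catalogues of up to 20 enzymes, and greedy set
#' cover with a deterministic tie-break (most plasmids covered, then
#' catalogue order) above that.
#'
#' @param plasmids List of circular [dna_seq].
#' @param catalogue List of [enzyme] objects.
#' @return List with `panel` (list of enzymes) and `assignment` (named
#'   character vector, plasmid id -> enzyme name).
#' @export
min_enzyme_panel <- function(plasmids, catalogue = default_enzymes()) {
  ids <- vapply(plasmids, function(p) p$id, "")
  covers <- lapply(catalogue, function(e) {
    which(vapply(plasmids,
                 function(p) length(find_sites(p, e)$positions) == 1L,
                 logical(1)))
  })
  covered_any <- sort(unique(unlist(covers)))
  if (length(covered_any) < length(plasmids)) {
    missing <- setdiff(seq_along(plasmids), covered_any)
    stop("no single-cutter in the catalogue for plasmid(s): ",
         paste(ids[missing], collapse = ", "), call. = FALSE)
  }
  n <- length(plasmids)
  chosen <- NULL
  if (length(catalogue) <= 20L) {
    for (sz in seq_along(catalogue)) {
      for (idx in utils::combn(length(catalogue), sz, simplify = FALSE)) {
        if (length(unique(unlist(covers[idx]))) == n) { chosen <- idx; break }
      }
      if (!is.null(chosen)) break
    }
  } else {
    uncovered <- seq_len(n)
    chosen <- integer()
    while (length(uncovered)) {
      gain <- vapply(covers, function(cv) length(intersect(cv, uncovered)), 0L)
      pick <- which.max(gain)  # ties: first in catalogue order
      chosen <- c(chosen, pick)
      uncovered <- setdiff(uncovered, covers[[pick]])
    }
  }
  assignment <- character(n)
  for (i in seq_len(n)) {
    for (j in chosen) {
      if (i %in% covers[[j]]) { assignment[i] <- catalogue[[j]]$name; break }
    }
  }
  list(panel = catalogue[chosen], assignment = setNames(assignment, ids))
}

#' Linearize a circular plasmid at its unique cut site
#'
#' Returns the rotation of the circle beginning at the cut position; length
#' is preserved.
#'
#' @param plasmid Circular [dna_seq] with exactly one cut for `e`.
#' @param e An [enzyme].
#' @return Linear [dna_seq].
#' @export
linearize <- function(plasmid, e) {
  plasmid <- as_dna_seq(plasmid)
  cm <- find_sites(plasmid, e)
  if (length(cm$positions) != 1L)
    stop(sprintf("linearization with %s requires exactly 1 cut, found %d",
                 e$name, length(cm$positions)), call. = FALSE)
  p <- cm$positions[1]
  L <- nchar(plasmid$seq)
  rotated <- paste0(substr(plasmid$seq, p + 1, L), substr(plasmid$seq, 1, p))
  dna_seq(rotated, id = paste0(plasmid$id, "_lin"), topology = "linear")
}
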