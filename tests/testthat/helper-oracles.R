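# Independent reference implementations ("oracles") used to validate the
# package's aligners, site scanner, ORF finder and panel selector. These are
# deliberately written in plain, slow R with their own conventions so that a
# shared bug with the production code is unlikely.

# ---- random sequences -----------------------------------------------------

rand_seq <- function(n, gc = 50) {
  g <- gc / 200
  a <- (100 - gc) / 200
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(a, g, g, a)), collapse = "")
}

# ---- affine-gap alignment scores (full-matrix DP, score only) -------------

oracle_local_score <- function(q, t, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  qq <- strsplit(q, "", fixed = TRUE)[[1]]
  tt <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qq); m <- length(tt)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open + gap_extend,
                           E[i + 1, j] + gap_extend)
    F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open + gap_extend,
                           F[i, j + 1] + gap_extend)
    s <- if (qq[i] == tt[j] && qq[i] != "N") match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
  }
  best
}

oracle_fit_score <- function(q, t, match = 2, mismatch = -3,
                             gap_open = -5, gap_extend = -2) {
  qq <- strsplit(q, "", fixed = TRUE)[[1]]
  tt <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qq); m <- length(tt)
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  H[1, ] <- 0  # leading target is free
  for (i in seq_len(n)) {
    H[i + 1, 1] <- gap_open + i * gap_extend
    F[i + 1, 1] <- gap_open + i * gap_extend
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open + gap_extend,
                             E[i + 1, j] + gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open + gap_extend,
                             F[i, j + 1] + gap_extend)
      s <- if (qq[i] == tt[j] && qq[i] != "N") match else mismatch
      H[i + 1, j + 1] <- max(H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  max(H[n + 1, ])  # trailing target is free
}

# ---- restriction cuts by brute rotation scan ------------------------------

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_iupac_rc <- function(site) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(site, "", fixed = TRUE)[[1]]]), collapse = "")
}

# sorted 0-based cut positions of enzyme e on dna_seq s, checking every
# start position one base at a time with modular indexing for circles
oracle_cuts <- function(s, e) {
  chars <- strsplit(s$seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  circ <- s$topology == "circular"
  site_f <- strsplit(e$site, "", fixed = TRUE)[[1]]
  site_r <- strsplit(oracle_iupac_rc(e$site), "", fixed = TRUE)[[1]]
  k <- length(site_f)
  matches_at <- function(site_chars, p0) {
    for (off in seq_len(k) - 1L) {
      idx <- p0 + off
      if (circ) idx <- idx %% L else if (idx >= L) return(FALSE)
      if (!(chars[idx + 1L] %in% ORACLE_IUPAC[[site_chars[off + 1L]]]))
        return(FALSE)
    }
    TRUE
  }
  starts <- if (circ) 0:(L - 1L) else if (L >= k) 0:(L - k) else integer()
  cuts <- integer()
  for (p0 in starts) {
    if (matches_at(site_f, p0)) cuts <- c(cuts, p0 + e$cut_offset)
    if (!identical(site_f, site_r) && matches_at(site_r, p0))
      cuts <- c(cuts, p0 + (k - e$cut_offset))
  }
  if (circ) cuts <- cuts %% L
  sort(unique(cuts[cuts >= 0 & cuts <= L]))
}

# ---- ORF enumeration ------------------------------------------------------

# enumerate ORFs per frame by explicit inspection of the codon list
oracle_orfs <- function(s, min_len = 150, start_codons = "ATG",
                        allow_truncated = TRUE) {
  L <- nchar(s$seq)
  rows <- NULL
  add <- function(strand, frame, c_start, c_end, trunc) {
    nt_start <- frame + 3L * (c_start - 1L)
    nt_end <- frame + 3L * c_end - 1L
    len <- nt_end - nt_start + 1L
    if (len < min_len) return()
    if (strand == "+") { a <- nt_start; b <- nt_end }
    else { a <- L - nt_end + 1L; b <- L - nt_start + 1L }
    rows <<- rbind(rows, data.frame(
      start = a, end = b, strand = strand, frame = frame,
      length_nt = len, truncated = trunc, stringsAsFactors = FALSE))
  }
  for (strand in c("+", "-")) {
    chr <- if (strand == "+") s$seq else reverse_complement(s$seq)
    for (frame in 1:3) {
      n <- (nchar(chr) - frame + 1L) %/% 3L
      if (n <= 0) next
      off <- frame + 3L * (0:(n - 1L))
      codons <- substring(chr, off, off + 2L)
      stop_i <- which(codons %in% c("TAA", "TAG", "TGA"))
      start_i <- which(codons %in% start_codons)
      prev <- 0L
      for (stp in stop_i) {
        inside <- start_i[start_i > prev & start_i < stp]
        if (length(inside)) add(strand, frame, min(inside), stp, "none")
        else if (allow_truncated && prev == 0L && stp > 1L)
          add(strand, frame, 1L, stp, "5prime")
        prev <- stp
      }
      if (allow_truncated && prev < n) {
        inside <- start_i[start_i > prev]
        if (length(inside)) add(strand, frame, min(inside), n, "3prime")
        else if (prev == 0L) add(strand, frame, 1L, n, "both")
      }
    }
  }
  if (is.null(rows))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      length_nt = integer(), truncated = character(),
                      stringsAsFactors = FALSE))
  rows <- rows[order(rows$start, rows$strand, rows$frame), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

# ---- enzyme panel: which plasmids each enzyme single-cuts -----------------

oracle_covers <- function(plasmids, catalogue) {
  lapply(catalogue, function(e)
    which(vapply(plasmids,
                 function(p) length(find_sites(p, e)$positions) == 1L,
                 logical(1))))
}

# TRUE when some subset of `covers` of size `sz` covers all n plasmids
oracle_cover_exists <- function(covers, n, sz) {
  if (sz == 0) return(n == 0)
  for (idx in utils::combn(length(covers), sz, simplify = FALSE)) {
    if (length(unique(unlist(covers[idx]))) == n) return(TRUE)
  }
  FALSE
}

# all strings of length `len` over `alphabet`
all_strings <- function(len, alphabet) {
  grid <- do.call(expand.grid, rep(list(alphabet), len))
  apply(grid, 1, paste, collapse = "")
}
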