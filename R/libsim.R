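#' Cloning vector model
#'
#' A circular backbone with exactly one BamHI site (the cloning site) and
#' two primer annealing spans flanking it, mimicking the M13F/M13R layout
#' of pUC118-family vectors. `cloning_site` is the 0-based top-strand cut
#' position; primer spans are 0-based half-open and must not overlap the
#' cut.
#'
#' @param backbone Circular [dna_seq].
#' @param cloning_site 0-based BamHI cut position.
#' @param fwd_primer_site,rev_primer_site Integer length-2 spans.
#' @param marker_spans Optional named list of informational spans.
#' @return A `vector_model`.
#' @export
vector_model <- function(backbone, cloning_site, fwd_primer_site,
                         rev_primer_site, marker_spans = list()) {
  stopifnot(inherits(backbone, "dna_seq"), backbone$topology == "circular")
  bam <- find_sites(backbone, enzyme("BamHI", "GGATCC", 1L))
  if (length(bam$positions) != 1L)
    stop("vector backbone must contain exactly one BamHI site", call. = FALSE)
  if (bam$positions[1] != cloning_site)
    stop("cloning_site does not match the backbone's BamHI cut position",
         call. = FALSE)
  overlaps <- function(span) cloning_site > span[1] && cloning_site < span[2]
  if (overlaps(fwd_primer_site) || overlaps(rev_primer_site))
    stop("primer sites must not overlap the cloning site", call. = FALSE)
  fwd_seq <- substr(backbone$seq, fwd_primer_site[1] + 1, fwd_primer_site[2])
  rev_seq <- substr(backbone$seq, rev_primer_site[1] + 1, rev_primer_site[2])
  structure(list(backbone = backbone, cloning_site = as.integer(cloning_site),
                 fwd_primer_site = as.integer(fwd_primer_site),
                 rev_primer_site = as.integer(rev_primer_site),
                 fwd_primer_seq = fwd_seq, rev_primer_seq = rev_seq,
                 marker_spans = marker_spans),
            class = "vector_model")
}

#' @export
print.vector_model <- function(x, ...) {
  cat(sprintf("<vector_model> %s  %d bp circular, BamHI cut at %d\n",
              x$backbone$id, nchar(x$backbone$seq), x$cloning_site))
  invisible(x)
}

# mutate the middle base of every occurrence of `site` that lies outside
# `protected` (0-based half-open spans); returns the edited string
scrub_site <- function(seqchr, site, protected) {
  repeat {
    starts <- iupac_match_starts(
      site, paste0(seqchr, substr(seqchr, 1, nchar(site) - 1)))
    starts <- starts %% nchar(seqchr)
    keep <- starts[!vapply(starts, function(p) {
      any(vapply(protected, function(sp) p >= sp[1] - nchar(site) &&
                   p < sp[2], logical(1)))
    }, logical(1))]
    if (!length(keep)) return(seqchr)
    p <- keep[1] + 2L  # 0-based position of the base to flip
    p <- (p %% nchar(seqchr)) + 1L
    cur <- substr(seqchr, p, p)
    substr(seqchr, p, p) <- chartr("ACGT", "CATG", cur)
  }
}

#' Default synthetic cloning vector
#'
#' A deterministically constructed 3162 bp circular backbone emulating
#' pUC118: a single BamHI cloning site (cut at position 1001), a HindIII
#' site 400 bp upstream and XbaI/EcoRI sites downstream (linearization
#' candidates), and 20 bp forward/reverse primer annealing sites flanking
#' the cloning site. No other occurrence of any of these sites exists on
#' the backbone, so HindIII, XbaI and EcoRI single-cut any recombinant
#' whose insert lacks the corresponding site. This is a synthetic stand-in
#' for the real vector sequence.
#'
#' @return A [vector_model].
#' @export
default_vector <- function() {
  with_seed(31620L, {
    L <- 3162L
    bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    seqchr <- paste(bases, collapse = "")
    sites <- list(HindIII = c(600L, "AAGCTT"), BamHI = c(1000L, "GGATCC"),
                  XbaI = c(1400L, "TCTAGA"), EcoRI = c(1800L, "GAATTC"))
    for (s in sites) {
      p0 <- as.integer(s[1])
      substr(seqchr, p0 + 1, p0 + 6) <- s[2]
    }
    protected <- lapply(sites, function(s) {
      p0 <- as.integer(s[1]); c(p0, p0 + 6L)
    })
    # scrubbing one site can create another; iterate to a joint fixed point
    repeat {
      before <- seqchr
      for (s in sites) seqchr <- scrub_site(seqchr, s[[2]], protected)
      if (identical(seqchr, before)) break
    }
    backbone <- dna_seq(seqchr, id = "pUC118like_synthetic",
                        topology = "circular")
    vector_model(backbone, cloning_site = 1001L,
                 fwd_primer_site = c(900L, 920L),
                 rev_primer_site = c(1080L, 1100L),
                 marker_spans = list(lacZ_like = c(500L, 1200L),
                                     ampR_like = c(2000L, 2900L)))
  })
}

#' Simulate a genome of given GC content
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc_target/200` and
#' `P(A) = P(T) = (100 - gc_target)/200`.
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc_target Target GC percent in (0, 100); default 75.35, the
#'   high-GC regime the pipeline is designed for.
#' @param seed Integer RNG seed.
#' @param id Sequence id.
#' @return Linear [dna_seq].
#' @export
simulate_genome <- function(length, gc_target = 75.35, seed = 1L,
                            id = "sim_genome") {
  stopifnot(length >= 1000)
  if (gc_target <= 0 || gc_target >= 100)
    stop("gc_target must be strictly between 0 and 100", call. = FALSE)
  g <- gc_target / 200; a <- (100 - gc_target) / 200
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c(a, g, g, a))
    dna_seq(paste(bases, collapse = ""), id = id, topology = "linear")
  })
}

new_fragment <- function(seqchr, start, end, source_id) {
  list(seq = seqchr, start = as.integer(start), end = as.integer(end),
       source_id = source_id)
}

#' Partial restriction digest
#'
#' Each recognition-site cut position is cut independently with
#' probability `p_cut`; fragments are the intervals between consecutive
#' realized cuts (plus the two terminal pieces for linear input; wrapping
#' for circular input). Fragment records carry 1-based inclusive source
#' coordinates. Zero-length terminal pieces are dropped.
#'
#' @param genome A [dna_seq].
#' @param e An [enzyme]; default Sau3AI.
#' @param p_cut Per-site cut probability in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return List of fragment records (`seq`, `start`, `end`, `source_id`).
#' @export
partial_digest <- function(genome, e = default_enzymes()[[1]], p_cut = 0.1,
                           seed = 1L) {
  stopifnot(p_cut >= 0, p_cut <= 1)
  genome <- as_dna_seq(genome)
  cm <- find_sites(genome, e)
  L <- nchar(genome$seq)
  with_seed(seed, {
    realized <- cm$positions[runif(length(cm$positions)) < p_cut]
    frags <- list()
    if (genome$topology == "linear") {
      bounds <- unique(c(0L, realized, L))
      for (i in seq_len(length(bounds) - 1L)) {
        a <- bounds[i]; b <- bounds[i + 1L]
        if (b > a) {
          frags[[length(frags) + 1L]] <- new_fragment(
            substr(genome$seq, a + 1L, b), a + 1L, b, genome$id)
        }
      }
    } else {
      if (!length(realized)) {
        frags[[1L]] <- new_fragment(genome$seq, 1L, L, genome$id)
      } else {
        k <- length(realized)
        for (i in seq_len(k)) {
          a <- realized[i]
          b <- if (i < k) realized[i + 1L] else realized[1L]
          if (i < k) {
            frags[[length(frags) + 1L]] <- new_fragment(
              substr(genome$seq, a + 1L, b), a + 1L, b, genome$id)
          } else {
            wrapped <- paste0(substr(genome$seq, a + 1L, L),
                              substr(genome$seq, 1L, b))
            if (nchar(wrapped) > 0)
              frags[[length(frags) + 1L]] <- new_fragment(
                wrapped, a + 1L, b, genome$id)
          }
        }
      }
    }
    frags
  })
}

#' Size-select fragments
#'
#' Keeps fragments with `min_bp <= length <= max_bp` (both inclusive),
#' emulating gel-based size selection. Defaults cover the 1-3000 bp
#' small-insert window.
#'
#' @param fragments List of fragment records.
#' @param min_bp,max_bp Inclusive bounds.
#' @return Filtered list.
#' @export
size_select <- function(fragments, min_bp = 1L, max_bp = 3000L) {
  stopifnot(min_bp >= 1, max_bp >= min_bp)
  Filter(function(f) {
    n <- nchar(f$seq); n >= min_bp && n <= max_bp
  }, fragments)
}

#' Ligate a fragment into the vector's cloning site
#'
#' The circular recombinant is the backbone opened at the cloning site
#' with the fragment inserted verbatim in a random orientation (fair coin
#' from `seed`). Sticky-end chemistry is abstracted away; plasmid length is
#' backbone length plus fragment length.
#'
#' @param fragment A fragment record or [dna_seq]/character.
#' @param vector A [vector_model].
#' @param seed Integer RNG seed for the orientation coin.
#' @param id Plasmid id.
#' @return List with `plasmid` (circular [dna_seq]) and `orientation`
#'   (`"+"` or `"-"`).
#' @export
clone_into_vector <- function(fragment, vector, seed = 1L, id = "plasmid") {
  fr <- if (is.list(fragment) && !inherits(fragment, "dna_seq"))
    fragment$seq else seq_chr(as_dna_seq(fragment))
  if (!nzchar(fr)) stop("empty fragment", call. = FALSE)
  orientation <- with_seed(seed, if (runif(1) < 0.5) "+" else "-")
  ins <- if (orientation == "+") fr else revcomp_chr(fr)
  b <- vector$backbone$seq
  c0 <- vector$cloning_site
  plasmid <- dna_seq(paste0(substr(b, 1, c0), ins,
                            substr(b, c0 + 1, nchar(b))),
                     id = id, topology = "circular")
  list(plasmid = plasmid, orientation = orientation)
}

#' Build a clone library with a ground-truth manifest
#'
#' Draws `n_unique` distinct size-selected fragments from repeated
#' independent partial digests of the genome (each digested molecule is an
#' independent Bernoulli realization over the cut sites, as in a bulk
#' partial digest), replicates each fragment according to its duplication
#' group size (same insert, independent orientation), ligates every clone
#' into the vector, and returns clone records plus a truth manifest.
#'
#' @param genome Linear [dna_seq].
#' @param vector A [vector_model]; default [default_vector()].
#' @param n_unique Number of distinct inserts.
#' @param duplication Integer vector of group sizes, one per unique insert.
#' @param p_cut Per-site cut probability of the partial digest.
#' @param min_bp,max_bp Size-selection window.
#' @param seed Integer RNG seed.
#' @param e Digestion [enzyme]; default Sau3AI.
#' @param clone_ids Optional list of character vectors (one per group)
#'   overriding the automatic clone ids.
#' @param max_molecules Digestion attempts before giving up.
#' @return List with `clones` (list of `clone_record`) and `manifest`
#'   (data.frame: clone_id, group_id, start, end, strand, insert_len).
#' @export
build_library <- function(genome, vector = default_vector(), n_unique,
                          duplication, p_cut = 0.1, min_bp = 1L,
                          max_bp = 3000L, seed = 1L,
                          e = default_enzymes()[[1]], clone_ids = NULL,
                          max_molecules = 5000L) {
  stopifnot(length(duplication) == n_unique, all(duplication >= 1))
  genome <- as_dna_seq(genome)
  cm <- find_sites(genome, e)
  pos <- cm$positions
  L <- nchar(genome$seq)
  with_seed(seed, {
    seen <- character()
    eligible <- list()
    molecules <- 0L
    pick <- integer()
    # greedy distinct-locus selection over a random candidate order:
    # overlapping digestion fragments from one region would collapse into a
    # single group downstream, so the unique inserts must be
    # distinguishable (pairwise overlap < half the shorter)
    try_pick <- function() {
      perm <- sample.int(length(eligible))
      chosen <- integer()
      for (cand in perm) {
        a <- eligible[[cand]]
        ok <- TRUE
        for (p in chosen) {
          b <- eligible[[p]]
          ov <- min(a[2], b[2]) - max(a[1], b[1]) + 1L
          if (ov >= 0.5 * min(a[2] - a[1] + 1L, b[2] - b[1] + 1L)) {
            ok <- FALSE; break
          }
        }
        if (ok) chosen <- c(chosen, cand)
        if (length(chosen) == n_unique) break
      }
      chosen
    }
    repeat {
      if (length(eligible) >= n_unique) {
        pick <- try_pick()
        if (length(pick) == n_unique) break
      }
      if (molecules >= max_molecules) {
        if (length(eligible) < n_unique)
          stop(sprintf(paste0(
            "only %d eligible fragment(s) found after %d digested ",
            "molecules; adjust p_cut, widen the size window, or use a ",
            "longer genome"),
            length(eligible), molecules), call. = FALSE)
        stop(sprintf(paste0(
          "only %d sufficiently distinct fragment(s) among %d eligible; ",
          "adjust p_cut, widen the size window, or use a longer genome"),
          length(pick), length(eligible)), call. = FALSE)
      }
      molecules <- molecules + 1L
      realized <- pos[runif(length(pos)) < p_cut]
      bounds <- unique(c(0L, realized, L))
      lens <- diff(bounds)
      ok <- which(lens >= min_bp & lens <= max_bp)
      for (i in ok) {
        key <- paste0(bounds[i], "-", bounds[i + 1L])
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          eligible[[length(eligible) + 1L]] <-
            c(bounds[i] + 1L, bounds[i + 1L])
        }
      }
    }
    clones <- list()
    manifest <- NULL
    clone_counter <- 0L
    for (g in seq_len(n_unique)) {
      locus <- eligible[[pick[g]]]
      ins_chr <- substr(genome$seq, locus[1], locus[2])
      gid <- paste0("g", g)
      for (r in seq_len(duplication[g])) {
        clone_counter <- clone_counter + 1L
        cid <- if (!is.null(clone_ids)) clone_ids[[g]][r]
               else sprintf("c%02d", clone_counter)
        orientation <- if (runif(1) < 0.5) "+" else "-"
        ins_used <- if (orientation == "+") ins_chr else revcomp_chr(ins_chr)
        b <- vector$backbone$seq
        c0 <- vector$cloning_site
        plasmid <- dna_seq(paste0(substr(b, 1, c0), ins_used,
                                  substr(b, c0 + 1, nchar(b))),
                           id = cid, topology = "circular")
        rec <- structure(list(
          clone_id = cid,
          insert = dna_seq(ins_chr, id = paste0(cid, "_insert")),
          source_locus = locus, orientation = orientation,
          group_id = gid, plasmid = plasmid), class = "clone_record")
        clones[[length(clones) + 1L]] <- rec
        manifest <- rbind(manifest, data.frame(
          clone_id = cid, group_id = gid, start = locus[1], end = locus[2],
          strand = orientation, insert_len = nchar(ins_chr),
          stringsAsFactors = FALSE))
      }
    }
    list(clones = clones, manifest = manifest)
  })
}

#' Write a truth manifest TSV
#' @param manifest Data frame from [build_library()].
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  write_tsv_commented(manifest, path,
    comments = "truth manifest: loci are 1-based inclusive on the source genome")
}
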