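#' CCS error model
#'
#' Per-base independent substitution, insertion and deletion
#' probabilities. Defaults are in the circular-consensus accuracy regime
#' (0.2% each); the `raw_pacbio` preset reflects the much noisier raw
#' subread regime (~13% combined).
#'
#' @param sub_rate,ins_rate,del_rate Probabilities in `[0, 1)`, summing
#'   to less than 1.
#' @return A `ccs_error_model`.
#' @export
ccs_error_model <- function(sub_rate = 0.002, ins_rate = 0.002,
                            del_rate = 0.002) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate < 1, ins_rate < 1, del_rate < 1,
            sub_rate + ins_rate + del_rate < 1)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "ccs_error_model")
}

#' @rdname ccs_error_model
#' @export
ccs_presets <- function() {
  list(ccs = ccs_error_model(0.002, 0.002, 0.002),
       raw_pacbio = ccs_error_model(0.06, 0.05, 0.02),
       perfect = ccs_error_model(0, 0, 0))
}

#' Sanger early-termination model
#'
#' Emulates the GC-dependent early termination of dideoxy sequencing on
#' high-GC templates: at base i the read terminates with hazard
#' `min(1, h0 * exp(beta * g_i))` where `g_i` is the GC fraction of the
#' trailing `window` bases of template. Reads are capped at `max_len` and
#' flagged invalid below `min_valid` (default 20 bp, the practical lower
#' limit for a usable tag).
#'
#' @param h0 Baseline per-base termination hazard (>= 0).
#' @param beta GC sensitivity (hazard multiplier exponent).
#' @param window Trailing window (bp) for local GC.
#' @param max_len Hard read-length cap (bp).
#' @param min_valid Minimum valid read length (bp).
#' @param sub_rate Per-base substitution error rate of the read.
#' @return A `sanger_model`.
#' @export
sanger_model <- function(h0 = 5e-4, beta = 2, window = 50L,
                         max_len = 1000L, min_valid = 20L,
                         sub_rate = 0.001) {
  stopifnot(h0 >= 0, window >= 1, max_len > min_valid, min_valid >= 1,
            sub_rate >= 0, sub_rate < 1)
  structure(list(h0 = h0, beta = beta, window = as.integer(window),
                 max_len = as.integer(max_len),
                 min_valid = as.integer(min_valid), sub_rate = sub_rate),
            class = "sanger_model")
}

apply_substitutions <- function(bases, rate) {
  if (rate <= 0 || !length(bases)) return(bases)
  hit <- which(runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  bases
}

#' Simulate a CCS read of a linear template
#'
#' Applies per-base independent substitutions, insertions and deletions;
#' the read covers the full template (full-length consensus assumption).
#'
#' @param template Linear [dna_seq].
#' @param model A [ccs_error_model()].
#' @param seed Integer RNG seed.
#' @param id Read id.
#' @return Linear [dna_seq].
#' @export
sim_ccs <- function(template, model = ccs_error_model(), seed = 1L,
                    id = paste0(template$id, "_ccs")) {
  template <- as_dna_seq(template)
  with_seed(seed, {
    b <- strsplit(template$seq, "", fixed = TRUE)[[1]]
    n <- length(b)
    keep <- runif(n) >= model$del_rate
    b <- apply_substitutions_masked(b, model$sub_rate, keep)
    ins <- runif(n) < model$ins_rate
    ins_base <- character(n)
    if (any(ins)) ins_base[ins] <- sample(c("A", "C", "G", "T"),
                                          sum(ins), replace = TRUE)
    out <- paste0(ifelse(keep, b, ""), ins_base)
    dna_seq(paste(out, collapse = ""), id = id, topology = "linear")
  })
}

# substitute only surviving bases so the draw count is deterministic
apply_substitutions_masked <- function(bases, rate, mask) {
  if (rate <= 0) return(bases)
  hit <- which(mask & runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  bases
}

# template walk of up to max_len bases along a circular plasmid
walk_template <- function(plasmid_chr, start0, step, max_len) {
  L <- nchar(plasmid_chr)
  idx <- (start0 + step * (seq_len(min(max_len, L)) - 1L)) %% L
  substring(plasmid_chr, idx + 1L, idx + 1L)
}

#' Simulate a Sanger tag read from a recombinant plasmid
#'
#' The read starts immediately 3' of the primer annealing site in the
#' requested direction and proceeds base by base; termination follows the
#' GC-dependent hazard of the [sanger_model()]. Reverse reads are
#' reported in sequencing orientation (reverse complement of the top
#' strand). The returned read carries a logical `valid` attribute.
#'
#' @param plasmid Circular [dna_seq] containing the vector's primer
#'   sites.
#' @param vector A [vector_model].
#' @param direction `"forward"` or `"reverse"`.
#' @param model A [sanger_model()].
#' @param seed Integer RNG seed.
#' @param id Read id; defaults to `<plasmid>_F` / `<plasmid>_R`.
#' @return Linear [dna_seq] with attribute `valid`.
#' @export
sim_sanger <- function(plasmid, vector, direction = c("forward", "reverse"),
                       model = sanger_model(), seed = 1L, id = NULL) {
  direction <- match.arg(direction)
  plasmid <- as_dna_seq(plasmid)
  L <- nchar(plasmid$seq)
  doubled <- paste0(plasmid$seq, plasmid$seq)
  primer <- if (direction == "forward") vector$fwd_primer_seq
            else vector$rev_primer_seq
  m <- regexpr(primer, doubled, fixed = TRUE)
  if (m == -1L)
    stop(sprintf("%s primer site not found on plasmid '%s'",
                 direction, plasmid$id), call. = FALSE)
  p0 <- as.integer(m) - 1L  # 0-based primer start on top strand
  if (direction == "forward") {
    start0 <- (p0 + nchar(primer)) %% L
    tmpl <- walk_template(plasmid$seq, start0, +1L, model$max_len)
  } else {
    start0 <- (p0 - 1L) %% L
    tmpl <- chartr("ACGTN", "TGCAN",
                   walk_template(plasmid$seq, start0, -1L, model$max_len))
  }
  if (is.null(id))
    id <- paste0(plasmid$id, if (direction == "forward") "_F" else "_R")
  with_seed(seed, {
    n <- length(tmpl)
    gc <- as.numeric(tmpl %in% c("G", "C"))
    cs <- c(0, cumsum(gc))
    i <- seq_len(n)
    lo <- pmax(0L, i - model$window)
    g <- (cs[i + 1L] - cs[lo + 1L]) / (i - lo)
    hazard <- pmin(1, model$h0 * exp(model$beta * g))
    u <- runif(n)
    stop_at <- which(u < hazard)
    len <- if (length(stop_at)) stop_at[1] else n
    bases <- apply_substitutions(tmpl[seq_len(len)], model$sub_rate)
    read <- dna_seq(paste(bases, collapse = ""), id = id,
                    topology = "linear")
    attr(read, "valid") <- len >= model$min_valid
    read
  })
}

#' Simulate a full sequencing run of a clone library
#'
#' One full-length CCS read per clone from its linearized plasmid,
#' shuffled and emitted anonymously (the pooled long-read library carries
#' no clone identity), plus two labelled Sanger tag reads per clone. A
#' run manifest records the ground truth for scoring.
#'
#' @param clones List of `clone_record`s from [build_library()].
#' @param vector A [vector_model].
#' @param ccs_model A [ccs_error_model()].
#' @param sanger_mod A [sanger_model()].
#' @param assignment Named character vector (clone id -> enzyme name)
#'   from [min_enzyme_panel()].
#' @param seed Integer RNG seed.
#' @param catalogue Enzyme catalogue resolving `assignment` names.
#' @return List with `ccs` (anonymous [dna_seq] reads, ids
#'   `ccs_0001`...), `sanger` (labelled reads with `valid` attributes)
#'   and `manifest` (data.frame: ccs_id, clone_id, group_id, start, end,
#'   strand, enzyme).
#' @export
sim_run <- function(clones, vector, ccs_model = ccs_error_model(),
                    sanger_mod = sanger_model(), assignment, seed = 1L,
                    catalogue = default_enzymes()) {
  enz_by_name <- setNames(catalogue, vapply(catalogue, `[[`, "", "name"))
  ccs_reads <- base::vector("list", length(clones))
  sanger_reads <- base::vector("list", 2L * length(clones))
  for (i in seq_along(clones)) {
    cl <- clones[[i]]
    ename <- assignment[[cl$clone_id]]
    if (is.null(ename) || is.na(ename))
      stop(sprintf("no panel enzyme assigned for clone '%s'", cl$clone_id),
           call. = FALSE)
    lin <- linearize(cl$plasmid, enz_by_name[[ename]])
    ccs_reads[[i]] <- sim_ccs(lin, ccs_model,
                              seed = stage_seed(seed, paste0("ccs_", cl$clone_id)),
                              id = cl$clone_id)
    sanger_reads[[2 * i - 1]] <- sim_sanger(
      cl$plasmid, vector, "forward", sanger_mod,
      seed = stage_seed(seed, paste0("sangerF_", cl$clone_id)))
    sanger_reads[[2 * i]] <- sim_sanger(
      cl$plasmid, vector, "reverse", sanger_mod,
      seed = stage_seed(seed, paste0("sangerR_", cl$clone_id)))
  }
  perm <- with_seed(stage_seed(seed, "pool_shuffle"),
                    sample.int(length(clones)))
  manifest <- NULL
  pooled <- base::vector("list", length(clones))
  for (j in seq_along(perm)) {
    i <- perm[j]
    cl <- clones[[i]]
    anon <- sprintf("ccs_%04d", j)
    r <- ccs_reads[[i]]
    r$id <- anon
    pooled[[j]] <- r
    manifest <- rbind(manifest, data.frame(
      ccs_id = anon, clone_id = cl$clone_id, group_id = cl$group_id,
      start = cl$source_locus[1], end = cl$source_locus[2],
      strand = cl$orientation, enzyme = assignment[[cl$clone_id]],
      stringsAsFactors = FALSE))
  }
  list(ccs = pooled, sanger = sanger_reads, manifest = manifest)
}

#' Write Sanger reads to FASTA with a valid flag in the description
#' @param reads List of reads from [sim_sanger()].
#' @param path Output path.
#' @export
write_sanger_fasta <- function(reads, path) {
  labelled <- lapply(reads, function(r) {
    v <- attr(r, "valid"); if (is.null(v)) v <- TRUE
    r$id <- sprintf("%s valid=%d", r$id, as.integer(v))
    r
  })
  write_fasta(labelled, path)
}

#' Read Sanger reads written by [write_sanger_fasta()]
#' @param path File path.
#' @return List of [dna_seq] with `valid` attributes.
#' @export
read_sanger_fasta <- function(path) {
  lapply(read_fasta(path), function(r) {
    valid <- !grepl("valid=0", r$id, fixed = TRUE)
    r$id <- sub(" .*$", "", r$id)
    attr(r, "valid") <- valid
    r
  })
}
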