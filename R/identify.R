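#' Pipeline configuration for clone identification
#'
#' Thresholds for vector trimming, tag assignment, deduplication and
#' genome back-verification. Tag reads shorter than `min_tag_len`
#' (default 20 bp, the practical lower limit for an identifying tag) are
#' excluded read-wise, not clone-wise: a clone is `too_short` only when
#' none of its reads is usable.
#'
#' @param scheme [scoring_scheme()] used by every aligner call.
#' @param arm_len Length (bp) of each vector arm flanking the cloning
#'   site used for insert extraction.
#' @param min_arm_identity,min_arm_len Acceptance thresholds for an arm hit.
#' @param min_tag_len Minimum usable Sanger tag length (bp).
#' @param min_identity Minimum percent identity for a tag assignment.
#' @param margin Minimum score margin of the best group over the runner-up
#'   group.
#' @param dedup_identity,dedup_min_cov Single-linkage duplicate criteria:
#'   percent identity and percent coverage of the shorter insert.
#' @param k_assign,k_dedup,k_verify Exact k-mer seed lengths for candidate
#'   prefiltering / genome seeding.
#' @param min_report_identity Below this genome identity a representative
#'   is reported as `no_locus`.
#' @return A named list.
#' @export
identify_config <- function(scheme = scoring_scheme(), arm_len = 200L,
                            min_arm_identity = 80, min_arm_len = 30L,
                            min_tag_len = 20L, min_identity = 90,
                            margin = 5L, dedup_identity = 99,
                            dedup_min_cov = 90, k_assign = 16L,
                            k_dedup = 15L, k_verify = 15L,
                            min_report_identity = 80) {
  as.list(environment())
}

kmer_set <- function(chr, k) {
  n <- nchar(chr)
  if (n < k) return(character())
  unique(substring(chr, 1:(n - k + 1), k:n))
}

#' Extract the insert from a full-length read of a recombinant plasmid
#'
#' Locally aligns the two backbone arms flanking the cloning site against
#' the read (trying both read orientations); the insert is the read
#' segment strictly between the inner arm boundaries, with the read
#' orientation normalized so the left arm precedes the right arm.
#'
#' @param ccs Linear [dna_seq] (a full-length consensus read).
#' @param vector A [vector_model].
#' @param config An [identify_config()].
#' @return An `insert_call`: list with `ccs_id`, `status` (`ok`,
#'   `empty_vector` or `vector_not_found`), `insert`, the two arm
#'   `alignment_result`s and `orientation_normalized`.
#' @export
trim_vector <- function(ccs, vector, config = identify_config()) {
  ccs <- as_dna_seq(ccs)
  b <- vector$backbone$seq
  c0 <- vector$cloning_site
  al <- config$arm_len
  left_arm <- substr(b, c0 - al + 1, c0)
  right_arm <- substr(b, c0 + 1, c0 + al)
  best <- NULL
  for (orient in c("+", "-")) {
    read_chr <- if (orient == "+") ccs$seq else revcomp_chr(ccs$seq)
    la <- local_align(left_arm, read_chr, config$scheme)
    ra <- local_align(right_arm, read_chr, config$scheme)
    tot <- la$score + ra$score
    if (is.null(best) || tot > best$tot) {
      best <- list(tot = tot, la = la, ra = ra, orient = orient,
                   read_chr = read_chr)
    }
  }
  arm_ok <- function(a) {
    a$identity_pct >= config$min_arm_identity &&
      (a$target_span[2] - a$target_span[1]) >= config$min_arm_len
  }
  call <- list(ccs_id = ccs$id, insert = NULL,
               left_arm = best$la, right_arm = best$ra,
               orientation_normalized = best$orient == "-")
  if (!arm_ok(best$la) || !arm_ok(best$ra) ||
      best$ra$target_span[1] < best$la$target_span[2]) {
    call$status <- "vector_not_found"
  } else if (best$ra$target_span[1] == best$la$target_span[2]) {
    call$status <- "empty_vector"
  } else {
    call$status <- "ok"
    ins <- substr(best$read_chr, best$la$target_span[2] + 1,
                  best$ra$target_span[1])
    call$insert <- dna_seq(ins, id = paste0(ccs$id, "_insert"))
  }
  structure(call, class = "insert_call")
}

#' Group near-identical inserts
#'
#' Single-linkage grouping: two inserts link when a local alignment on
#' either strand covers at least `dedup_min_cov` percent of the shorter
#' insert at `dedup_identity` percent identity or better (exact sequence
#' or reverse-complement equality links immediately). Candidate pairs are
#' prefiltered by shared exact k-mers. The representative is the longest
#' member (ties broken by id); group ids are assigned in order of the
#' lexicographically smallest member id, so the output is invariant to
#' input order.
#'
#' @param inserts List of `insert_call`s with status `ok`.
#' @param config An [identify_config()].
#' @return List of groups: each a list with `group_id`, `members`
#'   (character ccs ids), `representative_id` and `representative`
#'   ([dna_seq]).
#' @export
dedup <- function(inserts, config = identify_config()) {
  n <- length(inserts)
  if (n == 0) return(list())
  ids <- vapply(inserts, function(x) x$ccs_id, "")
  seqs <- vapply(inserts, function(x) x$insert$seq, "")
  ord <- order(ids)
  ids <- ids[ord]; seqs <- seqs[ord]
  k <- config$k_dedup
  fwd_sets <- lapply(seqs, kmer_set, k = k)
  rc_seqs <- vapply(seqs, revcomp_chr, "")
  rc_sets <- lapply(rc_seqs, kmer_set, k = k)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  linked <- function(i, j) {
    if (seqs[i] == seqs[j] || seqs[i] == rc_seqs[j]) return(TRUE)
    t <- max(3, 0.1 * min(length(fwd_sets[[i]]), length(fwd_sets[[j]])))
    shared <- max(length(intersect(fwd_sets[[i]], fwd_sets[[j]])),
                  length(intersect(fwd_sets[[i]], rc_sets[[j]])))
    if (shared < t) return(FALSE)
    # align the shorter as query so coverage is measured on it
    if (nchar(seqs[i]) <= nchar(seqs[j])) { q <- seqs[i]; s <- seqs[j] }
    else { q <- seqs[j]; s <- seqs[i] }
    a <- local_align(q, s, config$scheme, both_strands = TRUE)
    cov <- 100 * (a$query_span[2] - a$query_span[1]) / nchar(q)
    cov >= config$dedup_min_cov && a$identity_pct >= config$dedup_identity
  }

  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (find(i) != find(j) && linked(i, j)) union_(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comp <- split(seq_len(n), roots)
  comp <- comp[order(vapply(comp, function(m) ids[min(m)], ""))]
  groups <- vector("list", length(comp))
  for (g in seq_along(comp)) {
    m <- comp[[g]]
    lens <- nchar(seqs[m])
    rep_i <- m[order(-lens, ids[m])][1]
    groups[[g]] <- list(group_id = sprintf("u%d", g),
                        members = ids[m],
                        representative_id = ids[rep_i],
                        representative = dna_seq(seqs[rep_i], id = ids[rep_i]))
  }
  groups
}

#' Assign Sanger tag reads to full-length inserts
#'
#' Each valid tag read of at least `min_tag_len` bp is locally aligned
#' (both strands) against candidate inserts sharing at least one exact
#' k-mer with the tag (all inserts when no k-mer is shared). A clone is
#' assigned to the best-scoring insert when the identity is at least
#' `min_identity`, the aligned tag length is at least `min_tag_len`, and
#' the score margin over the best insert of any *other* duplication group
#' is at least `margin` (near-identical inserts of one clone's own group
#' are not competitors). Forward and reverse evidence is combined; if both
#' pass they must agree on the group, otherwise the clone is `ambiguous`.
#' Clones with no usable read are `too_short`.
#'
#' @param inserts List of `insert_call`s with status `ok`.
#' @param sanger List of [dna_seq] tag reads with ids `<clone>_F` /
#'   `<clone>_R`; a logical `valid` attribute marks failed reads.
#' @param config An [identify_config()].
#' @param groups Optional output of [dedup()]; defaults to singleton
#'   groups.
#' @return A data.frame with one row per clone: `clone_id`, `ccs_id`,
#'   `group_id`, `status` (`assigned`, `ambiguous`, `too_short`,
#'   `no_hit`), best and runner-up scores, identity, and the forward /
#'   reverse tag lengths actually observed.
#' @export
assign_tags <- function(inserts, sanger, config = identify_config(),
                        groups = NULL) {
  ids <- vapply(inserts, function(x) x$ccs_id, "")
  seqs <- vapply(inserts, function(x) x$insert$seq, "")
  if (is.null(groups)) {
    grp <- setNames(ids, ids)
  } else {
    grp <- unlist(lapply(groups, function(g)
      setNames(rep(g$group_id, length(g$members)), g$members)))
  }
  k <- config$k_assign
  ins_sets <- lapply(seqs, kmer_set, k = k)

  read_clone <- sub("_[FR]$", "", vapply(sanger, function(s) s$id, ""))
  read_dir <- sub("^.*_", "", vapply(sanger, function(s) s$id, ""))
  clones <- unique(read_clone)

  score_read <- function(read) {
    tag <- read$seq
    tag_sets <- union(kmer_set(tag, k), kmer_set(revcomp_chr(tag), k))
    cand <- which(vapply(ins_sets, function(s)
      length(intersect(s, tag_sets)) > 0, logical(1)))
    if (!length(cand)) cand <- seq_along(seqs)
    res <- lapply(cand, function(i)
      local_align(tag, seqs[i], config$scheme, both_strands = TRUE))
    sc <- vapply(res, function(a) a$score, 0L)
    best_i <- cand[order(-sc, ids[cand])][1]
    best_a <- res[[which(cand == best_i)]]
    other <- grp[ids[cand]] != grp[ids[best_i]]
    second <- if (any(other)) max(sc[other]) else 0L
    alen <- best_a$query_span[2] - best_a$query_span[1]
    pass <- best_a$identity_pct >= config$min_identity &&
      alen >= config$min_tag_len &&
      (best_a$score - second) >= config$margin
    list(best_i = best_i, best = best_a, second = second, pass = pass,
         marginal = (best_a$identity_pct >= config$min_identity &&
                       alen >= config$min_tag_len &&
                       (best_a$score - second) < config$margin))
  }

  rows <- lapply(clones, function(cl) {
    reads <- sanger[read_clone == cl]
    dirs <- read_dir[read_clone == cl]
    lens <- setNames(rep(NA_integer_, 2), c("F", "R"))
    for (i in seq_along(reads)) lens[dirs[i]] <- nchar(reads[[i]]$seq)
    usable <- vapply(reads, function(r) {
      v <- attr(r, "valid"); if (is.null(v)) v <- TRUE
      isTRUE(v) && nchar(r$seq) >= config$min_tag_len
    }, logical(1))
    out <- data.frame(clone_id = cl, ccs_id = "unassigned",
                      group_id = NA_character_, status = "no_hit",
                      best_score = NA_integer_, second_best = NA_integer_,
                      identity_pct = NA_real_,
                      fwd_tag_len = lens[["F"]], rev_tag_len = lens[["R"]],
                      stringsAsFactors = FALSE)
    if (!length(seqs)) return(out)
    if (!any(usable)) { out$status <- "too_short"; return(out) }
    evid <- lapply(reads[usable], score_read)
    passing <- Filter(function(e) e$pass, evid)
    if (!length(passing)) {
      out$status <- if (any(vapply(evid, function(e) e$marginal,
                                   logical(1)))) "ambiguous" else "no_hit"
      best <- evid[[order(-vapply(evid, function(e) e$best$score, 0L))[1]]]
      out$best_score <- best$best$score
      out$second_best <- best$second
      out$identity_pct <- best$best$identity_pct
      return(out)
    }
    pgroups <- unique(vapply(passing, function(e) grp[[ids[e$best_i]]], ""))
    best <- passing[[order(-vapply(passing, function(e) e$best$score,
                                   0L))[1]]]
    out$best_score <- best$best$score
    out$second_best <- best$second
    out$identity_pct <- best$best$identity_pct
    if (length(pgroups) > 1) {
      out$status <- "ambiguous"
    } else {
      out$status <- "assigned"
      out$ccs_id <- ids[best$best_i]
      out$group_id <- pgroups
    }
    out
  })
  do.call(rbind, rows)
}

#' Locate a representative insert on the source genome
#'
#' Seed-and-extend mapping: exact k-mers of the representative are located
#' on both genome strands, seeds are clustered by diagonal, and the best
#' cluster is extended with a fitting alignment (the whole representative
#' against a genome window), so mutated insert ends count against
#' identity. Reports the 1-based inclusive locus, percent identity and
#' the GC content of the representative.
#'
#' @param representative [dna_seq] (must be at least `k_verify` bp).
#' @param genome Linear [dna_seq].
#' @param config An [identify_config()].
#' @return List with `status` (`ok` / `no_locus`), `locus`
#'   (c(start, end)), `strand`, `identity_pct`, `gc_pct`, `score`.
#' @export
verify_against_genome <- function(representative, genome,
                                  config = identify_config()) {
  rep <- as_dna_seq(representative)
  genome <- as_dna_seq(genome)
  k <- config$k_verify
  n <- nchar(rep$seq)
  if (n < k)
    stop(sprintf("representative (%d bp) shorter than seed length k=%d",
                 n, k), call. = FALSE)
  gss <- Biostrings::DNAString(genome$seq)
  L <- nchar(genome$seq)
  stride <- max(1L, (n - k) %/% 32L)
  qpos <- unique(c(seq(1L, n - k + 1L, by = stride), n - k + 1L))
  best <- NULL
  for (strand in c("+", "-")) {
    rep_s <- if (strand == "+") rep$seq else revcomp_chr(rep$seq)
    diags <- integer()
    for (qp in qpos) {
      kmer <- substr(rep_s, qp, qp + k - 1L)
      if (grepl("N", kmer, fixed = TRUE)) next
      hits <- IRanges::start(Biostrings::matchPattern(kmer, gss))
      if (length(hits) > 200) next  # uninformative repeat seed
      diags <- c(diags, hits - qp)
    }
    if (!length(diags)) next
    diags <- sort(diags)
    brk <- c(0L, which(diff(diags) > 100L), length(diags))
    sizes <- diff(brk)
    ci <- which.max(sizes)
    cluster <- diags[(brk[ci] + 1L):brk[ci + 1L]]
    d <- as.integer(round(stats::median(cluster)))
    ws <- max(1L, d + 1L - 150L)
    we <- min(L, d + n + 150L)
    if (we - ws + 1L < 1L) next
    a <- fit_align(rep_s, substr(genome$seq, ws, we), config$scheme)
    cand <- list(score = a$score, identity_pct = a$identity_pct,
                 strand = strand,
                 locus = c(ws + a$target_span[1], ws + a$target_span[2] - 1L))
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  gc <- gc_content(rep)
  if (is.null(best) || best$identity_pct < config$min_report_identity) {
    return(list(status = "no_locus", locus = c(NA_integer_, NA_integer_),
                strand = NA_character_, identity_pct = NA_real_,
                gc_pct = gc, score = NA_integer_))
  }
  c(list(status = "ok"), best[c("locus", "strand", "identity_pct")],
    list(gc_pct = gc, score = best$score))
}

#' Run the full clone-identification pipeline
#'
#' Vector trimming, deduplication of the full-length inserts, Sanger tag
#' assignment, and (when a genome is supplied) back-verification of each
#' unique representative, producing a per-group report and a per-clone
#' status table. Individual unusable reads are logged and statused; the
#' pipeline never aborts on a single bad read. When a truth manifest from
#' [sim_run()] is supplied a scoring block (assignment accuracy, group
#' count, exact-locus rate) is added.
#'
#' @param ccs List of [dna_seq] full-length reads (anonymous ids).
#' @param sanger List of [dna_seq] tag reads (`<clone>_F` / `<clone>_R`).
#' @param vector A [vector_model].
#' @param genome Optional linear [dna_seq].
#' @param truth Optional data.frame from [sim_run()]'s manifest (columns
#'   `ccs_id`, `clone_id`, `group_id`, `start`, `end`).
#' @param config An [identify_config()].
#' @return An `identification_report` object: list with `report` (one row
#'   per unique group), `clone_status`, `groups`, `insert_calls`,
#'   `verification`, and optionally `scoring`.
#' @export
run_identification <- function(ccs, sanger, vector, genome = NULL,
                               truth = NULL, config = identify_config()) {
  calls <- lapply(ccs, function(r)
    tryCatch(trim_vector(r, vector, config),
             error = function(e) structure(
               list(ccs_id = r$id, status = "error",
                    message = conditionMessage(e)), class = "insert_call")))
  ok <- Filter(function(x) identical(x$status, "ok"), calls)
  groups <- dedup(ok, config)
  assignments <- assign_tags(ok, sanger, config, groups = groups)

  verification <- lapply(groups, function(g) {
    if (is.null(genome)) return(NULL)
    tryCatch(verify_against_genome(g$representative, genome, config),
             error = function(e) list(status = "error",
                                      locus = c(NA, NA), strand = NA,
                                      identity_pct = NA_real_,
                                      gc_pct = NA_real_))
  })

  report <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    asg <- assignments[!is.na(assignments$group_id) &
                         assignments$group_id == g$group_id, , drop = FALSE]
    asg <- asg[order(asg$clone_id), , drop = FALSE]
    v <- verification[[i]]
    data.frame(
      group_id = g$group_id,
      clone_ids = paste(asg$clone_id, collapse = ","),
      fwd_tag_len = paste(asg$fwd_tag_len, collapse = ","),
      rev_tag_len = paste(asg$rev_tag_len, collapse = ","),
      full_length_bp = nchar(g$representative$seq),
      locus = if (!is.null(v) && identical(v$status, "ok"))
        sprintf("%d-%d", v$locus[1], v$locus[2]) else NA_character_,
      gc_pct = round(gc_content(g$representative), 2),
      identity_pct = if (!is.null(v) && identical(v$status, "ok"))
        round(v$identity_pct, 2) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  if (is.null(report))
    report <- data.frame(group_id = character(), clone_ids = character(),
                         fwd_tag_len = character(), rev_tag_len = character(),
                         full_length_bp = integer(), locus = character(),
                         gc_pct = numeric(), identity_pct = numeric(),
                         stringsAsFactors = FALSE)

  out <- list(report = report, clone_status = assignments, groups = groups,
              insert_calls = calls, verification = verification,
              config = config)

  if (!is.null(truth)) {
    grp_of_ccs <- unlist(lapply(groups, function(g)
      setNames(rep(g$group_id, length(g$members)), g$members)))
    considered <- assignments[assignments$status != "too_short", ,
                              drop = FALSE]
    correct <- 0L
    for (i in seq_len(nrow(considered))) {
      cl <- considered$clone_id[i]
      true_ccs <- truth$ccs_id[truth$clone_id == cl]
      if (length(true_ccs) == 1 &&
          considered$status[i] == "assigned" &&
          !is.na(grp_of_ccs[true_ccs]) &&
          identical(considered$group_id[i],
                    unname(grp_of_ccs[true_ccs]))) correct <- correct + 1L
    }
    exact_loci <- NA_real_
    if (!is.null(genome) && all(c("start", "end") %in% names(truth))) {
      hits <- 0L; tot <- 0L
      for (i in seq_along(groups)) {
        v <- verification[[i]]
        if (is.null(v) || !identical(v$status, "ok")) next
        m <- truth[truth$ccs_id %in% groups[[i]]$members, , drop = FALSE]
        tot <- tot + 1L
        if (any(m$start == v$locus[1] & m$end == v$locus[2]))
          hits <- hits + 1L
      }
      exact_loci <- if (tot) 100 * hits / tot else NA_real_
    }
    out$scoring <- list(
      n_clones = length(unique(assignments$clone_id)),
      n_considered = nrow(considered),
      n_assigned = sum(considered$status == "assigned"),
      assignment_accuracy_pct =
        if (nrow(considered)) 100 * correct / nrow(considered) else NA_real_,
      n_groups = length(groups),
      true_n_groups = length(unique(truth$group_id)),
      exact_locus_pct = exact_loci)
  }
  class(out) <- "identification_report"
  out
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("<identification_report> %d unique group(s) from %d read(s)\n",
              nrow(x$report), length(x$insert_calls)))
  print(x$report)
  if (!is.null(x$scoring)) {
    cat(sprintf("scoring: %d/%d clones assigned, accuracy %.1f%%, %d groups (truth %d)\n",
                x$scoring$n_assigned, x$scoring$n_considered,
                x$scoring$assignment_accuracy_pct, x$scoring$n_groups,
                x$scoring$true_n_groups))
  }
  invisible(x)
}

#' Write the identification report and per-clone status to TSV
#' @param x An `identification_report`.
#' @param report_path,status_path Output paths.
#' @export
write_identification_report <- function(x, report_path, status_path = NULL) {
  write_tsv_commented(x$report, report_path, comments = c(
    "clone identification report; loci are 1-based inclusive",
    "identity = 100 * matches / alignment columns (gaps included)"))
  if (!is.null(status_path))
    write_tsv_commented(x$clone_status, status_path,
                        comments = "per-clone tag-assignment status")
  invisible(x)
}
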