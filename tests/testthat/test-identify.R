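# helpers ------------------------------------------------------------------

ins_call <- function(id, seq) {
  structure(list(ccs_id = id, status = "ok",
                 insert = dna_seq(seq, id = paste0(id, "_insert"))),
            class = "insert_call")
}

make_read <- function(insert, vec, orientation = "+", id = "r1") {
  ins_used <- if (orientation == "+") insert else reverse_complement(insert)
  b <- vec$backbone$seq
  plasmid <- dna_seq(paste0(substr(b, 1, vec$cloning_site), ins_used,
                            substr(b, vec$cloning_site + 1, nchar(b))),
                     id = "p", topology = "circular")
  lin <- linearize(plasmid, default_enzymes()[[3]])  # HindIII
  dna_seq(lin$seq, id = id)
}

tag <- function(seq, id, valid = TRUE) {
  r <- dna_seq(seq, id = id)
  attr(r, "valid") <- valid
  r
}

# trim_vector ---------------------------------------------------------------

test_that("trim_vector recovers the insert from both read orientations", {
  vec <- default_vector()
  set.seed(501)
  ins <- rand_seq(800, gc = 75)
  for (orient in c("+", "-")) {
    read <- make_read(ins, vec, orient, id = "ccs_0001")
    call <- trim_vector(read, vec)
    expect_equal(call$status, "ok")
    expect_true(call$insert$seq %in% c(ins, reverse_complement(ins)))
    # and the read itself reverse-complemented must also work
    flipped <- dna_seq(reverse_complement(read$seq), id = "ccs_0002")
    call2 <- trim_vector(flipped, vec)
    expect_equal(call2$status, "ok")
    expect_true(call2$orientation_normalized != call$orientation_normalized)
    expect_true(call2$insert$seq %in% c(ins, reverse_complement(ins)))
  }
})

test_that("trim_vector flags empty vectors and foreign reads", {
  vec <- default_vector()
  bare <- linearize(vec$backbone, default_enzymes()[[3]])
  call <- trim_vector(dna_seq(bare$seq, id = "bare"), vec)
  expect_equal(call$status, "empty_vector")
  set.seed(502)
  call2 <- trim_vector(dna_seq(rand_seq(4000, gc = 75), id = "junk"), vec)
  expect_equal(call2$status, "vector_not_found")
})

test_that("trim_vector tolerates CCS-level noise", {
  vec <- default_vector()
  set.seed(503)
  ins <- rand_seq(1200, gc = 75)
  clean <- make_read(ins, vec, "+", id = "ccs_0001")
  noisy <- sim_ccs(clean, ccs_error_model(0.01, 0.005, 0.005), seed = 9)
  noisy$id <- "ccs_0001"
  call <- trim_vector(noisy, vec)
  expect_equal(call$status, "ok")
  expect_lt(abs(nchar(call$insert$seq) - 1200), 40)
})

# dedup ---------------------------------------------------------------------

test_that("dedup groups exact duplicates, reverse complements and overlaps", {
  set.seed(504)
  a <- rand_seq(900, gc = 75)
  b <- rand_seq(700, gc = 75)
  calls <- list(ins_call("ccs_0001", a),
                ins_call("ccs_0002", a),                        # exact dup
                ins_call("ccs_0003", reverse_complement(a)),    # rc dup
                ins_call("ccs_0004", substr(a, 1, 850)),        # nested
                ins_call("ccs_0005", b))
  groups <- dedup(calls)
  expect_equal(length(groups), 2L)
  expect_setequal(groups[[1]]$members,
                  c("ccs_0001", "ccs_0002", "ccs_0003", "ccs_0004"))
  expect_equal(groups[[2]]$members, "ccs_0005")
  # representative is the longest member
  expect_equal(nchar(groups[[1]]$representative$seq), 900L)
  # group ids follow the smallest member id
  expect_equal(groups[[1]]$group_id, "u1")
})

test_that("dedup output is invariant to input order", {
  set.seed(505)
  seqs <- c(replicate(3, rand_seq(600, gc = 75)))
  calls <- list(ins_call("ccs_0001", seqs[1]), ins_call("ccs_0002", seqs[1]),
                ins_call("ccs_0003", seqs[2]), ins_call("ccs_0004", seqs[3]),
                ins_call("ccs_0005", seqs[3]))
  g1 <- dedup(calls)
  g2 <- dedup(rev(calls))
  expect_identical(lapply(g1, `[[`, "members"),
                   lapply(g2, `[[`, "members"))
  expect_identical(vapply(g1, `[[`, "", "representative_id"),
                   vapply(g2, `[[`, "", "representative_id"))
})

test_that("dedup keeps distinct sequences apart and handles edge sizes", {
  set.seed(506)
  n <- 6
  calls <- lapply(seq_len(n), function(i)
    ins_call(sprintf("ccs_%04d", i), rand_seq(500, gc = 75)))
  expect_equal(length(dedup(calls)), n)
  expect_equal(dedup(list()), list())
  one <- dedup(calls[1])
  expect_equal(length(one), 1L)
  expect_equal(one[[1]]$members, "ccs_0001")
})

# assign_tags ---------------------------------------------------------------

test_that("assign_tags matches prefix, suffix and reverse-strand tags", {
  set.seed(507)
  inserts <- lapply(1:3, function(i)
    ins_call(sprintf("ccs_%04d", i), rand_seq(800, gc = 75)))
  s1 <- inserts[[1]]$insert$seq
  s2 <- inserts[[2]]$insert$seq
  s3 <- inserts[[3]]$insert$seq
  sanger <- list(
    tag(substr(s1, 1, 300), "c1_F"),
    tag(reverse_complement(substr(s1, 501, 800)), "c1_R"),
    tag(substr(s2, 1, 250), "c2_F"),
    tag(reverse_complement(substr(s2, 551, 800)), "c2_R"),
    tag(substr(s3, 1, 40), "c3_F"),   # short but usable
    tag(substr(s3, 1, 10), "c3_R"))   # below min_tag_len: excluded
  res <- assign_tags(inserts, sanger)
  res <- res[order(res$clone_id), ]
  expect_equal(res$status, rep("assigned", 3))
  expect_equal(res$ccs_id, c("ccs_0001", "ccs_0002", "ccs_0003"))
  expect_equal(res$identity_pct, rep(100, 3))
  expect_equal(res$fwd_tag_len, c(300L, 250L, 40L))
  expect_equal(res$rev_tag_len, c(300L, 250L, 10L))
})

test_that("clones with no usable read are too_short, not errors", {
  set.seed(508)
  inserts <- list(ins_call("ccs_0001", rand_seq(600, gc = 75)))
  sanger <- list(tag("ACGTACGT", "c1_F"),                 # too short
                 tag(strrep("ACGT", 20), "c1_R", valid = FALSE))
  res <- assign_tags(inserts, sanger)
  expect_equal(res$status, "too_short")
  expect_equal(res$ccs_id, "unassigned")
})

test_that("identical inserts in different groups are ambiguous; same group assigned", {
  set.seed(509)
  s <- rand_seq(700, gc = 75)
  inserts <- list(ins_call("ccs_0001", s), ins_call("ccs_0002", s))
  sanger <- list(tag(substr(s, 1, 300), "c1_F"))
  # no grouping: the duplicate is a competitor with zero margin
  res0 <- assign_tags(inserts, sanger)
  expect_equal(res0$status, "ambiguous")
  # with the dedup grouping the duplicate is the clone's own group
  res1 <- assign_tags(inserts, sanger, groups = dedup(inserts))
  expect_equal(res1$status, "assigned")
  expect_equal(res1$group_id, "u1")
})

test_that("foreign tags yield no_hit", {
  set.seed(510)
  inserts <- list(ins_call("ccs_0001", rand_seq(600, gc = 75)))
  sanger <- list(tag(rand_seq(300, gc = 20), "c1_F"))
  res <- assign_tags(inserts, sanger)
  expect_equal(res$status, "no_hit")
})

# verify_against_genome -----------------------------------------------------

test_that("verify_against_genome maps exact, mutated and foreign sequences", {
  g <- simulate_genome(60000, gc_target = 75.35, seed = 71)
  rep_plus <- dna_seq(substr(g$seq, 20001, 21500), id = "u1")
  v <- verify_against_genome(rep_plus, g)
  expect_equal(v$status, "ok")
  expect_equal(v$locus, c(20001L, 21500L))
  expect_equal(v$strand, "+")
  expect_equal(v$identity_pct, 100)
  expect_equal(v$gc_pct, gc_content(rep_plus))

  rep_minus <- reverse_complement(rep_plus)
  v2 <- verify_against_genome(rep_minus, g)
  expect_equal(v2$status, "ok")
  expect_equal(v2$locus, c(20001L, 21500L))
  expect_equal(v2$strand, "-")
  expect_equal(v2$identity_pct, 100)

  noisy <- sim_ccs(rep_plus, ccs_error_model(0.01, 0, 0), seed = 72)
  v3 <- verify_against_genome(dna_seq(noisy$seq, id = "u1"), g)
  expect_equal(v3$status, "ok")
  expect_lt(v3$identity_pct, 100)
  expect_gt(v3$identity_pct, 97)

  set.seed(511)
  v4 <- verify_against_genome(dna_seq(rand_seq(1500, gc = 75), id = "ux"), g)
  expect_equal(v4$status, "no_locus")
  expect_error(verify_against_genome(dna_seq("ACGT", id = "tiny"), g),
               "shorter than seed length")
})

# run_identification --------------------------------------------------------

test_that("run_identification recovers a small zero-error library exactly", {
  g <- simulate_genome(80000, gc_target = 75.35, seed = 81)
  vec <- default_vector()
  lib <- build_library(g, vec, n_unique = 4, duplication = c(2L, 1L, 1L, 3L),
                       p_cut = 0.1, min_bp = 200, max_bp = 2500, seed = 82)
  panel <- min_enzyme_panel(lapply(lib$clones, `[[`, "plasmid"))
  run <- sim_run(lib$clones, vec, ccs_error_model(0, 0, 0),
                 sanger_model(h0 = 0, sub_rate = 0), panel$assignment,
                 seed = 83)
  ident <- run_identification(run$ccs, run$sanger, vec, genome = g,
                              truth = run$manifest)
  expect_equal(nrow(ident$report), 4L)
  expect_equal(ident$scoring$n_groups, 4L)
  expect_equal(ident$scoring$true_n_groups, 4L)
  expect_equal(ident$scoring$assignment_accuracy_pct, 100)
  expect_equal(ident$scoring$exact_locus_pct, 100)
  expect_equal(ident$report$identity_pct, rep(100, 4))
  # loci in the report match the truth manifest
  truth_loci <- unique(sprintf("%d-%d", run$manifest$start,
                               run$manifest$end))
  expect_setequal(ident$report$locus, truth_loci)
  # every clone appears exactly once across the report's groups
  listed <- unlist(strsplit(ident$report$clone_ids, ","))
  expect_setequal(listed, lib$manifest$clone_id)
  expect_equal(anyDuplicated(listed), 0L)
})

test_that("clone-level read failures degrade gracefully, not fatally", {
  g <- simulate_genome(80000, gc_target = 75.35, seed = 81)
  vec <- default_vector()
  lib <- build_library(g, vec, n_unique = 4, duplication = c(2L, 1L, 1L, 3L),
                       p_cut = 0.1, min_bp = 200, max_bp = 2500, seed = 82)
  panel <- min_enzyme_panel(lapply(lib$clones, `[[`, "plasmid"))
  run <- sim_run(lib$clones, vec, ccs_error_model(0, 0, 0),
                 sanger_model(h0 = 0, sub_rate = 0), panel$assignment,
                 seed = 83)
  cripple <- function(r, n) { r$seq <- substr(r$seq, 1, n); r }
  sanger <- run$sanger
  ids <- vapply(sanger, `[[`, "", "id")
  victim <- run$manifest$clone_id[1]     # lose the forward read only
  dead <- run$manifest$clone_id[2]       # lose both reads
  sanger[[which(ids == paste0(victim, "_F"))]] <-
    cripple(sanger[[which(ids == paste0(victim, "_F"))]], 10)
  sanger[[which(ids == paste0(dead, "_F"))]] <-
    cripple(sanger[[which(ids == paste0(dead, "_F"))]], 8)
  sanger[[which(ids == paste0(dead, "_R"))]] <-
    cripple(sanger[[which(ids == paste0(dead, "_R"))]], 8)
  ident <- run_identification(run$ccs, sanger, vec, genome = g,
                              truth = run$manifest)
  st <- ident$clone_status
  expect_equal(st$status[st$clone_id == victim], "assigned")
  expect_equal(st$status[st$clone_id == dead], "too_short")
  # too_short clones are excluded read-wise from the accuracy denominator
  expect_equal(ident$scoring$n_considered, 6L)
  expect_equal(ident$scoring$assignment_accuracy_pct, 100)
  # all 4 groups are still present: the CCS pool is unaffected
  expect_equal(nrow(ident$report), 4L)
})

test_that("run_identification handles an empty CCS pool", {
  vec <- default_vector()
  sanger <- list(tag(strrep("ACGT", 30), "c1_F"))
  ident <- run_identification(list(), sanger, vec)
  expect_equal(nrow(ident$report), 0L)
  expect_equal(ident$clone_status$status, "no_hit")
})

test_that("identification report writes and reads back", {
  g <- simulate_genome(60000, gc_target = 75.35, seed = 91)
  vec <- default_vector()
  lib <- build_library(g, vec, n_unique = 2, duplication = c(1L, 2L),
                       p_cut = 0.1, min_bp = 200, max_bp = 2000, seed = 92)
  panel <- min_enzyme_panel(lapply(lib$clones, `[[`, "plasmid"))
  run <- sim_run(lib$clones, vec, ccs_error_model(0, 0, 0),
                 sanger_model(h0 = 0, sub_rate = 0), panel$assignment,
                 seed = 93)
  ident <- run_identification(run$ccs, run$sanger, vec, genome = g,
                              truth = run$manifest)
  rp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".tsv")
  write_identification_report(ident, rp, sp)
  back <- read.table(rp, header = TRUE, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(back), 2L)
  expect_equal(back$group_id, ident$report$group_id)
  expect_true(file.exists(sp))
})
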