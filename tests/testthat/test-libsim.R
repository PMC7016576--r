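test_that("simulate_genome is reproducible and hits its GC target", {
  g1 <- simulate_genome(50000, gc_target = 75.35, seed = 7)
  g2 <- simulate_genome(50000, gc_target = 75.35, seed = 7)
  g3 <- simulate_genome(50000, gc_target = 75.35, seed = 8)
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq, g3$seq))
  expect_equal(nchar(g1$seq), 50000L)
  # realized GC within the exact binomial 99.9% interval of the target
  n <- 50000; p <- 0.7535
  bounds <- 100 * qbinom(c(0.0005, 0.9995), n, p) / n
  gc <- gc_content(g1)
  expect_gte(gc, bounds[1])
  expect_lte(gc, bounds[2])
  expect_error(simulate_genome(50000, gc_target = 0), "strictly between")
  expect_error(simulate_genome(50000, gc_target = 100), "strictly between")
  expect_error(simulate_genome(500))
})

test_that("partial_digest at p_cut = 1 cuts every site; at 0, none", {
  sau <- default_enzymes()[[1]]
  g <- dna_seq(paste0(strrep("A", 4), "GATC", strrep("C", 4), "GATC",
                      strrep("T", 4)))   # sites at 4 and 12
  frags <- partial_digest(g, sau, p_cut = 1, seed = 1)
  expect_equal(length(frags), 3L)
  expect_equal(vapply(frags, `[[`, "", "seq"),
               c("AAAA", "GATCCCCC", "GATCTTTT"))
  expect_equal(vapply(frags, `[[`, 0L, "start"), c(1L, 5L, 13L))
  expect_equal(vapply(frags, `[[`, 0L, "end"), c(4L, 12L, 20L))
  expect_equal(paste(vapply(frags, `[[`, "", "seq"), collapse = ""), g$seq)

  none <- partial_digest(g, sau, p_cut = 0, seed = 1)
  expect_equal(length(none), 1L)
  expect_equal(none[[1]]$seq, g$seq)
})

test_that("circular digestion wraps across the origin", {
  sau <- default_enzymes()[[1]]
  g <- dna_seq(paste0(strrep("A", 4), "GATC", strrep("C", 4), "GATC",
                      strrep("T", 4)), topology = "circular")
  frags <- partial_digest(g, sau, p_cut = 1, seed = 1)
  expect_equal(length(frags), 2L)
  seqs <- vapply(frags, `[[`, "", "seq")
  expect_true("GATCCCCC" %in% seqs)
  expect_true("GATCTTTTAAAA" %in% seqs)   # wrapped terminal piece
  expect_equal(sum(nchar(seqs)), nchar(g$seq))
})

test_that("fragment coordinates index back into the source genome", {
  set.seed(301)
  g <- simulate_genome(20000, gc_target = 60, seed = 11)
  frags <- partial_digest(g, p_cut = 0.3, seed = 12)
  expect_gt(length(frags), 1)
  for (f in frags) {
    expect_equal(f$seq, substr(g$seq, f$start, f$end))
    expect_equal(f$source_id, g$id)
  }
  # fragments tile the genome
  expect_equal(sum(vapply(frags, function(f) nchar(f$seq), 0L)),
               nchar(g$seq))
})

test_that("realized cut count matches p_cut within Monte-Carlo error", {
  g <- simulate_genome(30000, gc_target = 75.35, seed = 21)
  k <- length(find_sites(g, default_enzymes()[[1]])$positions)
  expect_gt(k, 20)
  p <- 0.1; reps <- 400
  cuts <- vapply(seq_len(reps), function(i)
    length(partial_digest(g, p_cut = p, seed = 1000 + i)) - 1L, 0L)
  # fragments = realized cuts + 1 on a linear molecule
  se <- sqrt(reps * k * p * (1 - p))
  expect_lt(abs(sum(cuts) - reps * k * p), 4 * se)
})

test_that("size_select keeps the inclusive window", {
  mk <- function(n) list(seq = strrep("A", n), start = 1L, end = n,
                         source_id = "g")
  frags <- lapply(c(99, 100, 101, 2999, 3000, 3001), mk)
  kept <- size_select(frags, min_bp = 100, max_bp = 3000)
  expect_equal(vapply(kept, function(f) nchar(f$seq), 0L),
               c(100L, 101L, 2999L, 3000L))
  expect_error(size_select(frags, min_bp = 10, max_bp = 5))
})

test_that("clone_into_vector inserts verbatim in a seeded orientation", {
  vec <- default_vector()
  set.seed(302)
  ins <- rand_seq(500, gc = 75)
  res <- clone_into_vector(list(seq = ins, start = 1L, end = 500L,
                                source_id = "g"), vec, seed = 5)
  expect_equal(res$plasmid$topology, "circular")
  expect_equal(nchar(res$plasmid$seq), nchar(vec$backbone$seq) + 500L)
  placed <- substr(res$plasmid$seq, vec$cloning_site + 1,
                   vec$cloning_site + 500)
  if (res$orientation == "+") expect_equal(placed, ins)
  else expect_equal(placed, reverse_complement(ins))
  # same seed, same orientation; backbone flanks intact
  res2 <- clone_into_vector(ins, vec, seed = 5)
  expect_equal(res2$orientation, res$orientation)
  expect_equal(substr(res$plasmid$seq, 1, vec$cloning_site),
               substr(vec$backbone$seq, 1, vec$cloning_site))
  expect_error(clone_into_vector("", vec), "empty fragment")
})

test_that("build_library produces the requested duplication structure", {
  g <- simulate_genome(120000, gc_target = 75.35, seed = 31)
  vec <- default_vector()
  dup <- c(3L, 8L, 2L, 2L, 1L, 1L, 2L)
  lib <- build_library(g, vec, n_unique = 7, duplication = dup,
                       p_cut = 0.1, min_bp = 200, max_bp = 3000, seed = 32)
  expect_equal(length(lib$clones), 19L)
  expect_equal(nrow(lib$manifest), 19L)
  expect_equal(as.integer(table(lib$manifest$group_id)[paste0("g", 1:7)]),
               as.integer(dup))
  # inserts are verbatim genome substrings at their manifest locus
  for (cl in lib$clones) {
    m <- lib$manifest[lib$manifest$clone_id == cl$clone_id, ]
    expect_equal(cl$insert$seq, substr(g$seq, m$start, m$end))
    expect_equal(nchar(cl$insert$seq), m$insert_len)
    expect_gte(m$insert_len, 200L)
    expect_lte(m$insert_len, 3000L)
    # every insert starts at a Sau3AI cut or the genome start
    expect_true(m$start == 1L ||
                  substr(g$seq, m$start, m$start + 3) == "GATC")
    # plasmid carries the insert in the manifest orientation
    placed <- substr(cl$plasmid$seq, vec$cloning_site + 1,
                     vec$cloning_site + m$insert_len)
    expect_equal(placed, if (m$strand == "+") cl$insert$seq
                 else reverse_complement(cl$insert$seq))
  }
  # distinct loci: pairwise overlap below half the shorter insert
  u <- unique(lib$manifest[c("group_id", "start", "end")])
  expect_equal(nrow(u), 7L)
  for (i in 1:6) for (j in (i + 1):7) {
    ov <- min(u$end[i], u$end[j]) - max(u$start[i], u$start[j]) + 1L
    shorter <- min(u$end[i] - u$start[i], u$end[j] - u$start[j]) + 1L
    expect_lt(ov, 0.5 * shorter)
  }
  # bit-reproducible
  lib2 <- build_library(g, vec, n_unique = 7, duplication = dup,
                        p_cut = 0.1, min_bp = 200, max_bp = 3000, seed = 32)
  expect_identical(lib$manifest, lib2$manifest)
})

test_that("build_library honours clone_ids and fails loudly when starved", {
  g <- simulate_genome(60000, gc_target = 75.35, seed = 41)
  lib <- build_library(g, default_vector(), n_unique = 2,
                       duplication = c(2L, 1L), seed = 42,
                       clone_ids = list(c("x1", "x2"), "x9"))
  expect_equal(lib$manifest$clone_id, c("x1", "x2", "x9"))
  expect_error(
    build_library(g, default_vector(), n_unique = 3,
                  duplication = c(1L, 1L, 1L), p_cut = 0.5,
                  min_bp = 2999, max_bp = 3000, seed = 43,
                  max_molecules = 5L),
    "eligible fragment")
})

test_that("write_manifest emits a commented TSV that reads back", {
  g <- simulate_genome(60000, gc_target = 75, seed = 51)
  lib <- build_library(g, default_vector(), n_unique = 2,
                       duplication = c(1L, 1L), seed = 52)
  path <- tempfile(fileext = ".tsv")
  write_manifest(lib$manifest, path)
  expect_true(startsWith(readLines(path, n = 1), "#"))
  back <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE)
  expect_equal(back, lib$manifest)
})
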