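b62 <- load_matrix("blosum62")
g102 <- gap_model(10, 2)

test_that("reference engine reproduces hand-checked and enumerated scores", {
  expect_identical(sw_reference("A", "", b62, g102), 0L)
  expect_identical(sw_reference("A", "A", b62, g102), 4L)
  toy <- toy_matrix()
  # frozen from the exhaustive local-alignment enumerator
  expect_identical(sw_reference("GGTT", "GGATT", toy, gap_model(2, 1)), 9L)
  expect_identical(sw_reference("ACGT", "ACT", toy, gap_model(2, 1)), 6L)
  expect_identical(sw_reference("HEAGAW", "PAWHEA", b62, g102), 17L)
  expect_identical(sw_reference("MKV", "MKV", b62, g102), 14L)
  # and live against the enumerator on random tiny pairs
  toy_fn <- function(a, b) if (a == b) 3 else -3
  set.seed(101)
  for (rep in 1:15) {
    q <- paste(sample(c("A", "C", "G", "T"), sample(2:5, 1), TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), TRUE), collapse = "")
    rho <- sample(0:4, 1); sigma <- sample(1:3, 1)
    expect_identical(sw_reference(q, s, toy, gap_model(rho, sigma)),
                     as.integer(brute_local_sw(q, s, toy_fn, rho, sigma)),
                     info = paste(q, s, rho, sigma))
  }
})

test_that("reference engine agrees with an independent aligner", {
  # Biostrings' local pairwiseAlignment is a third, independent route
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(202)
  for (rep in 1:25) {
    q <- random_protein(sample(4:30, 1))
    s <- random_protein(sample(4:60, 1))
    rho <- sample(c(5, 10, 12), 1); sigma <- sample(1:3, 1)
    ours <- sw_reference(q, s, b62, gap_model(rho, sigma))
    theirs <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = rho, gapExtension = sigma,
      scoreOnly = TRUE)
    expect_equal(as.numeric(ours), as.numeric(theirs),
                 info = paste(q, s, rho, sigma))
  }
})

test_that("tiled engine is score-identical to the reference", {
  expect_identical(sw_tiled("A", "A", b62, g102)$score, 4L)
  set.seed(303)
  gaps <- list(gap_model(10, 2), gap_model(5, 1), gap_model(0, 4))
  mats <- list(b62, load_matrix("blosum50"))
  for (rep in 1:60) {
    q <- random_protein(sample(1:16, 1))
    s <- random_protein(sample(1:160, 1))
    gp <- gaps[[1 + rep %% 3]]
    m <- mats[[1 + rep %% 2]]
    expect_identical(sw_tiled(q, s, m, gp)$score, sw_reference(q, s, m, gp),
                     info = paste(rep, q))
  }
  # non-default tile geometries
  set.seed(304)
  for (cfg in list(tile_config(1, 4), tile_config(4, 8), tile_config(3, 4))) {
    for (rep in 1:10) {
      q <- random_protein(sample(1:16, 1))
      s <- random_protein(sample(1:80, 1))
      expect_identical(sw_tiled(q, s, b62, g102, tiles = cfg)$score,
                       sw_reference(q, s, b62, g102))
    }
  }
})

test_that("padding is score-neutral and pads never raise H above zero", {
  set.seed(404)
  for (rep in 1:10) {
    q <- random_protein(sample(1:14, 1))
    s <- random_protein(5)  # padded to 8 with K=4
    expect_identical(sw_tiled(q, s, b62, g102)$score,
                     sw_reference(q, s, b62, g102))
  }
  # a subject of pure padding in a multi-lane layout scores 0 for that lane
  layout <- interleave_group(c("MKVAW"), K = 4, group_size = 2L)
  prof <- build_query_profile("MKV", b62)
  r <- sw_tiled("MKV", matrix = b62, gaps = g102, profile = prof,
                layout = layout, lane = 2)
  expect_identical(r$score, 0L)
})

test_that("scores are nonnegative, symmetric, and monotone", {
  set.seed(505)
  for (rep in 1:20) {
    q <- random_protein(sample(1:12, 1))
    s <- random_protein(sample(1:40, 1))
    sc <- sw_reference(q, s, b62, g102)
    expect_gte(sc, 0L)
    # symmetry of the local score under a symmetric matrix
    expect_identical(sc, sw_reference(s, q, b62, g102))
    # appending subject residues never decreases the score
    expect_gte(sw_reference(q, paste0(s, random_protein(5)), b62, g102), sc)
    # raising gap penalties never increases the score
    expect_lte(sw_reference(q, s, b62, gap_model(12, 2)), sc)
    expect_lte(sw_reference(q, s, b62, gap_model(10, 3)), sc)
  }
  # zero iff no positive-scoring pair: a matrix with no positive off-diagonal
  toy <- toy_matrix()
  expect_identical(sw_reference("A", "C", toy, gap_model(2, 1)), 0L)
  expect_gt(sw_reference("A", "CA", toy, gap_model(2, 1)), 0L)
})

test_that("tile memory discipline: carries cross columns only via the buffer", {
  set.seed(606)
  q <- random_protein(13)  # Qpad = 16
  s <- random_protein(21)  # padded_len = 24, 6 tile columns
  r <- sw_tiled(q, s, b62, g102)
  st <- r$stats
  qpad <- 16; ncols <- 6
  # one H + one E write per row per tile column, never more than Qpad per
  # column of tiles per matrix (the shared buffer is reused across columns)
  expect_identical(st$buffer_writes, 2 * qpad * ncols)
  expect_identical(st$buffer_reads, 2 * qpad * ncols)
  expect_identical(st$tile_cols, as.integer(ncols))
  # 2 matrices x 2 bytes per buffered query position
  expect_identical(st$peak_buffer_bytes, 4 * qpad)
  expect_identical(st$cells, qpad * 24)
  expect_false(st$overflow)
})

test_that("16-bit overflow is flagged without corrupting the score", {
  hot <- substitution_matrix(
    matrix(c(9000L, -9000L, -9000L, 9000L), 2, 2,
           dimnames = list(c("A", "G"), c("A", "G"))), "hot")
  q <- paste(rep("A", 8), collapse = "")
  s <- paste(rep("A", 12), collapse = "")
  r <- sw_tiled(q, s, hot, gap_model(2, 1))
  expect_identical(r$score, sw_reference(q, s, hot, gap_model(2, 1)))
  expect_identical(r$score, 8L * 9000L)
  expect_true(r$stats$overflow)
})

test_that("queries beyond the budget are rejected by the tiled path", {
  budget <- memory_budget(16384, 256)  # Q_max = 16
  q16 <- random_protein(16)
  set.seed(707)
  expect_identical(
    sw_tiled(q16, "MKVAW", b62, g102, budget = budget)$score,
    sw_reference(q16, "MKVAW", b62, g102))
  expect_error(sw_tiled(random_protein(17), "MKVAW", b62, g102,
                        budget = budget), "Q_max")
})

test_that("batch search equals a map of the reference over all subjects", {
  set.seed(808)
  db <- synth_protein_db(40, law = "uniform", min_len = 5, max_len = 120,
                         seed = 99)
  q <- random_protein(12)
  res <- sw_batch(q, db, b62, g102, exec_config(warp_size = 8L))
  expect_identical(nrow(res), 40L)
  expect_identical(attr(res, "path"), "tiled_short_query")
  direct <- vapply(seq_len(db$n), function(i) {
    sw_reference(q, db$residues[[i]], b62, g102)
  }, 0L)
  names(direct) <- db$ids
  expect_identical(res$score, unname(direct[res$subject_id]))
  # ranked by descending score
  expect_true(all(diff(res$score) <= 0))
  expect_identical(res$rank, seq_len(40L))
})

test_that("batch search: self-match ranks first, duplicates tie id-ordered", {
  q <- "MKVAWGHEE"
  db <- sequence_db(c("dup_b", "self", "dup_a"),
                    c("GHEWK", "MKVAWGHEE", "GHEWK"))
  res <- sw_batch(q, db, b62, g102)
  expect_identical(res$subject_id[1], "self")
  expect_identical(res$score[1], sw_reference(q, q, b62, g102))
  dups <- res[res$subject_id %in% c("dup_a", "dup_b"), ]
  expect_identical(dups$score[1], dups$score[2])
  expect_identical(dups$subject_id, c("dup_a", "dup_b"))
})

test_that("batch search falls back for long queries and long subjects", {
  set.seed(909)
  db <- synth_protein_db(6, law = "uniform", min_len = 10, max_len = 30,
                         seed = 7)
  qlong <- random_protein(40)  # > Q_max = 16
  res <- sw_batch(qlong, db, b62, g102)
  expect_identical(attr(res, "path"), "reference_fallback")
  direct <- vapply(seq_len(db$n), function(i) {
    sw_reference(qlong, db$residues[[i]], b62, g102)
  }, 0L)
  names(direct) <- db$ids
  expect_identical(res$score, unname(direct[res$subject_id]))
  # subjects above the intertask threshold take the serial reference path
  # but still score identically
  mix <- sequence_db(c("short", "long"),
                     c("MKVAW", random_protein(50)))
  q <- random_protein(10)
  res2 <- sw_batch(q, mix, b62, g102,
                   exec_config(length_threshold = 40L, warp_size = 4L))
  direct2 <- vapply(seq_len(mix$n), function(i) {
    sw_reference(q, mix$residues[[i]], b62, g102)
  }, 0L)
  names(direct2) <- mix$ids
  expect_identical(res2$score, unname(direct2[res2$subject_id]))
})
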