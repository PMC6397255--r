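# Tile/domain model: reverse complement, design-rule validation, the
# strand-displacement activation cascade, and crossover geometry.

test_that("reverse_complement handles the cascade segments, empties, and errors", {
  expect_identical(reverse_complement("TGAACC"), "GGTTCA")
  expect_identical(reverse_complement("GTGACA"), "TGTCAC")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement(c("A", "ACGT")), c("T", "ACGT"))
  expect_error(reverse_complement("ACGU"), "non-DNA")
  expect_error(reverse_complement(42))
})

test_that("reverse_complement is an involution and matches a brute-force oracle", {
  withr::with_seed(11, {
    for (i in 1:30) {
      s <- random_dna(sample(1:60, 1))
      expect_identical(reverse_complement(reverse_complement(s)), s)
      expect_identical(reverse_complement(s), oracle_revcomp(s))
    }
  })
})

test_that("generator-built tiles pass validation; single-base corruptions are caught", {
  sys <- generate_tile_set(seed = 3)
  expect_s3_class(sys, "reaction_system")
  expect_identical(nrow(validate_system(sys)), 0L)

  mutate_base <- function(seq, pos) {
    old <- substr(seq, pos, pos)
    new <- setdiff(c("A", "C", "G", "T"), old)[1L]
    paste0(substr(seq, 1, pos - 1L), new,
           substr(seq, pos + 1L, nchar(seq)))
  }

  # one base of a declared sticky end -> exactly one sticky_pair_mismatch
  bad <- sys
  a2 <- bad$tiles$A$strands$a2
  bad$tiles$A$strands$a2 <- strand_spec("a2", mutate_base(a2$sequence, 2L))
  v <- validate_tile(bad$tiles$A, system = bad)
  expect_identical(nrow(v), 1L)
  expect_identical(v$rule, "sticky_pair_mismatch")

  # one base of a hairpin stem half -> stem_mismatch
  bad2 <- sys
  a4 <- bad2$tiles$A$strands$a4
  bad2$tiles$A$strands$a4 <- strand_spec("a4", mutate_base(a4$sequence, 8L))
  v2 <- validate_tile(bad2$tiles$A, system = bad2)
  expect_true("stem_mismatch" %in% v2$rule)
})

test_that("validation flags structural defects as data, not errors", {
  sys <- generate_tile_set(seed = 5)
  tile <- sys$tiles$A
  # drop a strand
  t3 <- tile
  t3$strands <- t3$strands[1:3]
  expect_true("strand_count" %in% validate_tile(t3)$rule)
  # toehold covered by a stem duplex
  t4 <- tile
  t4$domains <- rbind(t4$domains,
                      domain_annotation("a3", 0L, 6L, "stem"),
                      domain_annotation("a3", 6L, 12L, "stem"))
  expect_true("toehold_not_single_stranded" %in% validate_tile(t4)$rule)
})

test_that("sdr_cascade closes in three events and regenerates the initiator role", {
  sys <- generate_tile_set(seed = 1)
  ev <- sdr_cascade(sys)
  expect_identical(nrow(ev), 3L)
  expect_identical(ev$target, c("A", "B", "A"))
  expect_true(ev$closes[3L])
  expect_false(any(ev$closes[1:2]))
  # closure: event-3 invading segment is exactly the initiator's active segment
  expect_identical(ev$segment[3L], "GTGACA")
  iseq <- sys$initiator$sequence
  expect_identical(substr(iseq, nchar(iseq) - 5L, nchar(iseq)), ev$segment[3L])
})

test_that("cascade preconditions and failure modes", {
  sys <- generate_tile_set(seed = 2)
  # no initiator -> no polymerization, empty event list
  ctrl <- reaction_system(sys$tiles, initiator = NULL)
  expect_identical(nrow(sdr_cascade(ctrl)), 0L)
  # scrambled B toehold -> cascade halts after A activation (1-event prefix)
  scram <- sys
  b3 <- scram$tiles$B$strands$b3
  L <- nchar(b3$sequence)
  scram$tiles$B$strands$b3 <- strand_spec(
    "b3", paste0(substr(b3$sequence, 1L, L - 6L), "AAAAAA"))
  ev <- sdr_cascade(scram)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$target, "A")
  # empty system is a precondition error
  expect_error(sdr_cascade(reaction_system(list(), sys$initiator)), "empty")
})

test_that("crossover separation maps to half-turn parity and binding side", {
  r26 <- crossover_turns_and_side(26)
  expect_equal(r26$turns, 26 / 10.5, tolerance = 1e-12)
  expect_equal(r26$nearest_half_turn, 2.5)
  expect_identical(r26$side, "same")

  r32 <- crossover_turns_and_side(32)
  expect_equal(r32$nearest_half_turn, 3)
  expect_identical(r32$side, "opposite")

  r21 <- crossover_turns_and_side(21)
  expect_equal(r21$turns, 2)
  expect_identical(r21$side, "opposite")

  expect_error(crossover_turns_and_side(0), "> 0")
})

test_that("crossover side call is scale-consistent", {
  withr::with_seed(7, {
    for (i in 1:20) {
      sep <- sample(5:60, 1)
      g1 <- helix_geometry()
      g2 <- helix_geometry(bp_per_turn = 2 * g1$bp_per_turn)
      a <- crossover_turns_and_side(sep, g1)
      b <- crossover_turns_and_side(2 * sep, g2)
      expect_equal(a$turns, b$turns)
      expect_identical(a$side, b$side)
    }
  })
})

test_that("tile dimensions follow the helix geometry", {
  sys <- generate_tile_set(seed = 1)
  d <- tile_dimensions(sys$tiles$A)
  expect_equal(unname(d["length_nm"]), 47 * 0.34, tolerance = 1e-12)
  expect_equal(unname(d["width_nm"]), 2 * 2.25 + 0.5)

  t24 <- sys$tiles$A
  t24$tile_length_bp <- 24L
  expect_equal(unname(tile_dimensions(t24)["length_nm"]), 8.16)

  t0 <- sys$tiles$A
  t0$tile_length_bp <- 0L
  expect_error(tile_dimensions(t0), "> 0")
})

test_that("symmetry score counts repeated k-mers", {
  expect_identical(symmetry_score("ACGTACGT", 4), 1L)
  expect_identical(symmetry_score("ACGT", 4), 0L)
  expect_identical(symmetry_score("AACCGGTT", 1), 4L)
  expect_error(symmetry_score("ACGT", 5), "<=")
  expect_error(symmetry_score("ACGT", 0), "> 0")
})
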