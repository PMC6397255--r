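# Fixture generators: tile sequence sets, AFM length samples, trace batches.

test_that("generated systems are sound across seeds", {
  for (seed in seq(1, 50, by = 2)) {
    sys <- generate_tile_set(seed = seed)
    expect_identical(nrow(validate_system(sys)), 0L)
    ev <- sdr_cascade(sys)
    expect_identical(nrow(ev), 3L)
    expect_true(ev$closes[3L])
  }
})

test_that("generation is deterministic and honors the printed segments", {
  s1 <- generate_tile_set(seed = 9)
  s2 <- generate_tile_set(seed = 9)
  expect_identical(s1, s2)

  A <- s1$tiles$A
  B <- s1$tiles$B
  toehold <- function(t) {
    d <- t$domains[t$domains$role == "toehold", ]
    substr(t$strands[[d$strand]]$sequence, d$start + 1, d$end)
  }
  loop <- function(t) {
    d <- t$domains[t$domains$role == "loop", ]
    substr(t$strands[[d$strand]]$sequence, d$start + 1, d$end)
  }
  expect_identical(toehold(A), "TGTCAC")
  expect_identical(loop(A), "TGAACC")
  expect_identical(toehold(B), "GGTTCA")
  expect_identical(loop(B), "GTGACA")
  iseq <- s1$initiator$sequence
  expect_identical(substr(iseq, nchar(iseq) - 5, nchar(iseq)), "GTGACA")
  # the printed pairings are exact reverse complements
  expect_identical(reverse_complement("TGAACC"), toehold(B))
  expect_identical(reverse_complement(toehold(A)), "GTGACA")
})

test_that("reserved segments appear nowhere else in the strand set", {
  sys <- generate_tile_set(seed = 13)
  all_seqs <- vapply(c(sys$tiles$A$strands, sys$tiles$B$strands), `[[`, "",
                     "sequence")
  counts <- vapply(c("TGTCAC", "TGAACC", "GGTTCA", "GTGACA"), function(p)
    sum(vapply(all_seqs, function(s) {
      if (nchar(s) < 6) return(0L)
      st <- seq_len(nchar(s) - 5L)
      sum(substring(s, st, st + 5L) == p)
    }, 0L)), 0L)
  expect_identical(unname(counts), rep(1L, 4))
})

test_that("infeasible constraints are refused", {
  expect_error(generate_tile_set(seed = 1, stem_len = 3), "infeasible")
  expect_error(generate_tile_set(seed = 1, loop_len = 4), "infeasible")
})

test_that("configurable stem and loop lengths still produce closed cascades", {
  sys <- generate_tile_set(seed = 4, stem_len = 12, loop_len = 8)
  expect_identical(nrow(validate_system(sys)), 0L)
  expect_true(any(sdr_cascade(sys)$closes))
})

test_that("AFM sampling is the identity at zero noise and applies the floor", {
  pop <- tiny_pop(ratio = 3, n = 400, seed = 5)
  clean <- gen_afm_lengths(pop, noise_model(0, 0), tile_length_nm = 16,
                           seed = 1)
  expect_true(all(clean$values %% 16 == 0))
  expect_identical(sort(clean$values),
                   sort(chain_contour_lengths(pop, 16)[
                     chain_contour_lengths(pop, 16) > 0]))
  # floor removes unreacted initiators (0 nm) from the sample
  floored <- gen_afm_lengths(pop, noise_model(0, 10), 16, seed = 1)
  expect_true(all(floored$values >= 10))
  expect_identical(attr(floored, "n_dropped"), sum(pop$tiles == 0L))
})

test_that("measurement noise inflates the observed PDI", {
  # same chains measured with and without noise: the added measurement
  # variance inflates Lw relative to Ln
  pop <- simulate_living(2, 3000, seed = 6)
  noiseless <- dispersity_summary(gen_afm_lengths(pop, noise_model(0, 0),
                                                  16, seed = 2))
  noisy <- dispersity_summary(gen_afm_lengths(pop, noise_model(16, 0.1),
                                              16, seed = 2))
  expect_gt(noisy$PDI, noiseless$PDI)
})

test_that("trace batches mirror the population's A counts", {
  pop <- tiny_pop(ratio = 1, n = 60, seed = 8)
  traces <- gen_trace_batch(pop, max_traces = Inf, noise_sd = 0.1, seed = 3)
  expect_identical(length(traces), 60L)
  expect_identical(vapply(traces, function(t) t$meta$n_true_steps, 0L),
                   chain_composition(pop)$n_A)
  t2 <- gen_trace_batch(pop, max_traces = Inf, noise_sd = 0.1, seed = 3)
  expect_identical(traces, t2)
  sub <- gen_trace_batch(pop, max_traces = 10, seed = 4)
  expect_identical(length(sub), 10L)
})

test_that("end-to-end: simulated labels survive the bleaching pipeline", {
  # ratio-1 population, high SNR: histogram mode = population A-count mode
  pop <- simulate_living(1, 150, seed = 12)
  traces <- gen_trace_batch(pop, max_traces = Inf, noise_sd = 0.1, seed = 5)
  h <- step_histogram(traces)
  mode_called <- h$k[which.max(h$freq)]
  nA <- chain_composition(pop)$n_A
  mode_true <- as.integer(names(which.max(table(nA[nA > 0]))))
  expect_identical(mode_called, mode_true)
})

test_that("simulate -> AFM -> dispersity recovers the noiseless mean length", {
  means <- vapply(1:5, function(s) {
    pop <- simulate_living(5, 1500, seed = 200 + s)
    dispersity_summary(gen_afm_lengths(pop, noise_model(4, 10), 16,
                                       seed = 300 + s))$Ln
  }, 0)
  # truth: 2 * ratio * 16 nm = 160 nm; SE of each run ~ 3 nm
  expect_lt(abs(mean(means) - 160), 2 * 3 / sqrt(5) + 2)
})
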