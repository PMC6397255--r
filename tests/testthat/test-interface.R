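# Format round-trips and the pipeline driver.

test_that("reaction systems round-trip through JSON", {
  sys <- generate_tile_set(seed = 15)
  path <- withr::local_tempfile(fileext = ".json")
  write_system_json(sys, path)
  back <- read_system_json(path)
  expect_equal(back, sys, ignore_attr = TRUE)
  # behaviorally identical too
  expect_identical(nrow(validate_system(back)), 0L)
  expect_identical(sdr_cascade(back), sdr_cascade(sys))
  expect_error(read_system_json(withr::local_tempfile(lines = "{}",
                                                      fileext = ".json")),
               "malformed")
})

test_that("strands round-trip through FASTA with labels, lowercase warns", {
  sys <- generate_tile_set(seed = 16)
  path <- withr::local_tempfile(fileext = ".fa")
  write_strands_fasta(sys, path)
  back <- read_strands_fasta(path)
  expect_identical(length(back), 9L)  # 4 + 4 strands + initiator
  expect_identical(back$a1$sequence, sys$tiles$A$strands$a1$sequence)
  expect_identical(back$a1$labels$label, "biotin")
  expect_identical(back$I$sequence, sys$initiator$sequence)

  low <- withr::local_tempfile(lines = c(">x", "acgtacgt"), fileext = ".fa")
  expect_warning(s <- read_strands_fasta(low), "lowercase")
  expect_identical(s$x$sequence, "ACGTACGT")
})

test_that("populations round-trip through JSON", {
  pop <- tiny_pop(ratio = 3, n = 100, seed = 44)
  path <- withr::local_tempfile(fileext = ".json")
  write_population_json(pop, path)
  back <- read_population_json(path)
  expect_equal(back, pop, ignore_attr = TRUE)
  # an extended round-tripped population behaves like the original
  expect_identical(extend_population(back, 50, 50, seed = 2)$tiles,
                   extend_population(pop, 50, 50, seed = 2)$tiles)
})

test_that("length CSVs honor multiplicity columns", {
  s <- length_sample(c(32, 64, 96), c(2, 1, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_lengths_csv(s, path)
  expect_true("length_nm" %in% names(utils::read.csv(path)))
  back <- read_lengths_csv(path)
  expect_equal(back$values, s$values)
  expect_equal(back$multiplicities, s$multiplicities)
  expect_equal(dispersity_summary(back), dispersity_summary(s))
  expect_error(read_lengths_csv(withr::local_tempfile(
    lines = "a,b\n1,2", fileext = ".csv")), "malformed")
})

test_that("trace CSVs round-trip values on the frame grid", {
  traces <- lapply(1:3, function(i) synthesize_trace(2, seed = i))
  path <- withr::local_tempfile(fileext = ".csv")
  write_traces_csv(traces, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("time_s", "intensity_au", "trace_id"))
  back <- read_traces_csv(path)
  expect_identical(length(back), 3L)
  expect_equal(back[[1]]$intensities, traces[[1]]$intensities)
  expect_equal(back[[2]]$times, traces[[2]]$times)
})

test_that("the pipeline runs stages in order and is byte-deterministic", {
  cfg <- list(stages = c("simulate", "stats"), seed = 5,
              simulate = list(ratio_MI = 2, n_initiators = 400))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- run_pipeline(cfg, out_dir = d1)
  m2 <- run_pipeline(cfg, out_dir = d2)
  expect_true(all(file.exists(file.path(d1, c("population.json",
                                              "lengths.csv", "summary.json",
                                              "manifest.json")))))
  expect_identical(m1$outputs, m2$outputs)  # identical checksums
  smry <- jsonlite::read_json(file.path(d1, "summary.json"),
                              simplifyVector = TRUE)
  expect_gte(smry$PDI, 1)
  # detectable chains only: E[pairs | pairs > 0] * 2 tiles * 16 nm
  expect_equal(smry$Ln, 2 * 2 * 16 / (1 - exp(-2)), tolerance = 0.05)
})

test_that("missing upstream artifacts raise dependency errors naming the stage", {
  d <- withr::local_tempdir()
  expect_error(run_pipeline(list(stages = "stats"), out_dir = d),
               "stats.*lengths", ignore.case = TRUE)
  expect_error(run_pipeline(list(stages = "bleach"), out_dir = d),
               "bleach.*population", ignore.case = TRUE)
  expect_error(run_pipeline(list(stages = "dance"), out_dir = d), "unknown")
})

test_that("YAML configs drive the pipeline", {
  d <- withr::local_tempdir()
  cfg_path <- file.path(d, "run.yaml")
  writeLines(c("stages: [fixtures]", "seed: 3",
               "fixtures:", "  stem_len: 8"), cfg_path)
  m <- run_pipeline(cfg_path, out_dir = d)
  expect_true(file.exists(file.path(d, "system.json")))
  expect_true(file.exists(file.path(d, "strands.fa")))
  sys <- read_system_json(file.path(d, "system.json"))
  expect_identical(nrow(validate_system(sys)), 0L)
})

test_that("the command-line wrapper drives the pipeline", {
  script <- system.file("scripts", "dht.R", package = "dhtsim")
  expect_true(nzchar(script))
  d <- withr::local_tempdir()
  res <- withr::with_envvar(
    c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)),
    system2("Rscript", c(script, "simulate", "--ratio", "2", "--n-init",
                         "200", "--seed", "4", "--out-dir", d),
            stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(file.path(d, "summary.json")))
  expect_true(file.exists(file.path(d, "lengths.csv")))
  res2 <- withr::with_envvar(
    c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)),
    suppressWarnings(  # the non-zero exit status is the point
      system2("Rscript", c(script, "validate", "--system",
                           file.path(d, "..", "nope.json")),
              stdout = TRUE, stderr = TRUE)))
  expect_false(is.null(attr(res2, "status")))  # missing input fails loudly
})
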