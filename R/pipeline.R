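# Pipeline driver: runs the requested stages in dependency order with one
# master seed, writes their outputs and a machine-readable manifest.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (`fixtures -> simulate -> stats / bleach / mech`), writing each stage's
#' outputs into `out_dir` plus a `manifest.json` with input parameters,
#' seeds and md5 checksums. One master seed drives every stage through
#' deterministically derived sub-seeds, so an identical configuration
#' yields byte-identical outputs.
#'
#' Configuration entries (all optional except `stages`):
#' \describe{
#'   \item{stages}{character vector among `fixtures`, `simulate`, `stats`,
#'     `bleach`, `mech`.}
#'   \item{seed}{master seed (default 1).}
#'   \item{fixtures}{`stem_len`, `loop_len`.}
#'   \item{simulate}{`ratio_MI`, `n_initiators`, `mode`, `tile_length_nm`.}
#'   \item{stats}{`lengths` (CSV path; defaults to the simulate stage's
#'     output), `poisson` (logical: fit label counts), `truncated`.}
#'   \item{bleach}{`max_traces`, `step_height`, `noise_sd`, `mean_dwell_s`,
#'     `duration_s`, `frame_rate_hz`; needs the simulate stage (or a
#'     `population` JSON path).}
#'   \item{mech}{`n_AB`, `exponent`.}
#' }
#'
#' @param config named list (or path to a YAML/JSON file readable by
#'   [read_config()]).
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir %||% ".") {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  stopifnot(is.list(config))
  stages <- config$stages %||% character(0)
  known <- c("fixtures", "simulate", "stats", "bleach", "mech")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  pop <- NULL

  if ("fixtures" %in% stages) {
    fx <- config$fixtures %||% list()
    sys <- generate_tile_set(seed = derive_seed(seed, 1L),
                             stem_len = fx$stem_len %||% 8,
                             loop_len = fx$loop_len %||% 6)
    p1 <- file.path(out_dir, "system.json")
    p2 <- file.path(out_dir, "strands.fa")
    write_system_json(sys, p1)
    write_strands_fasta(sys, p2)
    viol <- validate_system(sys)
    p3 <- file.path(out_dir, "violations.json")
    jsonlite::write_json(viol, p3, pretty = TRUE)
    outputs <- c(outputs, p1, p2, p3)
  }

  if ("simulate" %in% stages) {
    sm <- config$simulate %||% list()
    pop <- simulate_living(ratio_MI = sm$ratio_MI %||% 10,
                           n_initiators = sm$n_initiators %||% 10000,
                           mode = sm$mode %||% "ideal",
                           seed = derive_seed(seed, 2L))
    p1 <- file.path(out_dir, "population.json")
    p2 <- file.path(out_dir, "lengths.csv")
    write_population_json(pop, p1)
    write_chain_lengths_csv(pop, p2,
                            tile_length_nm = sm$tile_length_nm %||% 16)
    outputs <- c(outputs, p1, p2)
  }

  if ("stats" %in% stages) {
    st <- config$stats %||% list()
    lengths_path <- st$lengths %||% file.path(out_dir, "lengths.csv")
    if (!file.exists(lengths_path))
      stop("dependency error: stage `stats` needs a lengths CSV; run the ",
           "`simulate` stage or set stats$lengths", call. = FALSE)
    sample <- read_lengths_csv(lengths_path)
    ds <- dispersity_summary(sample)
    out <- list(Ln = ds$Ln, Lw = ds$Lw, sigma = ds$sigma, PDI = ds$PDI,
                N = ds$N)
    if (isTRUE(st$poisson)) {
      if (is.null(pop))
        stop("dependency error: stage `stats` with poisson = TRUE needs ",
             "the `simulate` stage", call. = FALSE)
      hist <- label_counts(pop, labeling_efficiency = 1,
                           seed = derive_seed(seed, 3L),
                           truncated = st$truncated %||% TRUE)
      fit <- fit_poisson(hist)
      out$poisson <- list(lambda_hat = fit$lambda_hat,
                          truncated = fit$truncated,
                          loglik = fit$log_likelihood)
    }
    p1 <- file.path(out_dir, "summary.json")
    jsonlite::write_json(out, p1, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs <- c(outputs, p1)
  }

  if ("bleach" %in% stages) {
    bl <- config$bleach %||% list()
    if (is.null(pop)) {
      pp <- bl$population %||% file.path(out_dir, "population.json")
      if (!file.exists(pp))
        stop("dependency error: stage `bleach` needs a population; run the ",
             "`simulate` stage or set bleach$population", call. = FALSE)
      pop <- read_population_json(pp)
    }
    traces <- gen_trace_batch(pop, max_traces = bl$max_traces %||% 100,
                              step_height = bl$step_height %||% 1,
                              noise_sd = bl$noise_sd %||% 0.2,
                              mean_dwell_s = bl$mean_dwell_s %||% 2,
                              duration_s = bl$duration_s %||% 60,
                              frame_rate_hz = bl$frame_rate_hz %||% 3.88,
                              seed = derive_seed(seed, 4L))
    p1 <- file.path(out_dir, "traces.csv")
    write_traces_csv(traces, p1)
    calls <- lapply(traces, count_steps)
    p2 <- file.path(out_dir, "calls.csv")
    utils::write.csv(data.frame(
      trace_id = seq_along(calls),
      n_true = vapply(traces, function(t) t$meta$n_true_steps, 0L),
      n_steps = vapply(calls, `[[`, 0L, "n_steps"),
      n_events = vapply(calls, `[[`, 0L, "n_events")), p2,
      row.names = FALSE)
    outputs <- c(outputs, p1, p2)
  }

  if ("mech" %in% stages) {
    mc <- config$mech %||% list()
    rod <- build_rod("filament", n_AB = mc$n_AB %||% 10)
    ref <- build_rod("dsDNA", bp = 24)
    prof <- compute_rmsf(rod)
    p1 <- file.path(out_dir, "rmsf.csv")
    utils::write.csv(data.frame(node_index = seq_along(prof$rmsf),
                                arc_nm = prof$node_pos,
                                rmsf_nm = prof$rmsf), p1, row.names = FALSE)
    p2 <- file.path(out_dir, "mech.json")
    jsonlite::write_json(list(
      min_rmsf_nm = prof$min_rmsf, max_rmsf_nm = prof$max_rmsf,
      compliance_vs_dsDNA24 = relative_compliance(
        ref, rod, exponent = mc$exponent %||% 3)),
      p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, p1, p2)
  }

  manifest <- list(
    package = "dhtsim",
    version = as.character(utils::packageVersion("dhtsim")),
    seed = seed,
    stages = stages,
    config = config,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
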