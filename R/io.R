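# Format round-trips: FASTA strands, reaction-system JSON, length-sample
# and chain-length CSV, trace CSV, population JSON, YAML configs.
# All CSV headers carry units (length_nm, time_s, intensity_au).

#' Write strands to FASTA
#'
#' One record per strand; labels are carried in the description as
#' `key=value` pairs (`label=` and `end=`).
#'
#' @param x a [reaction_system()], a list of [strand_spec()], or a single
#'   strand.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_strands_fasta <- function(x, path) {
  strands <- if (inherits(x, "reaction_system")) {
    c(unlist(lapply(x$tiles, `[[`, "strands"), recursive = FALSE),
      if (!is.null(x$initiator)) list(x$initiator))
  } else if (inherits(x, "strand_spec")) list(x)
  else x
  stopifnot(all(vapply(strands, inherits, TRUE, "strand_spec")))
  seqs <- Biostrings::DNAStringSet(vapply(strands, `[[`, "", "sequence"))
  names(seqs) <- vapply(strands, function(s) {
    desc <- if (!is.null(s$labels) && nrow(s$labels) > 0L)
      paste0(" ", paste(sprintf("label=%s end=%s", s$labels$label,
                                s$labels$end), collapse = " "))
    else ""
    paste0(s$name, desc)
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read strands from FASTA
#'
#' Lowercase sequences are normalized to uppercase with a warning;
#' descriptions of the form `label=<kind> end=<5p|3p>` are parsed back into
#' strand labels.
#'
#' @param path FASTA file.
#' @return named list of [strand_spec()] objects.
#' @export
read_strands_fasta <- function(path) {
  # Biostrings normalizes case silently; check the raw text so the
  # normalization is reported
  txt <- readLines(path, warn = FALSE)
  if (any(grepl("[acgt]", txt[!startsWith(txt, ">")])))
    warning("lowercase bases in FASTA normalized to uppercase",
            call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  out <- lapply(seq_along(seqs), function(i) {
    raw <- toupper(as.character(seqs[[i]]))
    parts <- strsplit(headers[i], "\\s+")[[1L]]
    name <- parts[1L]
    labels <- NULL
    labs <- grep("^label=", parts)
    if (length(labs) > 0L) {
      labels <- data.frame(
        label = sub("^label=", "", parts[labs]),
        end = sub("^end=", "", parts[labs + 1L]),
        stringsAsFactors = FALSE)
    }
    strand_spec(name, raw, labels = labels)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

strand_to_list <- function(s) {
  list(name = s$name, sequence = s$sequence,
       labels = if (is.null(s$labels)) NULL else s$labels)
}

strand_from_list <- function(l) {
  raw <- l$labels
  labels <- NULL
  if (is.data.frame(raw) && nrow(raw) > 0L && !all(is.na(raw))) {
    labels <- raw[!is.na(raw$label), c("label", "end"), drop = FALSE]
    if (nrow(labels) == 0L) labels <- NULL
  } else if (is.list(raw) && !is.null(raw$label)) {
    labels <- data.frame(label = unlist(raw$label), end = unlist(raw$end),
                         stringsAsFactors = FALSE)
  }
  strand_spec(l$name, l$sequence, labels = labels)
}

#' Write a reaction system to JSON
#'
#' @param system a [reaction_system()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_system_json <- function(system, path) {
  stopifnot(inherits(system, "reaction_system"))
  doc <- list(
    tiles = lapply(unname(system$tiles), function(tl) list(
      tile_id = tl$tile_id,
      strands = lapply(unname(tl$strands), strand_to_list),
      domains = tl$domains,
      sticky_pairs = tl$sticky_pairs,
      crossover_separation_nt = tl$crossover_separation_nt,
      tile_length_bp = tl$tile_length_bp)),
    initiator = if (is.null(system$initiator)) NULL
                else strand_to_list(system$initiator))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a reaction system from JSON
#'
#' @param path file written by [write_system_json()].
#' @return a [reaction_system()] equal to the one written.
#' @export
read_system_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (is.null(doc$tiles))
    stop("malformed system JSON (", path, "): no `tiles` field",
         call. = FALSE)
  tiles <- lapply(seq_len(length(doc$tiles$tile_id)), function(i) {
    strands_raw <- doc$tiles$strands[[i]]
    strands <- lapply(seq_len(nrow(strands_raw)), function(j)
      strand_from_list(list(name = strands_raw$name[j],
                            sequence = strands_raw$sequence[j],
                            labels = strands_raw$labels[[j]])))
    sp <- doc$tiles$sticky_pairs[[i]]
    if (!is.null(sp) && (!is.data.frame(sp) || nrow(sp) == 0L)) sp <- NULL
    tile_spec(doc$tiles$tile_id[i], strands,
              domains = as.data.frame(doc$tiles$domains[[i]]),
              sticky_pairs = sp,
              crossover_separation_nt = doc$tiles$crossover_separation_nt[i],
              tile_length_bp = doc$tiles$tile_length_bp[i])
  })
  initiator <- if (is.null(doc$initiator)) NULL
               else strand_from_list(doc$initiator)
  reaction_system(tiles, initiator = initiator)
}

#' Write per-chain lengths of a population to CSV
#'
#' One row per chain: `chain_id`, `n_A`, `n_B`, `length_nm`.
#'
#' @param pop a [dht_population].
#' @param path output file.
#' @param tile_length_nm axial tile length (nm).
#' @return `path`, invisibly.
#' @export
write_chain_lengths_csv <- function(pop, path, tile_length_nm = 16) {
  comp <- chain_composition(pop)
  comp$length_nm <- chain_contour_lengths(pop, tile_length_nm)
  utils::write.csv(comp[, c("chain_id", "n_A", "n_B", "length_nm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a length sample to CSV
#'
#' Columns `length_nm` and `multiplicity`.
#'
#' @param sample a [length_sample()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lengths_csv <- function(sample, path) {
  stopifnot(inherits(sample, "length_sample"))
  utils::write.csv(data.frame(length_nm = sample$values,
                              multiplicity = sample$multiplicities),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a length sample from CSV
#'
#' Accepts a `length_nm` (or `value`) column with an optional
#' `multiplicity` column; also accepts per-chain files from
#' [write_chain_lengths_csv()]. Non-positive lengths (undetectable
#' objects) are dropped with a count recorded in attribute `n_dropped`.
#'
#' @param path CSV file.
#' @return a [length_sample()].
#' @export
read_lengths_csv <- function(path) {
  df <- utils::read.csv(path)
  col <- intersect(c("length_nm", "value", "length_tiles"), names(df))
  if (length(col) == 0L)
    stop("malformed lengths CSV (", path,
         "): need a `length_nm` or `value` column", call. = FALSE)
  values <- df[[col[1L]]]
  mult <- if ("multiplicity" %in% names(df)) df$multiplicity
          else rep(1, length(values))
  keep <- values > 0
  out <- length_sample(values[keep], mult[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write a batch of traces to CSV
#'
#' Long format with columns `time_s`, `intensity_au`, `trace_id`.
#'
#' @param traces list of `dht_trace` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(all(vapply(traces, inherits, TRUE, "dht_trace")))
  df <- do.call(rbind, lapply(seq_along(traces), function(i)
    data.frame(time_s = traces[[i]]$times,
               intensity_au = traces[[i]]$intensities,
               trace_id = i)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a batch of traces from CSV
#'
#' @param path file with columns `time_s`, `intensity_au` and optional
#'   `trace_id` (a single trace is assumed when absent).
#' @return list of `dht_trace` objects (meta limited to the frame rate).
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "intensity_au")
  if (!all(need %in% names(df)))
    stop("malformed traces CSV (", path, "): need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"trace_id" %in% names(df)) df$trace_id <- 1L
  lapply(split(df, df$trace_id), function(d) {
    structure(list(times = d$time_s, intensities = d$intensity_au,
                   meta = list(frame_rate_hz = 1 / stats::median(diff(d$time_s)))),
              class = "dht_trace")
  })
}

#' Write a population to JSON
#'
#' Full round-trip serialization of a [dht_population].
#'
#' @param pop a [dht_population].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_population_json <- function(pop, path) {
  stopifnot(inherits(pop, "dht_population"))
  doc <- list(tiles = pop$tiles, free_A = pop$free_A, free_B = pop$free_B,
              free_I = pop$free_I, mode = pop$mode, params = pop$params,
              n_extensions = pop$n_extensions)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a population from JSON
#'
#' @param path file written by [write_population_json()].
#' @return the [dht_population] that was written.
#' @export
read_population_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$tiles) || is.null(doc$mode))
    stop("malformed population JSON (", path, ")", call. = FALSE)
  structure(list(tiles = as.integer(doc$tiles),
                 free_A = as.integer(doc$free_A),
                 free_B = as.integer(doc$free_B),
                 free_I = as.integer(doc$free_I),
                 mode = doc$mode,
                 params = doc$params,
                 n_extensions = as.integer(doc$n_extensions)),
            class = "dht_population")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` config file.
#' @return a named list, see [run_pipeline()].
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
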