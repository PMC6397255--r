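# Generators for every fixture the pipeline needs: constraint-satisfying
# tile sequence sets, AFM-style noisy length samples, and photobleaching
# trace batches. Everything is seeded and reproducible, so all downstream
# stages are testable without external data.

# The four 6-nt segments with fixed roles in the activation cascade:
# a3's 5' toehold, a4's loop (which invades b3's 3' toehold), and b4's loop
# (identical to the initiator's 3' active segment).
RESERVED_6MERS <- c(a3_toehold = "TGTCAC", a4_loop = "TGAACC",
                    b3_toehold = "GGTTCA", b4_loop = "GTGACA")

count_occurrences <- function(seq, pattern) {
  if (nchar(seq) < nchar(pattern)) return(0L)
  starts <- seq_len(nchar(seq) - nchar(pattern) + 1L)
  sum(substring(seq, starts, starts + nchar(pattern) - 1L) == pattern)
}

contains_reserved <- function(seq) {
  any(vapply(RESERVED_6MERS, function(p) count_occurrences(seq, p) > 0L,
             TRUE))
}

# random filler of given length avoiding the reserved 6-mers (rejection
# sampling); among `n_cand` candidates the one with the lowest 6-mer
# symmetry score is kept (greedy sequence-symmetry minimization)
random_filler <- function(len, n_cand = 12L, max_tries = 200L) {
  if (len == 0L) return("")
  best <- NULL
  best_score <- Inf
  found <- 0L
  for (i in seq_len(max_tries)) {
    cand <- paste(sample(DNA_ALPHABET, len, replace = TRUE), collapse = "")
    if (contains_reserved(cand)) next
    score <- if (len >= 6L) symmetry_score(cand, 6L) else 0L
    if (score < best_score) {
      best <- cand
      best_score <- score
    }
    found <- found + 1L
    if (found >= n_cand || best_score == 0L) break
  }
  if (is.null(best))
    stop("could not generate filler avoiding reserved segments",
         call. = FALSE)
  best
}

# as random_filler, but the whole assembled strand (context with the filler
# substituted) must contain each reserved 6-mer exactly as often as intended
filler_for_strand <- function(len, assemble, intended, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    cand <- random_filler(len)
    full <- assemble(cand)
    ok <- all(vapply(seq_along(RESERVED_6MERS), function(j)
      count_occurrences(full, RESERVED_6MERS[[j]]) == intended[[j]], TRUE))
    if (ok) return(cand)
  }
  stop("could not satisfy segment-occurrence constraints", call. = FALSE)
}

#' Generate a constraint-satisfying DHT tile set
#'
#' Builds a two-tile reaction system (tiles A and B plus initiator I) whose
#' sequences honor the fixed cascade segments: the A toehold `TGTCAC` (5'
#' end of a3), the A loop `TGAACC` (which invades the B toehold `GGTTCA`,
#' the 3' end of b3), and the B loop ending in `GTGACA`, identical to the
#' initiator's 3' active segment. Hairpin stems are self-complementary by
#' construction, declared sticky pairs are reverse-complementary, and all
#' remaining bases are random filler with greedily minimized 6-mer symmetry
#' score, rejected if they create stray copies of the reserved segments.
#' The generated system passes [validate_system()] with zero violations and
#' [sdr_cascade()] closes in three events.
#'
#' @param seed RNG seed.
#' @param stem_len hairpin stem length (nt, >= 6).
#' @param loop_len hairpin loop length (nt, >= 6; default 6, so the loop is
#'   exactly the reserved segment).
#' @param sticky_len sticky-end length (nt).
#' @return a [reaction_system()].
#' @export
generate_tile_set <- function(seed = NULL, stem_len = 8, loop_len = 6,
                              sticky_len = 6) {
  stop_if_not_scalar_number(stem_len, "stem_len", positive = TRUE,
                            integerish = TRUE)
  stop_if_not_scalar_number(loop_len, "loop_len", positive = TRUE,
                            integerish = TRUE)
  stop_if_not_scalar_number(sticky_len, "sticky_len", positive = TRUE,
                            integerish = TRUE)
  if (stem_len < 6)
    stop("infeasible constraints: stem_len must be >= 6", call. = FALSE)
  if (loop_len < 6)
    stop("infeasible constraints: loop_len must be >= 6 to hold the cascade segment",
         call. = FALSE)
  stem_len <- as.integer(stem_len)
  loop_len <- as.integer(loop_len)
  sticky_len <- as.integer(sticky_len)

  with_seed(seed, {
    core_len <- 26L  # core strand spans the intermolecular crossover separation

    # sticky ends appear on both tiles (as themselves and as their reverse
    # complement), so neither orientation may contain a reserved segment
    random_sticky <- function(len) {
      for (i in 1:200) {
        cand <- random_filler(len)
        if (!contains_reserved(reverse_complement(cand))) return(cand)
      }
      stop("could not generate sticky end", call. = FALSE)
    }

    # simple strands: filler avoiding reserved segments everywhere
    a1 <- random_filler(core_len)
    b1 <- random_filler(core_len)
    a2_sticky <- random_sticky(sticky_len)
    a2 <- paste0(a2_sticky,
                 filler_for_strand(10L, function(f) paste0(a2_sticky, f),
                                   intended = c(0L, 0L, 0L, 0L)))
    b2_sticky <- reverse_complement(a2_sticky)
    b2 <- paste0(b2_sticky,
                 filler_for_strand(10L, function(f) paste0(b2_sticky, f),
                                   intended = c(0L, 0L, 0L, 0L)))

    # a3: toehold TGTCAC at the 5' end, then core filler
    a3 <- paste0(RESERVED_6MERS[["a3_toehold"]],
                 filler_for_strand(12L,
                   function(f) paste0(RESERVED_6MERS[["a3_toehold"]], f),
                   intended = c(1L, 0L, 0L, 0L)))

    # a4: sticky end + stem + loop (3' end TGAACC) + revcomp stem
    a4_sticky <- random_sticky(sticky_len)
    a4_loop <- paste0(random_filler(loop_len - 6L),
                      RESERVED_6MERS[["a4_loop"]])
    a4_stem <- filler_for_strand(stem_len,
      function(f) paste0(a4_sticky, f, a4_loop, reverse_complement(f)),
      intended = c(0L, 1L, 0L, 0L))
    a4 <- paste0(a4_sticky, a4_stem, a4_loop, reverse_complement(a4_stem))

    # b3: 5' sticky end complementary to a4's, core, 3' toehold GGTTCA
    b3 <- paste0(reverse_complement(a4_sticky),
                 filler_for_strand(10L,
                   function(f) paste0(reverse_complement(a4_sticky), f,
                                      RESERVED_6MERS[["b3_toehold"]]),
                   intended = c(0L, 0L, 1L, 0L)),
                 RESERVED_6MERS[["b3_toehold"]])

    # b4: stem + loop (3' end GTGACA) + revcomp stem
    b4_loop <- paste0(random_filler(loop_len - 6L),
                      RESERVED_6MERS[["b4_loop"]])
    b4_stem <- filler_for_strand(stem_len,
      function(f) paste0(f, b4_loop, reverse_complement(f)),
      intended = c(0L, 0L, 0L, 1L))
    b4 <- paste0(b4_stem, b4_loop, reverse_complement(b4_stem))

    # initiator: matches A's stem, 3' active segment GTGACA
    iseq <- paste0(reverse_complement(a4_stem), RESERVED_6MERS[["b4_loop"]])

    dom_A <- rbind(
      domain_annotation("a1", 0L, nchar(a1), "core"),
      domain_annotation("a2", 0L, sticky_len, "sticky_end"),
      domain_annotation("a2", sticky_len, nchar(a2), "core"),
      domain_annotation("a3", 0L, 6L, "toehold"),
      domain_annotation("a3", 6L, nchar(a3), "core"),
      domain_annotation("a4", 0L, sticky_len, "sticky_end"),
      domain_annotation("a4", sticky_len, sticky_len + stem_len, "stem"),
      domain_annotation("a4", sticky_len + stem_len,
                        sticky_len + stem_len + loop_len, "loop"),
      domain_annotation("a4", sticky_len + stem_len + loop_len,
                        sticky_len + 2L * stem_len + loop_len, "stem"))
    dom_B <- rbind(
      domain_annotation("b1", 0L, nchar(b1), "core"),
      domain_annotation("b2", 0L, sticky_len, "sticky_end"),
      domain_annotation("b2", sticky_len, nchar(b2), "core"),
      domain_annotation("b3", 0L, sticky_len, "sticky_end"),
      domain_annotation("b3", sticky_len, nchar(b3) - 6L, "core"),
      domain_annotation("b3", nchar(b3) - 6L, nchar(b3), "toehold"),
      domain_annotation("b4", 0L, stem_len, "stem"),
      domain_annotation("b4", stem_len, stem_len + loop_len, "loop"),
      domain_annotation("b4", stem_len + loop_len,
                        2L * stem_len + loop_len, "stem"))

    sticky_pairs_A <- data.frame(
      strand = c("a2", "a4"), start = c(0L, 0L),
      end = c(sticky_len, sticky_len),
      partner_tile = c("B", "B"), partner_strand = c("b2", "b3"),
      partner_start = c(0L, 0L), partner_end = c(sticky_len, sticky_len),
      stringsAsFactors = FALSE)

    tile_A <- tile_spec("A",
      list(strand_spec("a1", a1,
                       labels = data.frame(label = "biotin", end = "5p")),
           strand_spec("a2", a2), strand_spec("a3", a3),
           strand_spec("a4", a4)),
      dom_A, sticky_pairs = sticky_pairs_A,
      crossover_separation_nt = 26L, tile_length_bp = 47L)
    tile_B <- tile_spec("B",
      list(strand_spec("b1", b1), strand_spec("b2", b2),
           strand_spec("b3", b3), strand_spec("b4", b4)),
      dom_B, sticky_pairs = NULL,
      crossover_separation_nt = 26L, tile_length_bp = 47L)

    reaction_system(list(tile_A, tile_B),
                    initiator = strand_spec("I", iseq))
  })
}

#' AFM measurement noise model
#'
#' Emulates manual contour-length measurement from AFM images: additive
#' Gaussian length noise, a constant tip-broadening offset, and a detection
#' floor below which objects are not scored. The defaults (8 nm sd, 10 nm
#' floor, no broadening) are plausible instrument-scale package defaults,
#' not measured values.
#'
#' @param length_noise_sd measurement noise sd (nm, >= 0).
#' @param min_detectable_nm detection floor (nm, >= 0).
#' @param tip_broadening_nm additive broadening constant (nm).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(length_noise_sd = 8, min_detectable_nm = 10,
                        tip_broadening_nm = 0) {
  stop_if_not_scalar_number(length_noise_sd, "length_noise_sd", nonneg = TRUE)
  stop_if_not_scalar_number(min_detectable_nm, "min_detectable_nm",
                            nonneg = TRUE)
  stop_if_not_scalar_number(tip_broadening_nm, "tip_broadening_nm",
                            nonneg = TRUE)
  structure(list(length_noise_sd = length_noise_sd,
                 min_detectable_nm = min_detectable_nm,
                 tip_broadening_nm = tip_broadening_nm),
            class = "noise_model")
}

#' Simulate AFM-style contour-length measurements of a population
#'
#' True per-chain contour lengths plus Gaussian measurement noise and tip
#' broadening; measurements below the detection floor (or non-positive) are
#' dropped and counted.
#'
#' @param pop a [dht_population].
#' @param noise a [noise_model()].
#' @param tile_length_nm axial tile length (nm).
#' @param seed RNG seed.
#' @return a [length_sample()] of detected lengths, with attribute
#'   `n_dropped` (objects below the floor).
#' @export
gen_afm_lengths <- function(pop, noise = noise_model(), tile_length_nm = 16,
                            seed = NULL) {
  stopifnot(inherits(pop, "dht_population"), inherits(noise, "noise_model"))
  true_len <- chain_contour_lengths(pop, tile_length_nm = tile_length_nm)
  if (length(true_len) == 0L) stop("empty population", call. = FALSE)
  obs <- with_seed(seed,
    true_len + noise$tip_broadening_nm +
      stats::rnorm(length(true_len), sd = noise$length_noise_sd))
  keep <- obs >= noise$min_detectable_nm & obs > 0
  out <- length_sample(obs[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Generate a photobleaching trace batch from a population
#'
#' One trace per chain, with the true fluorophore number equal to the
#' chain's count of Cy3-carrying A monomers; delegates to
#' [synthesize_trace()].
#'
#' @param pop a [dht_population].
#' @param max_traces cap on the number of traces (chains are sampled
#'   without replacement when the population is larger); `Inf` takes all.
#' @param step_height,noise_sd,mean_dwell_s,duration_s,frame_rate_hz trace
#'   synthesis parameters, see [synthesize_trace()].
#' @param seed RNG seed (per-trace sub-seeds are derived from it).
#' @return list of `dht_trace` objects.
#' @export
gen_trace_batch <- function(pop, max_traces = 100, step_height = 1,
                            noise_sd = 0.2, mean_dwell_s = 2,
                            duration_s = 60, frame_rate_hz = 3.88,
                            seed = NULL) {
  stopifnot(inherits(pop, "dht_population"))
  nA <- chain_composition(pop)$n_A
  if (length(nA) == 0L) stop("empty population", call. = FALSE)
  with_seed(seed, {
    idx <- if (length(nA) > max_traces)
      sample(seq_along(nA), max_traces) else seq_along(nA)
    lapply(seq_along(idx), function(i)
      synthesize_trace(nA[idx[i]], step_height = step_height,
                       noise_sd = noise_sd, mean_dwell_s = mean_dwell_s,
                       duration_s = duration_s,
                       frame_rate_hz = frame_rate_hz,
                       seed = NULL))
  })
}
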