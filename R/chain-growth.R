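# Stochastic simulator of initiator-triggered living chain-growth
# copolymerization of DHT monomers A and B, plus a thermal (initiator-free)
# step-growth control and stepwise monomer re-feeding.
#
# Concentrations enter only through the monomer-to-initiator ratio: the
# initiator ensemble is represented by `n_initiators` discrete chains and the
# monomer pools by integer counts, so volume is implicit.
#
# A chain always starts with monomer A on the initiator and strictly
# alternates A,B,A,B,..., so its composition is fully determined by its tile
# count T: n_A = ceiling(T/2), n_B = floor(T/2).

new_population <- function(tiles, free_A, free_B, mode, params) {
  structure(list(
    tiles = as.integer(tiles),
    free_A = as.integer(free_A),
    free_B = as.integer(free_B),
    free_I = sum(tiles == 0L),
    mode = mode,
    params = params,
    n_extensions = 0L
  ), class = "dht_population")
}

#' Per-chain monomer counts
#'
#' @param pop a [dht_population] from [simulate_living()] or
#'   [simulate_thermal()].
#' @return data.frame with columns `chain_id`, `n_tiles`, `n_A`, `n_B`. For
#'   thermal (initiator-free) populations the A/B split of the unordered
#'   condensation product is reported as an even split.
#' @export
chain_composition <- function(pop) {
  stopifnot(inherits(pop, "dht_population"))
  t <- pop$tiles
  data.frame(chain_id = seq_along(t), n_tiles = t,
             n_A = as.integer(ceiling(t / 2)), n_B = as.integer(floor(t / 2)))
}

# Fast-initiation paired-unit allocation: A-B pairs are the propagation
# unit (the B pool mirrors the A pool and alternation is forced by design),
# and each pair event lands on a uniformly random chain, so the per-chain
# pair count is Multinomial(pairs, chains) ~ Poisson([M]0/[I]0) in the
# many-chain limit — the classical living-polymerization chain-length
# distribution. Unpaired surplus monomers stay in the free pools.
allocate_tiles <- function(tiles, n_A_pool, n_B_pool) {
  n <- length(tiles)
  nA <- as.integer(n_A_pool)
  nB <- as.integer(n_B_pool)
  pairs <- min(nA, nB)
  if (pairs > 0L) {
    add <- tabulate(sample.int(n, pairs, replace = TRUE), nbins = n)
    tiles <- tiles + 2L * add
    nA <- nA - pairs
    nB <- nB - pairs
  }
  list(tiles = tiles, free_A = nA, free_B = nB)
}

# Exact stochastic simulation (Gillespie selection) over
#   I + A -> I-A*        (k_init)
#   chain* + monomer -> chain*   (k_prop)
# Only the embedded jump chain matters for the final state, so reaction
# times are not tracked.
simulate_kinetic_core <- function(n_init, n_A_pool, n_B_pool, k_init, k_prop) {
  pick <- function(idx) if (length(idx) == 1L) idx
                        else idx[sample.int(length(idx), 1L)]
  tiles <- integer(n_init)
  initiated <- logical(n_init)
  nI <- n_init
  nA <- as.integer(n_A_pool)
  nB <- as.integer(n_B_pool)
  repeat {
    expects_A <- initiated & tiles %% 2L == 0L
    expects_B <- initiated & tiles %% 2L == 1L
    cA <- sum(expects_A)
    cB <- sum(expects_B)
    a_init <- k_init * nI * nA
    a_pA <- k_prop * cA * nA
    a_pB <- k_prop * cB * nB
    a0 <- a_init + a_pA + a_pB
    if (a0 <= 0) break
    u <- stats::runif(1L) * a0
    if (u < a_init) {
      id <- pick(which(!initiated))
      initiated[id] <- TRUE
      tiles[id] <- 1L
      nI <- nI - 1L
      nA <- nA - 1L
    } else if (u < a_init + a_pA) {
      id <- pick(which(expects_A))
      tiles[id] <- tiles[id] + 1L
      nA <- nA - 1L
    } else {
      id <- pick(which(expects_B))
      tiles[id] <- tiles[id] + 1L
      nB <- nB - 1L
    }
  }
  list(tiles = tiles, free_A = nA, free_B = nB)
}

#' Simulate living (initiator-triggered) chain-growth copolymerization
#'
#' In the fast-initiation ideal mode every initiator nucleates a chain and
#' A-B pairs are the propagation unit: each pair event lands on a uniformly
#' random chain until the pools are exhausted, so the per-chain pair count
#' follows the classical living-polymerization Poisson distribution with
#' mean `ratio_MI`, and the tile-unit polydispersity index is
#' `(1 + mu) / mu` with `mu = ratio_MI`.
#'
#' Kinetic mode runs an exact stochastic simulation over full two-species
#' events, initiation (`I + A -> I-A*`, rate `k_init`) and propagation
#' (`chain* + monomer -> chain*`, rate `k_prop`). With `k_init >> k_prop`
#' its mean chain length matches ideal mode, but its exhaustion endpoint is
#' narrower than Poisson: under strict alternation with equal pools the A
#' pool always runs out first and the B leftover exactly completes every
#' odd chain, which removes about half the count variance. Kinetic mode is
#' a sensitivity tool, not a fit (the system's rate constants are not
#' known).
#'
#' @param ratio_MI monomer-to-initiator ratio `[M]0/[I]0` (per species: the
#'   A pool and the B pool each hold `ratio_MI * n_initiators` monomers,
#'   matching equimolar A and B).
#' @param n_initiators number of simulated initiator molecules (>= 1).
#' @param mode `"ideal"` (fast-initiation limit) or `"kinetic"`.
#' @param k_init,k_prop rate constants for kinetic mode (arbitrary units;
#'   only their ratio matters). Default fast initiation `k_init/k_prop = 100`.
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @return an object of class `dht_population` with elements `tiles`
#'   (per-chain tile count; every initiator appears, length-0 chains are
#'   unreacted initiators), `free_A`, `free_B`, `free_I`, `mode`, `params`.
#' @examples
#' pop <- simulate_living(ratio_MI = 10, n_initiators = 1000, seed = 1)
#' summary(pop)
#' @export
simulate_living <- function(ratio_MI, n_initiators = 10000,
                            mode = c("ideal", "kinetic"),
                            k_init = 100, k_prop = 1, seed = NULL) {
  mode <- match.arg(mode)
  stop_if_not_scalar_number(ratio_MI, "ratio_MI", nonneg = TRUE)
  stop_if_not_scalar_number(n_initiators, "n_initiators", integerish = TRUE)
  if (n_initiators < 1L)
    stop("no active sites: living mode needs at least one initiator",
         call. = FALSE)
  stop_if_not_scalar_number(k_init, "k_init", positive = TRUE)
  stop_if_not_scalar_number(k_prop, "k_prop", positive = TRUE)
  n <- as.integer(n_initiators)
  pool <- as.integer(round(ratio_MI * n))
  params <- list(ratio_MI = ratio_MI, n_initiators = n, mode = mode,
                 k_init = k_init, k_prop = k_prop, seed = seed,
                 pool_A = pool, pool_B = pool)
  res <- with_seed(seed, {
    if (mode == "ideal") allocate_tiles(integer(n), pool, pool)
    else simulate_kinetic_core(n, pool, pool, k_init, k_prop)
  })
  new_population(res$tiles, res$free_A, res$free_B, mode, params)
}

#' Simulate thermal (initiator-free) step-growth copolymerization
#'
#' The control condition: heated monomers condense without any initiator.
#' At extent of reaction `p` each of the `n_monomers - 1` junctions along a
#' random monomer ordering is bonded independently with probability `p`, so
#' chain lengths follow the most-probable (Flory/geometric) distribution
#' with mean `1/(1-p)` and PDI converging to `1 + p`.
#'
#' @param conversion_p extent of reaction, `0 <= p < 1`.
#' @param n_monomers total monomer units to condense.
#' @param seed RNG seed.
#' @return a `dht_population` with `mode = "thermal"`; chains carry no
#'   active termini and cannot be extended.
#' @export
simulate_thermal <- function(conversion_p, n_monomers = 100000, seed = NULL) {
  stop_if_not_scalar_number(conversion_p, "conversion_p", nonneg = TRUE)
  if (conversion_p >= 1)
    stop("conversion_p must be < 1", call. = FALSE)
  stop_if_not_scalar_number(n_monomers, "n_monomers", positive = TRUE,
                            integerish = TRUE)
  n <- as.integer(n_monomers)
  lens <- with_seed(seed, {
    if (n == 1L) 1L
    else {
      bonded <- stats::runif(n - 1L) < conversion_p
      boundaries <- which(!bonded)
      as.integer(diff(c(0L, boundaries, n)))
    }
  })
  params <- list(conversion_p = conversion_p, n_monomers = n, seed = seed,
                 mode = "thermal")
  pop <- new_population(lens, 0L, 0L, "thermal", params)
  pop$free_I <- 0L  # no initiators exist in the thermal control
  pop
}

#' Extend a living population with fresh monomers (stepwise re-feeding)
#'
#' Living restart: added monomers propagate exclusively on the existing
#' chains' active termini. The chain count never changes and no new chains
#' nucleate. Thermal populations have no active termini and cannot be
#' extended.
#'
#' @param pop a living `dht_population`.
#' @param added_A,added_B monomer counts added to the pools (>= 0).
#' @param seed RNG seed; if `NULL`, a reproducible sub-seed is derived from
#'   the population's own seed (when it has one).
#' @return the extended `dht_population`; `params$pool_A`/`pool_B`
#'   accumulate the total fed monomers.
#' @export
extend_population <- function(pop, added_A, added_B, seed = NULL) {
  stopifnot(inherits(pop, "dht_population"))
  if (identical(pop$mode, "thermal"))
    stop("no active termini: thermal populations cannot be extended",
         call. = FALSE)
  stop_if_not_scalar_number(added_A, "added_A", nonneg = TRUE,
                            integerish = TRUE)
  stop_if_not_scalar_number(added_B, "added_B", nonneg = TRUE,
                            integerish = TRUE)
  if (is.null(seed) && !is.null(pop$params$seed))
    seed <- derive_seed(pop$params$seed, pop$n_extensions + 1L)
  nA <- pop$free_A + as.integer(added_A)
  nB <- pop$free_B + as.integer(added_B)
  res <- with_seed(seed, allocate_tiles(pop$tiles, nA, nB))
  out <- pop
  out$tiles <- res$tiles
  out$free_A <- res$free_A
  out$free_B <- res$free_B
  out$free_I <- sum(res$tiles == 0L)
  out$n_extensions <- pop$n_extensions + 1L
  out$params$pool_A <- pop$params$pool_A + as.integer(added_A)
  out$params$pool_B <- pop$params$pool_B + as.integer(added_B)
  out
}

#' Per-chain contour lengths
#'
#' @param pop a `dht_population`.
#' @param tile_length_nm axial length contributed by one tile (nm); the
#'   default 16 nm is the DHT tile length along the helical axis.
#' @param initiator_nm contour contribution of the initiator strand
#'   (default 0: a short single strand adds no measurable contour).
#' @return numeric vector of per-chain contour lengths (nm).
#' @export
chain_contour_lengths <- function(pop, tile_length_nm = 16,
                                  initiator_nm = 0) {
  stopifnot(inherits(pop, "dht_population"))
  stop_if_not_scalar_number(tile_length_nm, "tile_length_nm", positive = TRUE)
  stop_if_not_scalar_number(initiator_nm, "initiator_nm", nonneg = TRUE)
  init_nm <- if (identical(pop$mode, "thermal")) 0 else initiator_nm
  pop$tiles * tile_length_nm + init_nm
}

#' @export
print.dht_population <- function(x, ...) {
  cat(sprintf("<dht_population> %s mode: %d chains, mean %.2f tiles/chain\n",
              x$mode, length(x$tiles), mean(x$tiles)))
  cat(sprintf("  pools: free_A = %d, free_B = %d, unreacted initiators = %d\n",
              x$free_A, x$free_B, x$free_I))
  invisible(x)
}

#' @export
summary.dht_population <- function(object, tile_length_nm = 16, ...) {
  t <- object$tiles
  nonzero <- t[t > 0L]
  disp <- if (length(nonzero) > 0L)
    dispersity_summary(length_sample(nonzero)) else NULL
  out <- list(
    mode = object$mode,
    n_chains = length(t),
    n_detectable = length(nonzero),
    mean_tiles = mean(t),
    mean_contour_nm = mean(t) * tile_length_nm,
    dispersity = disp,
    free_A = object$free_A, free_B = object$free_B, free_I = object$free_I
  )
  class(out) <- "summary.dht_population"
  out
}

#' @export
print.summary.dht_population <- function(x, ...) {
  cat(sprintf("Population (%s mode): %d chains (%d with >= 1 tile)\n",
              x$mode, x$n_chains, x$n_detectable))
  cat(sprintf("  mean tiles/chain: %.3f (mean contour %.1f nm)\n",
              x$mean_tiles, x$mean_contour_nm))
  if (!is.null(x$dispersity))
    cat(sprintf("  tile-unit Ln = %.3f, Lw = %.3f, PDI = %.4f\n",
                x$dispersity$Ln, x$dispersity$Lw, x$dispersity$PDI))
  cat(sprintf("  free_A = %d, free_B = %d, unreacted initiators = %d\n",
              x$free_A, x$free_B, x$free_I))
  invisible(x)
}
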