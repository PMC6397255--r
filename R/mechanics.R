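# Discretized elastic-rod (worm-like chain) model of dsDNA, DHT monomers
# and nanofilaments: per-node thermal fluctuation amplitudes (RMSF) from
# transverse-bending normal-mode analysis, and relative bending compliance
# against a 24-bp duplex reference.
#
# This is a deliberately one-dimensional rod model: two independent
# transverse bending directions of an Euler-Bernoulli discretization.
# Stretching (1100 pN) and torsion (460 pN nm^2) are carried in the
# parameter set but excluded from the RMSF, whose soft modes are bending.

BOLTZMANN_PN_NM_PER_K <- 0.0138065  # pN nm / K

#' Elastic parameters of the rod model
#'
#' Defaults are the standard B-DNA beam parameters: bending stiffness
#' 230 pN nm^2, stretching modulus 1100 pN, torsional stiffness
#' 460 pN nm^2; bending (and torsion) are softened 100-fold at backbone
#' nicks; single-stranded segments are modeled as very soft bending
#' elements with stiffness `kBT * ss_persistence_nm`.
#'
#' @param bend_stiffness duplex bending stiffness (pN nm^2).
#' @param stretch_modulus stretching modulus (pN); stored, not used in RMSF.
#' @param torsion_stiffness torsional stiffness (pN nm^2); stored.
#' @param nick_softening stiffness reduction factor at nicks (>= 1).
#' @param temperature_K temperature (K); `kBT` is derived (4.114 pN nm at
#'   298 K).
#' @param ss_persistence_nm persistence length assigned to single-stranded
#'   segments (nm).
#' @param dx_multiplier bending-stiffness multiplier for the two-helix DX
#'   cross-section (parallel-axis offset ignored).
#' @return object of class `rod_params`.
#' @export
rod_params <- function(bend_stiffness = 230, stretch_modulus = 1100,
                       torsion_stiffness = 460, nick_softening = 100,
                       temperature_K = 298, ss_persistence_nm = 1.0,
                       dx_multiplier = 2) {
  for (nm in c("bend_stiffness", "stretch_modulus", "torsion_stiffness",
               "temperature_K", "ss_persistence_nm", "dx_multiplier"))
    stop_if_not_scalar_number(get(nm), nm, positive = TRUE)
  stop_if_not_scalar_number(nick_softening, "nick_softening", positive = TRUE)
  if (nick_softening < 1) stop("nick_softening must be >= 1", call. = FALSE)
  kBT <- BOLTZMANN_PN_NM_PER_K * temperature_K
  structure(list(bend_stiffness = bend_stiffness,
                 stretch_modulus = stretch_modulus,
                 torsion_stiffness = torsion_stiffness,
                 nick_softening = nick_softening,
                 temperature_K = temperature_K, kBT = kBT,
                 ss_persistence_nm = ss_persistence_nm,
                 dx_multiplier = dx_multiplier),
            class = "rod_params")
}

# coarse-grain element arrays so the rod has at most max_nodes nodes; only
# duplex-like runs are merged, nicks and ss elements are kept intact
coarsen_elements <- function(len, bend, kind, max_nodes) {
  while (length(len) + 1L > max_nodes) {
    g <- 2L
    r <- rle(kind)
    new_len <- numeric(0); new_bend <- numeric(0); new_kind <- character(0)
    pos <- 0L
    for (j in seq_along(r$lengths)) {
      idx <- pos + seq_len(r$lengths[j])
      pos <- pos + r$lengths[j]
      if (r$values[j] %in% c("duplex", "duplex_DX") && r$lengths[j] > 1L) {
        grp <- ceiling(seq_along(idx) / g)
        new_len <- c(new_len, tapply(len[idx], grp, sum))
        new_bend <- c(new_bend, tapply(bend[idx], grp, function(b) b[1L]))
        new_kind <- c(new_kind, rep(r$values[j], max(grp)))
      } else {
        new_len <- c(new_len, len[idx])
        new_bend <- c(new_bend, bend[idx])
        new_kind <- c(new_kind, kind[idx])
      }
    }
    if (length(new_len) == length(len)) break
    len <- as.numeric(new_len); bend <- as.numeric(new_bend); kind <- new_kind
  }
  list(len = len, bend = bend, kind = kind)
}

#' Build a discretized rod model
#'
#' Designs:
#' * `"dsDNA"`: a plain duplex of `bp` base pairs, all elements at the
#'   duplex bending stiffness;
#' * `"monomer"`: a single DHT tile — a DX core of `tile_length_bp`
#'   elements at `dx_multiplier` times the duplex stiffness, flanked by
#'   single-stranded sticky-end and loop segments (`ss_len_nt` each);
#' * `"filament"`: `I-[A-B]_n` — `2 * n_AB` DX tile cores joined by nicked
#'   one-bp elements (duplex stiffness divided by `nick_softening`), with
#'   terminal single-stranded segments.
#'
#' Nodes sit at per-bp arc positions (rise per bp), coarse-grained in
#' duplex runs so the rod never exceeds `max_nodes` nodes. Crossover
#' junction positions (tile boundaries) are recorded as `crossover_nodes`.
#'
#' @param design `"dsDNA"`, `"monomer"` or `"filament"`.
#' @param bp duplex length for `design = "dsDNA"`.
#' @param n_AB number of A-B tile pairs for `design = "filament"`.
#' @param tile_length_bp tile length per helix (bp).
#' @param ss_len_nt length of terminal single-stranded segments (nt).
#' @param geom a [helix_geometry()].
#' @param params a [rod_params()].
#' @param max_nodes coarse-graining cap on node count.
#' @return object of class `rod_model` with `node_pos` (arc-length nm),
#'   `element_len`, `element_bend` (pN nm^2), `element_kind`,
#'   `crossover_nodes`, `params`.
#' @export
build_rod <- function(design = c("dsDNA", "monomer", "filament"), bp = 24,
                      n_AB = 1, tile_length_bp = 47, ss_len_nt = 6,
                      geom = helix_geometry(), params = rod_params(),
                      max_nodes = 2000) {
  design <- match.arg(design)
  stopifnot(inherits(geom, "helix_geometry"), inherits(params, "rod_params"))
  rise <- geom$rise_nm_per_bp
  B_dup <- params$bend_stiffness
  B_dx <- params$dx_multiplier * B_dup
  B_nick <- B_dup / params$nick_softening
  B_ss <- params$kBT * params$ss_persistence_nm

  ss_el <- function(n) list(len = rep(rise, n), bend = rep(B_ss, n),
                            kind = rep("ss", n))
  dup_el <- function(n, B, kind) list(len = rep(rise, n), bend = rep(B, n),
                                      kind = rep(kind, n))
  cat_el <- function(...) {
    parts <- list(...)
    list(len = unlist(lapply(parts, `[[`, "len")),
         bend = unlist(lapply(parts, `[[`, "bend")),
         kind = unlist(lapply(parts, `[[`, "kind")))
  }

  if (design == "dsDNA") {
    stop_if_not_scalar_number(bp, "bp", positive = TRUE, integerish = TRUE)
    el <- dup_el(as.integer(bp), B_dup, "duplex")
    xovers <- integer(0)
  } else if (design == "monomer") {
    stop_if_not_scalar_number(tile_length_bp, "tile_length_bp",
                              positive = TRUE, integerish = TRUE)
    el <- cat_el(ss_el(ss_len_nt),
                 dup_el(tile_length_bp, B_dx, "duplex_DX"),
                 ss_el(ss_len_nt))
    xovers <- c(ss_len_nt + 1L, ss_len_nt + tile_length_bp + 1L)
  } else {
    stop_if_not_scalar_number(n_AB, "n_AB", positive = TRUE,
                              integerish = TRUE)
    n_tiles <- 2L * as.integer(n_AB)
    parts <- list(ss_el(ss_len_nt))
    for (i in seq_len(n_tiles)) {
      if (i > 1L) parts <- c(parts, list(dup_el(1L, B_nick, "nicked")))
      parts <- c(parts, list(dup_el(tile_length_bp, B_dx, "duplex_DX")))
    }
    parts <- c(parts, list(ss_el(ss_len_nt)))
    el <- do.call(cat_el, parts)
    xovers <- which(el$kind == "nicked")
  }
  if (length(el$len) < 1L) stop("zero-length design", call. = FALSE)

  el <- c(coarsen_elements(el$len, el$bend, el$kind, max_nodes),
          list())
  structure(list(node_pos = c(0, cumsum(el$len)),
                 element_len = el$len,
                 element_bend = el$bend,
                 element_kind = el$kind,
                 crossover_nodes = if (design == "filament")
                   which(el$kind == "nicked") else as.integer(xovers),
                 design = design, params = params),
            class = "rod_model")
}

#' @export
print.rod_model <- function(x, ...) {
  cat(sprintf("<rod model: %s> %d nodes, length %.2f nm; element kinds: %s\n",
              x$design, length(x$node_pos),
              max(x$node_pos),
              paste(sprintf("%s(%d)", names(table(x$element_kind)),
                            table(x$element_kind)), collapse = ", ")))
  invisible(x)
}

# hinge (interior-node) bending stiffness matrix K for one transverse
# direction: E = 1/2 u' K u with hinge angle theta_i =
# (u_{i+1}-u_i)/l_i - (u_i-u_{i-1})/l_{i-1} and hinge stiffness
# B_h / lbar (series/harmonic combination of the adjacent elements,
# attributed arc length lbar = (l_{i-1}+l_i)/2).
rod_stiffness_matrix <- function(rod) {
  l <- rod$element_len
  B <- rod$element_bend
  N <- length(l) + 1L
  if (N < 3L) return(matrix(0, N, N))
  Bh <- 2 / (1 / B[-length(B)] + 1 / B[-1L])       # harmonic mean per hinge
  lbar <- (l[-length(l)] + l[-1L]) / 2
  w <- Bh / lbar
  A <- matrix(0, N - 2L, N)
  for (i in seq_len(N - 2L)) {
    A[i, i] <- 1 / l[i]
    A[i, i + 1L] <- -(1 / l[i] + 1 / l[i + 1L])
    A[i, i + 2L] <- 1 / l[i + 1L]
  }
  crossprod(A * sqrt(w))
}

#' Per-node RMSF by normal-mode analysis
#'
#' Assembles the transverse-bending stiffness matrix of the discretized
#' rod, removes the two rigid-body modes (translation and rotation per
#' transverse direction), gives each remaining mode `kBT` of energy by
#' equipartition, and reports the root-mean-square fluctuation at each
#' node, summed over the two independent transverse directions.
#' Deterministic.
#'
#' @param rod a [build_rod()] model.
#' @param params optional [rod_params()] override (temperature enters
#'   through `kBT`).
#' @return object of class `rmsf_profile` with `node_pos`, `rmsf` (nm),
#'   `min_rmsf`, `max_rmsf`, `temperature_K`.
#' @export
compute_rmsf <- function(rod, params = NULL) {
  stopifnot(inherits(rod, "rod_model"))
  if (is.null(params)) params <- rod$params
  K <- rod_stiffness_matrix(rod)
  N <- nrow(K)
  if (N < 3L)
    stop("rod has no bending degrees of freedom (need >= 3 nodes)",
         call. = FALSE)
  # the rigid-body null space of a free bending rod is exactly
  # span{translation, rotation} = {1, arc position}; project it out and
  # invert the reduced stiffness. A rank deficiency beyond those two modes
  # shows up as a non-positive-definite reduced matrix.
  Qfull <- qr.Q(qr(cbind(1, rod$node_pos)), complete = TRUE)
  Qc <- Qfull[, 3:N, drop = FALSE]
  Kr <- crossprod(Qc, K %*% Qc)
  ch <- tryCatch(chol(Kr), error = function(e) NULL)
  if (is.null(ch))
    stop("singular non-rigid-body null space: reduced stiffness matrix ",
         "is not positive definite", call. = FALSE)
  M <- Qc %*% chol2inv(ch)            # covariance = kBT * Qc Kr^-1 Qc'
  var_1d <- params$kBT * rowSums(M * Qc)
  rmsf <- sqrt(2 * var_1d)  # two independent transverse directions
  structure(list(node_pos = rod$node_pos, rmsf = rmsf,
                 min_rmsf = min(rmsf), max_rmsf = max(rmsf),
                 temperature_K = params$temperature_K),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("<RMSF profile> %d nodes at %g K: min %.3f nm, max %.3f nm\n",
              length(x$rmsf), x$temperature_K, x$min_rmsf, x$max_rmsf))
  invisible(x)
}

#' @export
plot.rmsf_profile <- function(x, ...) {
  graphics::plot(x$node_pos, x$rmsf, type = "l", xlab = "arc length (nm)",
                 ylab = "RMSF (nm)", ...)
  invisible(x)
}

#' Relative bending compliance of a rod against a reference
#'
#' Effective bending stiffness of a beam of length `L`:
#' `kb = B_eff / L^exponent`, with `B_eff` the length-weighted harmonic mean
#' of element bending stiffness (springs in series) and the proportionality
#' constant cancelling in the ratio. Exponent 3 is cantilever beam theory;
#' exponent 1 (stiffness inversely proportional to length) is also
#' available. The returned ratio `kb(reference) / kb(rod)` exceeds 1 when
#' the rod is more compliant than the reference.
#'
#' @param reference,rod [build_rod()] models (reference conventionally the
#'   24-bp duplex).
#' @param exponent 1 or 3 (default 3).
#' @return dimensionless compliance ratio.
#' @export
relative_compliance <- function(reference, rod, exponent = 3) {
  stopifnot(inherits(reference, "rod_model"), inherits(rod, "rod_model"))
  if (!exponent %in% c(1, 3))
    stop("exponent must be 1 or 3", call. = FALSE)
  kb <- function(r) {
    L <- sum(r$element_len)
    if (L <= 0) stop("zero-length rod", call. = FALSE)
    B_eff <- L / sum(r$element_len / r$element_bend)
    B_eff / L^exponent
  }
  kb(reference) / kb(rod)
}
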