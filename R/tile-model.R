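# Strand/domain-level representation of DNA hairpin tiles (DHTs), design-rule
# validation, and the toehold-mediated strand-displacement activation cascade.
#
# Conventions: sequences are stored 5'->3' over {A,C,G,T}; intervals on
# strands are 0-based, half-open; complementarity is always checked as
# reverse-complement of the partner's annotated interval.

DNA_ALPHABET <- c("A", "C", "G", "T")
LABEL_KINDS <- c("biotin", "Cy3", "Cy5")

#' Watson-Crick reverse complement
#'
#' Thin wrapper over [Biostrings::reverseComplement()]; vectorized over the
#' input, and an involution (`reverse_complement(reverse_complement(x)) == x`).
#'
#' @param seq character vector of DNA sequences over \{A,C,G,T\} (5'->3').
#'   Empty strings are allowed and map to themselves.
#' @return character vector of reverse complements, 5'->3'.
#' @examples
#' reverse_complement("TGAACC")  # "GGTTCA"
#' reverse_complement("GTGACA")  # "TGTCAC"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("`seq` must be character", call. = FALSE)
  if (length(seq) == 0L) return(character(0))
  bad <- grepl(paste0("[^", paste(DNA_ALPHABET, collapse = ""), "]"), seq)
  if (any(bad))
    stop("non-DNA character in sequence(s): ",
         paste(seq[bad], collapse = ", "), call. = FALSE)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

#' Construct a strand specification
#'
#' @param name short identifier, e.g. `"a1"`.
#' @param sequence DNA string over \{A,C,G,T\}, 5'->3'; lowercase is
#'   normalized to uppercase.
#' @param labels optional data.frame with columns `label`
#'   (one of biotin, Cy3, Cy5) and `end` (`"5p"` or `"3p"`); at most one
#'   label per end.
#' @return an object of class `strand_spec`.
#' @export
strand_spec <- function(name, sequence, labels = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string", call. = FALSE)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("strand ", name, ": sequence contains non-DNA characters",
         call. = FALSE)
  if (!is.null(labels)) {
    stopifnot(is.data.frame(labels), all(c("label", "end") %in% names(labels)))
    if (!all(labels$label %in% LABEL_KINDS))
      stop("labels must be one of ", paste(LABEL_KINDS, collapse = ", "),
           call. = FALSE)
    if (!all(labels$end %in% c("5p", "3p")))
      stop("label end must be '5p' or '3p'", call. = FALSE)
    if (anyDuplicated(labels$end))
      stop("at most one label per strand end", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence, labels = labels),
            class = "strand_spec")
}

#' @export
print.strand_spec <- function(x, ...) {
  lab <- if (is.null(x$labels) || nrow(x$labels) == 0L) ""
         else paste0(" [", paste(x$labels$label, x$labels$end, sep = "@",
                                 collapse = ", "), "]")
  cat(sprintf("<strand %s> %d nt: %s%s\n", x$name, nchar(x$sequence),
              x$sequence, lab))
  invisible(x)
}

#' Domain annotations on strands
#'
#' A set of 0-based half-open intervals, each with a structural role.
#'
#' @param strand,start,end,role parallel vectors; `role` is one of
#'   `core`, `sticky_end`, `stem`, `loop`, `toehold`.
#' @return a data.frame with one row per annotation.
#' @export
domain_annotation <- function(strand, start, end, role) {
  roles <- c("core", "sticky_end", "stem", "loop", "toehold")
  if (!all(role %in% roles))
    stop("role must be one of ", paste(roles, collapse = ", "), call. = FALSE)
  if (any(start < 0) || any(end <= start))
    stop("need 0 <= start < end for every domain", call. = FALSE)
  data.frame(strand = as.character(strand), start = as.integer(start),
             end = as.integer(end), role = as.character(role),
             stringsAsFactors = FALSE)
}

#' Helix geometry of B-form DNA
#'
#' Defaults are the canonical B-DNA beam parameters: 0.34 nm axial rise per
#' base pair, 2.25 nm helical diameter, 10.5 base pairs per turn.
#'
#' @param rise_nm_per_bp axial rise per base pair (nm).
#' @param diameter_nm helical diameter (nm).
#' @param bp_per_turn base pairs per helical turn.
#' @return an object of class `helix_geometry`.
#' @export
helix_geometry <- function(rise_nm_per_bp = 0.34, diameter_nm = 2.25,
                           bp_per_turn = 10.5) {
  stop_if_not_scalar_number(rise_nm_per_bp, "rise_nm_per_bp", positive = TRUE)
  stop_if_not_scalar_number(diameter_nm, "diameter_nm", positive = TRUE)
  stop_if_not_scalar_number(bp_per_turn, "bp_per_turn", positive = TRUE)
  structure(list(rise_nm_per_bp = rise_nm_per_bp, diameter_nm = diameter_nm,
                 bp_per_turn = bp_per_turn), class = "helix_geometry")
}

#' Construct a DHT tile specification
#'
#' A DHT monomer is assembled from exactly four strands: a core strand
#' bridging the two crossover junctions, strands carrying single-stranded
#' sticky ends, and a hairpin strand (stem + loop) whose associated sticky
#' end serves as the toehold for strand-displacement activation.
#'
#' @param tile_id tile label, conventionally `"A"`, `"B"`, `"C"`, `"D"`.
#' @param strands list of exactly four [strand_spec()] objects.
#' @param domains data.frame from [domain_annotation()].
#' @param sticky_pairs data.frame of declared inter-tile complementary
#'   sticky-end pairs, columns `strand`, `start`, `end`, `partner_tile`,
#'   `partner_strand`, `partner_start`, `partner_end` (intervals 0-based,
#'   half-open, on 5'->3' sequences).
#' @param crossover_separation_nt separation between the two intermolecular
#'   crossover junctions, in nucleotides (> 0).
#' @param tile_length_bp tile length per helix, in base pairs.
#' @return an object of class `tile_spec`. Construction does not validate
#'   design rules; see [validate_tile()].
#' @export
tile_spec <- function(tile_id, strands, domains, sticky_pairs = NULL,
                      crossover_separation_nt = 26L, tile_length_bp = 47L) {
  if (!is.list(strands) || !all(vapply(strands, inherits, TRUE, "strand_spec")))
    stop("`strands` must be a list of strand_spec objects", call. = FALSE)
  names(strands) <- vapply(strands, `[[`, "", "name")
  stop_if_not_scalar_number(crossover_separation_nt, "crossover_separation_nt",
                            positive = TRUE, integerish = TRUE)
  stop_if_not_scalar_number(tile_length_bp, "tile_length_bp",
                            positive = TRUE, integerish = TRUE)
  structure(list(tile_id = as.character(tile_id), strands = strands,
                 domains = domains, sticky_pairs = sticky_pairs,
                 crossover_separation_nt = as.integer(crossover_separation_nt),
                 tile_length_bp = as.integer(tile_length_bp)),
            class = "tile_spec")
}

#' @export
print.tile_spec <- function(x, ...) {
  cat(sprintf("<DHT tile %s> %d strands, %d domain annotations, %d bp/helix\n",
              x$tile_id, length(x$strands), nrow(x$domains), x$tile_length_bp))
  invisible(x)
}

# sequence of a 0-based half-open interval on a strand
strand_subseq <- function(tile, strand, start, end) {
  s <- tile$strands[[strand]]
  if (is.null(s)) return(NA_character_)
  if (start < 0 || end > nchar(s$sequence)) return(NA_character_)
  substr(s$sequence, start + 1L, end)
}

#' Construct a reaction system
#'
#' @param tiles list of [tile_spec()] objects (named by tile id).
#' @param initiator a [strand_spec()] for the single-stranded initiator, or
#'   `NULL` for an initiator-free (control) system.
#' @return an object of class `reaction_system`. Activation edges are not
#'   stored; they are derived from sequences alone by [sdr_cascade()].
#' @export
reaction_system <- function(tiles, initiator = NULL) {
  if (!is.list(tiles) || !all(vapply(tiles, inherits, TRUE, "tile_spec")))
    stop("`tiles` must be a list of tile_spec objects", call. = FALSE)
  names(tiles) <- vapply(tiles, `[[`, "", "tile_id")
  if (!is.null(initiator) && !inherits(initiator, "strand_spec"))
    stop("`initiator` must be a strand_spec or NULL", call. = FALSE)
  structure(list(tiles = tiles, initiator = initiator),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("<reaction system> tiles: %s; initiator: %s\n",
              paste(names(x$tiles), collapse = ", "),
              if (is.null(x$initiator)) "none" else x$initiator$name))
  invisible(x)
}

empty_violations <- function() {
  data.frame(rule = character(0), location = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

violation <- function(rule, location, detail) {
  data.frame(rule = rule, location = location, detail = detail,
             stringsAsFactors = FALSE)
}

#' Validate a tile against the DHT design rules
#'
#' Checks (violations are returned as data, never raised):
#' * the tile has exactly four strands;
#' * domain intervals lie within strand bounds and do not overlap per strand;
#' * hairpin stem halves are reverse-complementary (stems are paired in
#'   annotation order per strand);
#' * the toehold is single-stranded, i.e. not covered by any stem annotation;
#' * every declared sticky pair is reverse-complementary (cross-tile pairs
#'   need `system`; unresolvable partners are reported as violations).
#'
#' @param tile a [tile_spec()].
#' @param system optional [reaction_system()] used to resolve partner tiles
#'   of declared sticky pairs.
#' @return a data.frame of violations with columns `rule`, `location`,
#'   `detail`; zero rows iff the tile passes.
#' @export
validate_tile <- function(tile, system = NULL) {
  stopifnot(inherits(tile, "tile_spec"))
  v <- empty_violations()
  id <- tile$tile_id

  if (length(tile$strands) != 4L)
    v <- rbind(v, violation("strand_count", id,
                            sprintf("expected 4 strands, found %d",
                                    length(tile$strands))))

  dom <- tile$domains
  for (i in seq_len(nrow(dom))) {
    s <- tile$strands[[dom$strand[i]]]
    loc <- sprintf("%s.%s[%d,%d)", id, dom$strand[i], dom$start[i], dom$end[i])
    if (is.null(s)) {
      v <- rbind(v, violation("domain_out_of_bounds", loc, "unknown strand"))
      next
    }
    if (dom$end[i] > nchar(s$sequence))
      v <- rbind(v, violation("domain_out_of_bounds", loc,
                              sprintf("strand has %d nt", nchar(s$sequence))))
  }
  for (sn in unique(dom$strand)) {
    d <- dom[dom$strand == sn, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      v <- rbind(v, violation("domain_overlap", paste0(id, ".", sn),
                              "overlapping domain annotations"))
  }

  # hairpin stems: paired in order per strand, halves reverse-complementary
  for (sn in unique(dom$strand[dom$role == "stem"])) {
    st <- dom[dom$strand == sn & dom$role == "stem", , drop = FALSE]
    st <- st[order(st$start), , drop = FALSE]
    if (nrow(st) %% 2L != 0L) {
      v <- rbind(v, violation("stem_unpaired", paste0(id, ".", sn),
                              "odd number of stem annotations"))
      next
    }
    for (j in seq_len(nrow(st) / 2L)) {
      h1 <- strand_subseq(tile, sn, st$start[2L * j - 1L], st$end[2L * j - 1L])
      h2 <- strand_subseq(tile, sn, st$start[2L * j], st$end[2L * j])
      if (is.na(h1) || is.na(h2)) next
      if (!identical(h2, reverse_complement(h1)))
        v <- rbind(v, violation("stem_mismatch", paste0(id, ".", sn),
                                sprintf("%s vs %s", h1, h2)))
    }
  }

  # toehold must not be covered by any stem (duplex) annotation
  th <- dom[dom$role == "toehold", , drop = FALSE]
  stems <- dom[dom$role == "stem", , drop = FALSE]
  for (i in seq_len(nrow(th))) {
    ov <- stems$strand == th$strand[i] &
      stems$start < th$end[i] & stems$end > th$start[i]
    if (any(ov))
      v <- rbind(v, violation("toehold_not_single_stranded",
                              paste0(id, ".", th$strand[i]),
                              "toehold overlaps a stem duplex"))
  }

  # declared sticky pairs reverse-complementary
  sp <- tile$sticky_pairs
  for (i in seq_len(if (is.null(sp)) 0L else nrow(sp))) {
    own <- strand_subseq(tile, sp$strand[i], sp$start[i], sp$end[i])
    ptile <- if (identical(sp$partner_tile[i], id)) tile
             else if (!is.null(system)) system$tiles[[sp$partner_tile[i]]]
             else NULL
    loc <- sprintf("%s.%s ~ %s.%s", id, sp$strand[i],
                   sp$partner_tile[i], sp$partner_strand[i])
    if (is.null(ptile)) {
      v <- rbind(v, violation("sticky_pair_unresolved", loc,
                              "partner tile not available"))
      next
    }
    par <- strand_subseq(ptile, sp$partner_strand[i],
                         sp$partner_start[i], sp$partner_end[i])
    if (is.na(own) || is.na(par)) {
      v <- rbind(v, violation("sticky_pair_unresolved", loc,
                              "interval outside strand"))
      next
    }
    if (!identical(par, reverse_complement(own)))
      v <- rbind(v, violation("sticky_pair_mismatch", loc,
                              sprintf("%s vs %s", own, par)))
  }
  v
}

#' Validate every tile in a reaction system
#'
#' @param system a [reaction_system()].
#' @return combined violation data.frame over all tiles.
#' @export
validate_system <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  do.call(rbind, c(list(empty_violations()),
                   lapply(system$tiles, validate_tile, system = system)))
}

# toehold and loop sequence of a tile's hairpin machinery (NA if absent)
tile_toehold <- function(tile) {
  th <- tile$domains[tile$domains$role == "toehold", , drop = FALSE]
  if (nrow(th) == 0L) return(NA_character_)
  strand_subseq(tile, th$strand[1L], th$start[1L], th$end[1L])
}

tile_loop <- function(tile) {
  lp <- tile$domains[tile$domains$role == "loop", , drop = FALSE]
  if (nrow(lp) == 0L) return(NA_character_)
  strand_subseq(tile, lp$strand[1L], lp$start[1L], lp$end[1L])
}

#' Replay the strand-displacement activation cascade
#'
#' Starting from the initiator's 3'-terminal segment, repeatedly finds the
#' tile whose single-stranded toehold is complementary to the current
#' invading segment, opens that tile's hairpin (a topological flag, not a
#' thermodynamic computation), and takes its exposed loop as the next
#' invader. The cascade closes when a newly exposed segment is
#' sequence-identical to the initiator's active segment, so the initiator's
#' role is regenerated; a non-closing system yields the maximal prefix.
#'
#' @param system a validated [reaction_system()]. A system without an
#'   initiator returns an empty event list (no polymerization without
#'   initiator).
#' @return data.frame of activation events with columns `step`, `invader`,
#'   `segment` (invading sequence), `target` (tile opened), `toehold`,
#'   `exposed` (loop revealed by opening), `closes` (logical: exposed
#'   segment identical to the initiator's active segment).
#' @export
sdr_cascade <- function(system) {
  stopifnot(inherits(system, "reaction_system"))
  if (length(system$tiles) == 0L)
    stop("empty system: no tiles", call. = FALSE)
  events <- data.frame(step = integer(0), invader = character(0),
                       segment = character(0), target = character(0),
                       toehold = character(0), exposed = character(0),
                       closes = logical(0), stringsAsFactors = FALSE)
  if (is.null(system$initiator)) return(events)

  iseq <- system$initiator$sequence
  toeholds <- vapply(system$tiles, tile_toehold, "")
  loops <- vapply(system$tiles, tile_loop, "")

  # 3'-terminal segment of length L (the business end of an invader)
  tail3 <- function(seq, L) {
    if (is.na(seq) || nchar(seq) < L) NA_character_
    else substr(seq, nchar(seq) - L + 1L, nchar(seq))
  }
  # find the tile whose toehold is complementary to the invader's 3' tail
  find_target <- function(invader_seq, candidates) {
    for (tid in candidates) {
      th <- toeholds[[tid]]
      if (is.na(th) || !nzchar(th)) next
      seg <- tail3(invader_seq, nchar(th))
      if (!is.na(seg) && identical(seg, reverse_complement(th)))
        return(list(tile = tid, segment = seg))
    }
    NULL
  }

  hit <- find_target(iseq, names(system$tiles))
  if (is.null(hit)) return(events)
  initiator_segment <- hit$segment

  first_tile <- hit$tile
  invader <- system$initiator$name
  segment <- hit$segment
  target <- hit$tile
  opened <- character(0)
  step <- 0L
  repeat {
    step <- step + 1L
    exposed <- loops[[target]]
    events <- rbind(events, data.frame(
      step = step, invader = invader, segment = segment, target = target,
      toehold = toeholds[[target]], exposed = exposed, closes = FALSE,
      stringsAsFactors = FALSE))
    opened <- c(opened, target)
    if (is.na(exposed)) break
    # cascade closes when the newly exposed loop carries a 3' segment
    # identical to the initiator's active segment: it re-invades the first
    # tile, regenerating the initiator's role
    closing_seg <- tail3(exposed, nchar(initiator_segment))
    if (!is.na(closing_seg) && identical(closing_seg, initiator_segment)) {
      events <- rbind(events, data.frame(
        step = step + 1L, invader = target, segment = closing_seg,
        target = first_tile, toehold = toeholds[[first_tile]],
        exposed = loops[[first_tile]], closes = TRUE,
        stringsAsFactors = FALSE))
      break
    }
    hit <- find_target(exposed, setdiff(names(system$tiles), opened))
    if (is.null(hit)) break
    invader <- target
    segment <- hit$segment
    target <- hit$tile
  }
  events
}

#' Helical turns between crossovers, and the side the next monomer binds
#'
#' The separation between the two intermolecular crossover junctions, in
#' nucleotides, fixes the number of helical turns between them. Rounded to
#' the nearest half-turn: an integer number of turns places the next monomer
#' on the opposite side of the growing chain (2D growth geometry), a
#' half-integer on the same side (linear 1D growth).
#'
#' @param separation_nt crossover separation (nt, > 0).
#' @param geom a [helix_geometry()].
#' @return list with `turns` (separation / bp_per_turn), `nearest_half_turn`
#'   and `side` (`"same"` or `"opposite"`).
#' @examples
#' crossover_turns_and_side(26)  # ~2.5 turns, same side (1D filaments)
#' crossover_turns_and_side(32)  # ~3 turns, opposite side (2D platelets)
#' @export
crossover_turns_and_side <- function(separation_nt, geom = helix_geometry()) {
  stop_if_not_scalar_number(separation_nt, "separation_nt", positive = TRUE)
  stopifnot(inherits(geom, "helix_geometry"))
  turns <- separation_nt / geom$bp_per_turn
  nearest <- round(turns * 2) / 2
  side <- if (abs(nearest - round(nearest)) < 1e-9) "opposite" else "same"
  list(turns = turns, nearest_half_turn = nearest, side = side)
}

#' Physical dimensions of a tile
#'
#' Length along the helical axis is `tile_length_bp * rise`; width across
#' the two helices is twice the helical diameter plus a configurable
#' inter-helix gap (default 0.5 nm, giving the conventional ~5 nm DX width);
#' thickness is one helical diameter.
#'
#' @param tile a [tile_spec()] with `tile_length_bp` set.
#' @param geom a [helix_geometry()].
#' @param gap_nm inter-helix gap (nm).
#' @return named numeric vector `c(thickness_nm, width_nm, length_nm)`.
#' @export
tile_dimensions <- function(tile, geom = helix_geometry(), gap_nm = 0.5) {
  stopifnot(inherits(tile, "tile_spec"), inherits(geom, "helix_geometry"))
  stop_if_not_scalar_number(gap_nm, "gap_nm", nonneg = TRUE)
  if (is.null(tile$tile_length_bp) || tile$tile_length_bp <= 0)
    stop("tile_length_bp must be > 0", call. = FALSE)
  c(thickness_nm = geom$diameter_nm,
    width_nm = 2 * geom$diameter_nm + gap_nm,
    length_nm = tile$tile_length_bp * geom$rise_nm_per_bp)
}

#' Sequence-symmetry score
#'
#' Number of distinct k-mers occurring more than once in a sequence: a
#' design-quality heuristic in the spirit of sequence symmetry minimization
#' (lower is better; 0 means every k-mer is unique).
#'
#' @param seq DNA string.
#' @param k k-mer size, `1 <= k <= nchar(seq)`.
#' @return integer count of repeated distinct k-mers.
#' @export
symmetry_score <- function(seq, k) {
  if (!is.character(seq) || length(seq) != 1L)
    stop("`seq` must be a single string", call. = FALSE)
  stop_if_not_scalar_number(k, "k", positive = TRUE, integerish = TRUE)
  n <- nchar(seq)
  if (k > n) stop("`k` must be <= nchar(seq)", call. = FALSE)
  kmers <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  sum(table(kmers) > 1L)
}
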