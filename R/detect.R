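# Threshold screening with 50% fallback and proton-transfer pairing;
# correlated-motion filtering; mode classification.

#' Screening configuration for internal-coordinate changes
#'
#' Defaults follow the optimized screening tiers: 0.4 Angstrom for bonds, 10
#' degrees for angles, 20 degrees for dihedrals; when nothing at all is
#' flagged the thresholds are reduced by 50% once (low-magnitude modes such
#' as hindered rotations); hydrogen bond-breaking events look for a paired
#' bond-making event at a secondary reduced bond threshold
#' (`proton_factor * bond_thresh`).
#'
#' @param bond_thresh Bond-change threshold, Angstrom.
#' @param angle_thresh Angle-change threshold, degrees.
#' @param dihedral_thresh Dihedral-change threshold, degrees.
#' @param fallback_factor Multiplier applied to all thresholds on the
#'   fallback retry (< 1).
#' @param proton_factor Fraction of `bond_thresh` used as the secondary
#'   threshold when pairing proton transfers.
#' @param max_fallbacks Maximum number of fallback retries (the fallback
#'   fires only when the primary tier flags nothing).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(bond_thresh = 0.4,
                          angle_thresh = 10,
                          dihedral_thresh = 20,
                          fallback_factor = 0.5,
                          proton_factor = 0.5,
                          max_fallbacks = 1L) {
  stopifnot(bond_thresh > 0, angle_thresh > 0, dihedral_thresh > 0,
            fallback_factor > 0, fallback_factor < 1, proton_factor > 0)
  structure(list(bond_thresh = bond_thresh,
                 angle_thresh = angle_thresh,
                 dihedral_thresh = dihedral_thresh,
                 fallback_factor = fallback_factor,
                 proton_factor = proton_factor,
                 max_fallbacks = as.integer(max_fallbacks)),
            class = "screen_config")
}

kind_threshold <- function(kind, config, scale = 1) {
  scale * unname(c(bond = config$bond_thresh,
                   angle = config$angle_thresh,
                   dihedral = config$dihedral_thresh,
                   improper = config$dihedral_thresh)[kind])
}

empty_changes <- function() {
  tibble::tibble(kind = character(0), a1 = integer(0), a2 = integer(0),
                 a3 = integer(0), a4 = integer(0), label = character(0),
                 delta = numeric(0), classification = character(0),
                 provenance = character(0))
}

change_sort <- function(changes) {
  kind_rank <- match(changes$kind, c("bond", "angle", "dihedral", "improper"))
  ord <- order(kind_rank, -abs(changes$delta), changes$a1, changes$a2,
               changes$a3, changes$a4, na.last = TRUE)
  changes[ord, , drop = FALSE]
}

#' Screen internal-coordinate deltas for meaningful changes
#'
#' Tier 1 flags coordinates whose absolute change meets its kind's
#' threshold. If nothing at all is flagged, one retry is made with all
#' thresholds multiplied by `fallback_factor` (provenance `"fallback"`).
#' For every flagged hydrogen-containing bond break, a candidate partner
#' bond of the same hydrogen shortening by at least
#' `proton_factor * bond_thresh` is added as the paired formation
#' (provenance `"proton_pairing"`), and symmetrically for flagged
#' formations; pairing never adds a partner already bonded to the hydrogen
#' in the supplied graph.
#'
#' @param deltas Tibble of internal coordinates with a `delta` column (from
#'   the evaluated forward/reverse or selected trajectory frames).
#' @param config A [screen_config()].
#' @param graph Optional `mol_graph` (used for element symbols and for the
#'   proton-pairing double-counting guard).
#' @param elements Optional character vector of element symbols (defaults to
#'   `graph$atoms$element`).
#' @return A change tibble sorted by kind then decreasing `|delta|`: columns
#'   `kind`, `a1`..`a4`, `label`, `delta`, `classification`
#'   (`bond_break`/`bond_form`/`angle_change`/`rotation`), `provenance`
#'   (`primary`/`fallback`/`proton_pairing`).
#' @export
detect_changes <- function(deltas, config = screen_config(), graph = NULL,
                           elements = NULL) {
  if (is.null(elements) && !is.null(graph)) elements <- graph$atoms$element
  deltas <- deltas[deltas$kind %in% c("bond", "angle", "dihedral"), ,
                   drop = FALSE]
  if (nrow(deltas) == 0L) return(empty_changes())

  flag_tier <- function(scale, provenance) {
    thr <- kind_threshold(deltas$kind, config, scale)
    hit <- abs(deltas$delta) >= thr
    out <- deltas[hit, , drop = FALSE]
    if (nrow(out) == 0L) return(empty_changes())
    tibble::tibble(
      kind = out$kind, a1 = out$a1, a2 = out$a2, a3 = out$a3, a4 = out$a4,
      label = out$label %||% internal_labels(out, elements),
      delta = out$delta,
      classification = dplyr::case_when(
        out$kind == "bond" & out$delta > 0 ~ "bond_break",
        out$kind == "bond" ~ "bond_form",
        out$kind == "angle" ~ "angle_change",
        TRUE ~ "rotation"),
      provenance = provenance)
  }

  changes <- flag_tier(1, "primary")
  if (nrow(changes) == 0L && config$max_fallbacks >= 1L) {
    changes <- flag_tier(config$fallback_factor, "fallback")
  }

  # proton-transfer pairing
  if (nrow(changes) > 0L && !is.null(elements)) {
    bonds <- deltas[deltas$kind == "bond", , drop = FALSE]
    flagged_bonds <- changes[changes$kind == "bond", , drop = FALSE]
    additions <- list()
    for (r in seq_len(nrow(flagged_bonds))) {
      ev <- flagged_bonds[r, ]
      ats <- c(ev$a1, ev$a2)
      h <- ats[elements[ats] == "H"]
      if (length(h) == 0L) next
      h <- h[[1]]
      breaking <- ev$delta > 0
      cand <- bonds[(bonds$a1 == h | bonds$a2 == h) &
                      !(bonds$a1 == ev$a1 & bonds$a2 == ev$a2), ,
                    drop = FALSE]
      # partner must move oppositely past the secondary threshold
      sec <- config$proton_factor * config$bond_thresh
      cand <- if (breaking) {
        cand[cand$delta <= -sec, , drop = FALSE]
      } else {
        cand[cand$delta >= sec, , drop = FALSE]
      }
      if (nrow(cand) == 0L) next
      # skip partners already flagged
      key <- paste(changes$a1, changes$a2)
      cand <- cand[!(paste(cand$a1, cand$a2) %in% key), , drop = FALSE]
      # a forming partner must not already be bonded to the hydrogen
      if (!is.null(graph) && breaking) {
        keep <- !vapply(seq_len(nrow(cand)), function(k) {
          has_edge(graph, cand$a1[k], cand$a2[k])
        }, logical(1))
        cand <- cand[keep, , drop = FALSE]
      }
      if (nrow(cand) == 0L) next
      cand <- cand[order(-abs(cand$delta), cand$a1, cand$a2), , drop = FALSE]
      best <- cand[1, ]
      additions[[length(additions) + 1L]] <- tibble::tibble(
        kind = "bond", a1 = best$a1, a2 = best$a2, a3 = NA_integer_,
        a4 = NA_integer_,
        label = best$label %||% internal_labels(best, elements),
        delta = best$delta,
        classification = if (breaking) "bond_form" else "bond_break",
        provenance = "proton_pairing")
    }
    if (length(additions)) {
      changes <- dplyr::distinct(
        dplyr::bind_rows(changes, additions),
        .data$kind, .data$a1, .data$a2, .keep_all = TRUE)
    }
  }

  change_sort(changes)
}

#' Filter correlated motion out of a change list
#'
#' Angle and dihedral changes involving any atom of a flagged bond change
#' are removed (they are geometric consequences of the bond event).
#' Equivalent dihedrals sharing a rotational axis (the same unordered
#' central atom pair) are reduced to one: the dihedral defined by the
#' heaviest terminal atoms (sum of terminal masses; ties by the larger
#' single terminal mass, then lowest indices). Bond changes pass through
#' untouched.
#'
#' @param changes Change tibble from [detect_changes()].
#' @param graph The `mol_graph` of the transition state (for element
#'   masses).
#' @return The filtered change tibble.
#' @export
filter_correlated <- function(changes, graph) {
  if (nrow(changes) == 0L) return(changes)
  el <- graph$atoms$element
  bond_rows <- changes$kind == "bond"
  bond_atoms <- unique(c(changes$a1[bond_rows], changes$a2[bond_rows]))

  keep <- vapply(seq_len(nrow(changes)), function(r) {
    if (changes$kind[r] == "bond") return(TRUE)
    ats <- c(changes$a1[r], changes$a2[r], changes$a3[r], changes$a4[r])
    !any(stats::na.omit(ats) %in% bond_atoms)
  }, logical(1))
  changes <- changes[keep, , drop = FALSE]

  dih <- which(changes$kind == "dihedral")
  if (length(dih) > 1L) {
    axis <- vapply(dih, function(r) {
      paste(sort(c(changes$a2[r], changes$a3[r])), collapse = "-")
    }, character(1))
    drop <- integer(0)
    for (ax in unique(axis)) {
      grp <- dih[axis == ax]
      if (length(grp) == 1L) next
      m1 <- atomic_mass(el[changes$a1[grp]])
      m4 <- atomic_mass(el[changes$a4[grp]])
      ord <- order(-(m1 + m4), -pmax(m1, m4), changes$a1[grp],
                   changes$a4[grp])
      drop <- c(drop, grp[ord[-1]])
    }
    if (length(drop)) changes <- changes[-drop, , drop = FALSE]
  }
  change_sort(changes)
}

#' Classify the transition-state mode from the filtered changes
#'
#' Appends pyramidal-inversion events and derives the overall mode class.
#' An inversion is reported for any 3-coordinate center free of flagged
#' bond changes whose three-angle sum crosses (or touches) 354 degrees
#' between the frames (360 = planar), or whose signed out-of-plane angle
#' changes sign with `|delta|` beyond the dihedral threshold. Bond events
#' give `bond_change` (`mixed` if rotations or inversions also survive);
#' dihedral-only changes give `rotation`; inversion-only gives
#' `inversion`; an empty list gives `none`.
#'
#' @param changes Filtered change tibble.
#' @param graph `mol_graph` of the transition state.
#' @param forward,reverse Geometry tibbles of the two compared frames.
#' @param config A [screen_config()].
#' @return List with `mode_class` (character scalar) and `changes` (the
#'   change tibble with inversion rows appended, kind `"improper"`).
#' @export
classify_mode <- function(changes, graph, forward, reverse,
                          config = screen_config()) {
  nb <- graph_neighbors(graph)
  bond_rows <- changes$kind == "bond"
  bond_atoms <- unique(c(changes$a1[bond_rows], changes$a2[bond_rows]))
  el <- graph$atoms$element

  inversions <- list()
  for (ctr in seq_along(nb)) {
    nbs <- nb[[ctr]]
    if (length(nbs) != 3L || ctr %in% bond_atoms ||
        any(nbs %in% bond_atoms)) next
    angle_sum <- function(geom) {
      xyz <- coords(geom)
      cmb <- utils::combn(nbs, 2L)
      sum(vapply(seq_len(ncol(cmb)), function(k) {
        angle_between_deg(xyz[cmb[1, k], ] - xyz[ctr, ],
                          xyz[cmb[2, k], ] - xyz[ctr, ])
      }, numeric(1)))
    }
    oop <- function(geom) {
      xyz <- coords(geom)
      out_of_plane_deg(xyz[ctr, ], xyz[nbs[1], ], xyz[nbs[2], ],
                       xyz[nbs[3], ])
    }
    s_f <- angle_sum(forward); s_r <- angle_sum(reverse)
    o_f <- oop(forward); o_r <- oop(reverse)
    crosses <- (s_f - 354) * (s_r - 354) <= 0
    flips <- sign(o_f) != sign(o_r) &&
      abs(o_f - o_r) >= config$dihedral_thresh
    if (crosses || flips) {
      coord <- tibble::tibble(kind = "improper", a1 = ctr, a2 = nbs[1],
                              a3 = nbs[2], a4 = nbs[3])
      inversions[[length(inversions) + 1L]] <- tibble::tibble(
        kind = "improper", a1 = ctr, a2 = nbs[1], a3 = nbs[2], a4 = nbs[3],
        label = internal_labels(coord, el),
        delta = o_f - o_r,
        classification = "inversion",
        provenance = "primary")
    }
  }
  if (length(inversions)) {
    changes <- change_sort(dplyr::bind_rows(changes, inversions))
  }

  cls <- changes$classification
  has_bond <- any(cls %in% c("bond_break", "bond_form"))
  has_rot <- any(cls == "rotation")
  has_inv <- any(cls == "inversion")
  has_ang <- any(cls == "angle_change")
  mode_class <- if (nrow(changes) == 0L) {
    "none"
  } else if (has_bond) {
    if (has_rot || has_inv) "mixed" else "bond_change"
  } else if (has_rot && has_inv) {
    "mixed"
  } else if (has_rot) {
    "rotation"
  } else if (has_inv) {
    "inversion"
  } else if (has_ang) {
    "mixed"
  } else {
    "none"
  }
  list(mode_class = mode_class, changes = changes)
}
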