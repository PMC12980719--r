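# Internal coordinates: enumeration from graph topology, evaluation on
# Cartesian frames, and signed differences (with dihedral wrap-around).

angle_between_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("undefined angle: zero-length vector",
                               call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Signed dihedral (degrees, (-180, 180]) via the standard atan2
# construction: project the outer bond vectors onto the plane normal to the
# central axis; the sign follows the right-hand rule about j->k.
dihedral_deg <- function(p1, p2, p3, p4) {
  axis <- p3 - p2
  na2 <- sum(axis^2)
  if (na2 == 0) stop("undefined dihedral: zero-length axis", call. = FALSE)
  ax <- axis / sqrt(na2)
  u <- (p1 - p2) - sum((p1 - p2) * ax) * ax
  w <- (p4 - p3) - sum((p4 - p3) * ax) * ax
  if (sum(u^2) == 0 || sum(w^2) == 0) {
    stop("undefined dihedral: collinear atoms", call. = FALSE)
  }
  ang <- atan2(sum(cross3(ax, u) * w), sum(u * w)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

canonical_internal <- function(kind, a) {
  if (kind == "bond" && a[1] > a[2]) a <- rev(a)
  if (kind == "angle" && a[1] > a[3]) a <- rev(a)
  if (kind == "dihedral" && a[1] > a[4]) a <- rev(a)
  a
}

#' Enumerate a nonredundant internal-coordinate set from graph topology
#'
#' Bonds are the graph's edge set (optionally unioned with edges of reactant
#' or product graphs so forming/breaking coordinates are never missed);
#' angles are all neighbor pairs at each atom of degree >= 2; dihedrals are
#' all `i-j-k-l` chains about each bond `j-k`. The list is deduplicated under
#' canonical orientation (first index < last index).
#'
#' @param graph A `mol_graph`.
#' @param augment Optional list of `mol_graph`s (e.g. reactant/product) whose
#'   edges augment the bond set. Atom counts must match.
#' @return A tibble with columns `kind` (`"bond"`, `"angle"`, `"dihedral"`)
#'   and 1-based atom index columns `a1`..`a4` (`NA` where unused).
#' @export
enumerate_internals <- function(graph, augment = NULL) {
  n <- n_atoms(graph)
  edges <- graph$bonds[, c("i", "j")]
  for (g in augment %||% list()) {
    if (n_atoms(g) != n) {
      stop("augmentation graph has a different atom count", call. = FALSE)
    }
    edges <- rbind(edges, g$bonds[, c("i", "j")])
  }
  edges <- dplyr::distinct(dplyr::arrange(edges, .data$i, .data$j))

  union_graph <- new_mol_graph(graph$atoms,
                               tibble::tibble(i = edges$i, j = edges$j,
                                              order = 1, dative = FALSE))
  nb <- graph_neighbors(union_graph)

  rows <- list(tibble::tibble(kind = "bond", a1 = edges$i, a2 = edges$j,
                              a3 = NA_integer_, a4 = NA_integer_))

  for (ctr in seq_len(n)) {
    nbs <- nb[[ctr]]
    if (length(nbs) >= 2L) {
      cmb <- utils::combn(nbs, 2L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = "angle", a1 = cmb[1, ], a2 = ctr, a3 = cmb[2, ],
        a4 = NA_integer_)
    }
  }

  dih <- list()
  for (r in seq_len(nrow(edges))) {
    jj <- edges$i[r]; kk <- edges$j[r]
    for (ii in setdiff(nb[[jj]], kk)) {
      for (ll in setdiff(nb[[kk]], jj)) {
        if (ii == ll) next
        a <- canonical_internal("dihedral", c(ii, jj, kk, ll))
        dih[[length(dih) + 1L]] <- a
      }
    }
  }
  if (length(dih)) {
    dm <- do.call(rbind, dih)
    rows[[length(rows) + 1L]] <- dplyr::distinct(tibble::tibble(
      kind = "dihedral", a1 = dm[, 1], a2 = dm[, 2], a3 = dm[, 3],
      a4 = dm[, 4]))
  }

  out <- dplyr::bind_rows(rows)
  out$kind <- as.character(out$kind)
  out
}

#' Evaluate internal coordinates on a Cartesian frame
#'
#' Bonds are Euclidean distances (Angstrom); angles are in `[0, 180]`
#' degrees; dihedrals are signed angles in `(-180, 180]` degrees from the
#' standard two-plane atan2 construction. The `"improper"` kind (a trigonal
#' center and its three neighbors) evaluates the signed out-of-plane angle of
#' the center, used for pyramidal-inversion detection.
#'
#' @param internals Internal-coordinate tibble from [enumerate_internals()].
#' @param geometry Geometry tibble.
#' @return Numeric vector of values, one per internal coordinate.
#' @export
evaluate_internals <- function(internals, geometry) {
  xyz <- coords(geometry)
  vapply(seq_len(nrow(internals)), function(r) {
    k <- internals$kind[r]
    a <- c(internals$a1[r], internals$a2[r], internals$a3[r], internals$a4[r])
    switch(k,
      bond = sqrt(sum((xyz[a[1], ] - xyz[a[2], ])^2)),
      angle = angle_between_deg(xyz[a[1], ] - xyz[a[2], ],
                                xyz[a[3], ] - xyz[a[2], ]),
      dihedral = dihedral_deg(xyz[a[1], ], xyz[a[2], ], xyz[a[3], ],
                              xyz[a[4], ]),
      improper = out_of_plane_deg(xyz[a[1], ], xyz[a[2], ], xyz[a[3], ],
                                  xyz[a[4], ]),
      stop("unknown internal-coordinate kind: ", k, call. = FALSE))
  }, numeric(1))
}

# Signed out-of-plane angle (degrees) of the bond center->n3 relative to the
# plane spanned by center->n1 and center->n2; sign flips on inversion.
out_of_plane_deg <- function(center, n1, n2, n3) {
  u <- n1 - center; v <- n2 - center; w <- n3 - center
  nrm <- cross3(u, v)
  if (sum(nrm^2) == 0 || sum(w^2) == 0) {
    stop("undefined out-of-plane angle", call. = FALSE)
  }
  s <- sum(nrm * w) / (sqrt(sum(nrm^2)) * sqrt(sum(w^2)))
  asin(pmin(1, pmax(-1, s))) * 180 / pi
}

#' Signed change of an internal coordinate between two frames
#'
#' Bonds and angles subtract directly; dihedrals (and impropers) take the
#' minimal signed circular difference, so 170 to -170 degrees is +20, not
#' -340.
#'
#' @param kind Character vector of coordinate kinds.
#' @param value_a,value_b Values at the two frames.
#' @return Signed deltas `value_b - value_a` (circular for dihedrals), in
#'   `(-180, 180]` for angular kinds.
#' @export
delta_internal <- function(kind, value_a, value_b) {
  d <- value_b - value_a
  circ <- kind %in% c("dihedral", "improper")
  d[circ] <- ((d[circ] + 180) %% 360) - 180
  d[circ & d == -180] <- 180
  d
}

# Internal deltas between two frames, as one tidy table.
internal_deltas <- function(internals, geom_a, geom_b) {
  va <- evaluate_internals(internals, geom_a)
  vb <- evaluate_internals(internals, geom_b)
  el <- geom_a$element
  out <- internals
  out$value_a <- va
  out$value_b <- vb
  out$delta <- delta_internal(internals$kind, va, vb)
  out$label <- internal_labels(internals, el)
  out
}

internal_labels <- function(internals, elements) {
  vapply(seq_len(nrow(internals)), function(r) {
    a <- c(internals$a1[r], internals$a2[r], internals$a3[r], internals$a4[r])
    a <- a[!is.na(a)]
    paste(paste0(elements[a], a - 1L), collapse = "-")
  }, character(1))
}
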