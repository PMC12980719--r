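# Two-pass distance-based connectivity with geometric validation.

bond_class <- function(el_a, el_b) {
  ma <- is_metal(el_a); mb <- is_metal(el_b)
  dplyr::case_when(
    ma & mb ~ "metal_metal",
    ma | mb ~ "metal_ligand",
    el_a == "H" | el_b == "H" ~ "hx",
    TRUE ~ "nonmetal")
}

class_factor <- function(class, config) {
  unname(c(hx = config$factor_hx,
           nonmetal = config$factor_nonmetal,
           metal_ligand = config$factor_metal_ligand,
           metal_metal = config$factor_metal_metal)[class])
}

#' Distance threshold for one element pair
#'
#' The bonding threshold is a per-bond-class fraction of the summed van der
#' Waals radii (tighter for covalent classes, looser for metal-ligand
#' contacts), optionally extended by a global scale for transition-state
#' geometries. Symmetric in its element arguments.
#'
#' @param el_a,el_b Element symbols (vectorized).
#' @param config A [graph_config()].
#' @param scale Global threshold multiplier (>= 1; the transition-state pass
#'   uses `config$ts_scale`).
#' @return Threshold length(s) in Angstrom.
#' @export
pair_threshold <- function(el_a, el_b, config = graph_config(), scale = 1) {
  stopifnot(scale >= 1)
  r <- vdw_radius(el_a) + vdw_radius(el_b)
  scale * class_factor(bond_class(el_a, el_b), config) * r
}

#' Geometric validation of a candidate bond
#'
#' A candidate in the outer distance band is rejected when (a) it makes an
#' acute angle (below the per-class minimum: metal endpoint 15 degrees,
#' nonmetal 30 degrees) with any already-accepted bond at either endpoint, or
#' (b) it closes a 3-membered ring, or a chord across an existing 4-membered
#' ring, whose length exceeds `ring_ratio_limit` times the mean of the ring's
#' existing bond lengths. These checks suppress artifactual small rings and
#' cross-links while keeping genuine ones.
#'
#' @param i,j 1-based atom indices of the candidate pair.
#' @param graph A `mol_graph` holding the already-accepted bonds.
#' @param geometry Geometry tibble.
#' @param config A [graph_config()].
#' @return `TRUE` if the candidate passes validation.
#' @export
validate_candidate <- function(i, j, graph, geometry, config = graph_config()) {
  xyz <- coords(geometry)
  el <- geometry$element
  nb <- graph_neighbors(graph)
  d_cand <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))

  # (a) acute-angle criterion at each endpoint
  for (ends in list(c(i, j), c(j, i))) {
    a <- ends[[1]]; b <- ends[[2]]
    amin <- if (is_metal(el[[a]])) config$angle_min_metal else config$angle_min_nonmetal
    v_cand <- xyz[b, ] - xyz[a, ]
    for (k in setdiff(nb[[a]], b)) {
      v_old <- xyz[k, ] - xyz[a, ]
      ang <- angle_between_deg(v_cand, v_old)
      if (ang < amin) return(FALSE)
    }
  }

  # (b) ring-diagonal criterion
  common <- intersect(nb[[i]], nb[[j]])
  for (c1 in common) {
    ring_len <- c(sqrt(sum((xyz[i, ] - xyz[c1, ])^2)),
                  sqrt(sum((xyz[j, ] - xyz[c1, ])^2)))
    if (d_cand > config$ring_ratio_limit * mean(ring_len)) return(FALSE)
  }
  if (length(common) >= 2L) {
    # candidate is a chord across an existing 4-ring i-c1-j-c2
    pairs <- utils::combn(common, 2L)
    for (p in seq_len(ncol(pairs))) {
      c1 <- pairs[1, p]; c2 <- pairs[2, p]
      ring_len <- c(sqrt(sum((xyz[i, ] - xyz[c1, ])^2)),
                    sqrt(sum((xyz[j, ] - xyz[c1, ])^2)),
                    sqrt(sum((xyz[i, ] - xyz[c2, ])^2)),
                    sqrt(sum((xyz[j, ] - xyz[c2, ])^2)))
      if (d_cand > config$ring_ratio_limit * mean(ring_len)) return(FALSE)
    }
  }
  TRUE
}

#' Perceive connectivity from Cartesian coordinates
#'
#' Two-pass distance-based bond perception. Pass one applies the per-class
#' thresholds at scale 1: pairs well below the threshold
#' (`< direct_accept * threshold`) are accepted outright, the remainder only
#' if [validate_candidate()] passes (candidates processed in ascending
#' distance order). With `ts_mode = TRUE` a second pass repeats the procedure
#' with all thresholds extended by `ts_scale`, adding (never removing)
#' validated bonds so elongated transition-state bonds are captured. Always
#' returns a graph, whatever the geometry.
#'
#' @param geometry Geometry tibble (columns `element`, `x`, `y`, `z`).
#' @param config A [graph_config()].
#' @param ts_mode Apply the transition-state threshold extension pass?
#' @return A `mol_graph` with all bond orders 1 and zero formal charges
#'   (orders and charges are assigned by [assign_bond_orders()]).
#' @export
build_connectivity <- function(geometry, config = graph_config(),
                               ts_mode = FALSE) {
  check_geometry(geometry)
  n <- nrow(geometry)
  graph <- new_mol_graph(geometry, empty_bonds(),
                         metadata = list(ts_mode = ts_mode))
  if (n < 2L) return(graph)

  xyz <- coords(geometry)
  dm <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  pr <- tibble::tibble(i = idx[, 1], j = idx[, 2],
                       d = dm[idx],
                       thr1 = pair_threshold(geometry$element[idx[, 1]],
                                             geometry$element[idx[, 2]],
                                             config))

  run_pass <- function(graph, scale) {
    thr <- scale * pr$thr1
    cand <- pr[pr$d < thr, ]
    cand$direct <- cand$d < config$direct_accept * thr[pr$d < thr]
    cand <- cand[!mapply(has_edge, i = cand$i, j = cand$j,
                         MoreArgs = list(graph = graph)), , drop = FALSE]
    cand <- cand[order(!cand$direct, cand$d, cand$i, cand$j), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      ok <- cand$direct[r] ||
        validate_candidate(cand$i[r], cand$j[r], graph, geometry, config)
      if (ok) {
        graph$bonds <- tibble::add_row(graph$bonds,
                                       i = cand$i[r], j = cand$j[r],
                                       order = 1, dative = FALSE)
      }
    }
    graph
  }

  graph <- run_pass(graph, 1)
  if (ts_mode) graph <- run_pass(graph, config$ts_scale)
  graph$bonds <- dplyr::arrange(graph$bonds, .data$i, .data$j)
  graph
}
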