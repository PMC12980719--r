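# Molecular graph container: atoms (geometry tibble) + bonds tibble
# (i, j, order, dative; canonical i < j) + per-atom formal charges.

new_mol_graph <- function(atoms, bonds, formal_charges = NULL,
                          total_charge = 0L, metadata = list()) {
  if (is.null(formal_charges)) formal_charges <- integer(nrow(atoms))
  structure(list(atoms = atoms,
                 bonds = bonds,
                 formal_charges = formal_charges,
                 total_charge = as.integer(total_charge),
                 metadata = metadata),
            class = "mol_graph")
}

empty_bonds <- function() {
  tibble::tibble(i = integer(0), j = integer(0),
                 order = numeric(0), dative = logical(0))
}

#' Number of atoms / bonds in a molecular graph
#' @param graph A `mol_graph`.
#' @return Integer count.
#' @export
n_atoms <- function(graph) nrow(graph$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(graph) nrow(graph$bonds)

# Adjacency list: integer vector of neighbors per atom (1-based internally).
graph_neighbors <- function(graph) {
  n <- n_atoms(graph)
  nb <- vector("list", n)
  b <- graph$bonds
  for (r in seq_len(nrow(b))) {
    nb[[b$i[r]]] <- c(nb[[b$i[r]]], b$j[r])
    nb[[b$j[r]]] <- c(nb[[b$j[r]]], b$i[r])
  }
  lapply(nb, function(v) sort(unique(v)))
}

has_edge <- function(graph, i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  any(graph$bonds$i == a & graph$bonds$j == b)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", n_atoms(x), " atoms, ", n_bonds(x), " bonds, charge ",
      x$total_charge, "\n", sep = "")
  if (isTRUE(x$metadata$ts_mode)) cat("  built with transition-state scaling\n")
  if (isTRUE(x$metadata$order_warning)) {
    cat("  warning: bond-order optimization hit the iteration cap\n")
  }
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a molecular graph into its bond table
#'
#' @param x A `mol_graph`.
#' @param ... Unused.
#' @return A tibble with one row per bond: 0-based atom indices `i`, `j`,
#'   element symbols, bond length (Angstrom), `order` and `dative` flag.
#' @export
tidy.mol_graph <- function(x, ...) {
  b <- x$bonds
  xyz <- coords(x$atoms)
  len <- if (nrow(b)) {
    sqrt(rowSums((xyz[b$i, , drop = FALSE] - xyz[b$j, , drop = FALSE])^2))
  } else numeric(0)
  tibble::tibble(
    i = b$i - 1L, j = b$j - 1L,
    el_i = x$atoms$element[b$i], el_j = x$atoms$element[b$j],
    length = len, order = b$order, dative = b$dative)
}

#' One-row summary of a molecular graph
#'
#' @param x A `mol_graph`.
#' @param ... Unused.
#' @return A one-row tibble: atom/bond counts, total charge, number of
#'   aromatic (order 1.5) bonds, dative bonds, and whether the bond-order
#'   optimization converged.
#' @export
glance.mol_graph <- function(x, ...) {
  tibble::tibble(
    n_atoms = n_atoms(x),
    n_bonds = n_bonds(x),
    total_charge = x$total_charge,
    n_aromatic = sum(x$bonds$order == 1.5),
    n_dative = sum(x$bonds$dative),
    converged = !isTRUE(x$metadata$order_warning))
}

#' Plot a molecular graph as a 2D projection
#'
#' Projects the atoms onto the two principal axes of the coordinates and
#' draws bonds as segments (double width for higher orders, dashed for
#' dative bonds).
#'
#' @param object A `mol_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mol_graph <- function(object, ...) {
  xyz <- coords(object$atoms)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  pc <- svd(ctr, nu = 0, nv = 2)$v
  p2 <- ctr %*% pc
  atoms <- tibble::tibble(px = p2[, 1], py = p2[, 2],
                          element = object$atoms$element)
  b <- object$bonds
  seg <- tibble::tibble(
    x = p2[b$i, 1], y = p2[b$i, 2], xend = p2[b$j, 1], yend = p2[b$j, 2],
    order = b$order, dative = b$dative)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linewidth = .data$order, linetype = .data$dative),
      color = "grey40", show.legend = c(linewidth = TRUE, linetype = FALSE)) +
    ggplot2::geom_point(data = atoms,
                        ggplot2::aes(x = .data$px, y = .data$py), size = 6,
                        color = "white") +
    ggplot2::geom_text(data = atoms,
                       ggplot2::aes(x = .data$px, y = .data$py,
                                    label = .data$element)) +
    ggplot2::scale_linewidth_continuous(range = c(0.5, 2),
                                        breaks = c(1, 1.5, 2, 3)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "bond order")
}

#' Serialize a molecular graph to a plain-text document
#'
#' Writes a stable, versioned plain-text representation: one `atom` line per
#' atom (0-based index, element, formal charge), one `bond` line per bond
#' (0-based i, j, order, dative flag) and an adjacency list.
#'
#' @param graph A `mol_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  out <- c("# tsmode molecular graph, schema 1",
           paste("total_charge", graph$total_charge),
           sprintf("atom %d %s %d", seq_len(n_atoms(graph)) - 1L,
                   graph$atoms$element, graph$formal_charges))
  b <- graph$bonds
  if (nrow(b)) {
    out <- c(out, sprintf("bond %d %d %g %d", b$i - 1L, b$j - 1L, b$order,
                          as.integer(b$dative)))
  }
  nb <- graph_neighbors(graph)
  adj <- vapply(seq_along(nb), function(i) {
    paste0(i - 1L, ":", paste(nb[[i]] - 1L, collapse = ","))
  }, character(1))
  writeLines(c(out, paste("adjacency", adj)), path)
  invisible(path)
}
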