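# Frozen element table: van der Waals radii (Angstrom), standard atomic
# weights (amu), metal flags and allowed valences for Z = 1..86.
# Radii are a consolidated published set (Bondi/Mantina main group; Alvarez
# values for the d- and f-blocks); frozen here so graph perception is
# reproducible independent of any external table revision.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn")

.element_vdw <- c(
  1.10, 1.40, 1.81, 1.53, 1.92, 1.70, 1.55, 1.52, 1.47, 1.54,
  2.27, 1.73, 1.84, 2.10, 1.80, 1.80, 1.75, 1.88, 2.75, 2.31,
  2.15, 2.11, 2.07, 2.06, 2.05, 2.04, 2.00, 1.97, 1.96, 2.01,
  1.87, 2.11, 1.85, 1.90, 1.83, 2.02, 3.03, 2.49, 2.32, 2.23,
  2.18, 2.17, 2.16, 2.13, 2.10, 2.10, 2.11, 2.18, 1.93, 2.17,
  2.06, 2.06, 1.98, 2.16, 3.43, 2.68, 2.43, 2.42, 2.40, 2.39,
  2.38, 2.36, 2.35, 2.34, 2.33, 2.31, 2.30, 2.29, 2.27, 2.26,
  2.24, 2.23, 2.22, 2.18, 2.16, 2.16, 2.13, 2.13, 2.14, 2.23,
  1.96, 2.02, 2.07, 1.97, 2.02, 2.20)

.element_mass <- c(
  1.008, 4.003, 6.94, 9.012, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098, 40.078,
  44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
  92.906, 95.95, 97.91, 101.07, 102.906, 106.42, 107.868, 112.414, 114.818, 118.710,
  121.760, 127.60, 126.904, 131.293, 132.905, 137.327, 138.905, 140.116, 140.908, 144.242,
  145.0, 150.36, 151.964, 157.25, 158.925, 162.500, 164.930, 167.259, 168.934, 173.045,
  174.967, 178.49, 180.948, 183.84, 186.207, 190.23, 192.217, 195.084, 196.967, 200.592,
  204.38, 207.2, 208.980, 209.0, 210.0, 222.0)

# Metals: s-block (except H/He), d-block, f-block, plus the post-transition
# set Al/Ga/In/Tl/Sn/Pb/Bi. Needed for the angle criteria and for fixing
# metal-ligand bond orders.
.metal_symbols <- c(
  "Li", "Be", "Na", "Mg", "K", "Ca", "Rb", "Sr", "Cs", "Ba",
  .element_symbols[21:30], .element_symbols[39:48],
  .element_symbols[57:71], .element_symbols[72:80],
  "Al", "Ga", "In", "Tl", "Sn", "Pb", "Bi")

# Allowed valences for nonmetals (ordered, preferred first). Metals are NA:
# their bond orders are fixed at one and they carry no valence penalty.
.nonmetal_valences <- list(
  H = 1L, He = 0L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Ne = 0L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = c(1L, 3L, 5L, 7L),
  Ar = 0L, Ge = 4L, As = c(3L, 5L), Se = c(2L, 4L, 6L),
  Br = c(1L, 3L, 5L, 7L), Kr = c(0L, 2L), Sb = c(3L, 5L),
  Te = c(2L, 4L, 6L), I = c(1L, 3L, 5L, 7L), Xe = c(0L, 2L, 4L, 6L),
  Po = c(2L, 4L), At = 1L, Rn = 0L)

.element_env <- new.env(parent = emptyenv())

#' Periodic element data used for graph perception
#'
#' Returns the frozen per-element table: van der Waals radius (Angstrom),
#' atomic mass (amu), metal flag and allowed valences. Covers Z = 1..86.
#'
#' @return A tibble with columns `z`, `symbol`, `vdw_radius`, `mass`,
#'   `is_metal` and a list-column `valences` (integer vector per element,
#'   `NA` for metals).
#' @export
periodic_table <- function() {
  if (is.null(.element_env$table)) {
    stopifnot(length(.element_vdw) == 86L, length(.element_mass) == 86L)
    tab <- tibble::tibble(
      z = seq_along(.element_symbols),
      symbol = .element_symbols,
      vdw_radius = .element_vdw,
      mass = .element_mass,
      is_metal = .element_symbols %in% .metal_symbols,
      valences = lapply(.element_symbols, function(s) {
        v <- .nonmetal_valences[[s]]
        if (is.null(v)) NA_integer_ else v
      }))
    .element_env$table <- tab
  }
  .element_env$table
}

element_index <- function(symbols) {
  idx <- match(symbols, .element_symbols)
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' @rdname periodic_table
#' @param symbols Character vector of element symbols.
#' @export
vdw_radius <- function(symbols) .element_vdw[element_index(symbols)]

#' @rdname periodic_table
#' @export
atomic_mass <- function(symbols) .element_mass[element_index(symbols)]

#' @rdname periodic_table
#' @export
is_metal <- function(symbols) {
  .element_symbols[element_index(symbols)] %in% .metal_symbols
}

# Allowed valences for one element; integer(0) means "unconstrained" (metals).
allowed_valences <- function(symbol) {
  element_index(symbol)
  v <- .nonmetal_valences[[symbol]]
  if (is.null(v)) integer(0) else v
}

# Smallest |s - v| over allowed valences; metals contribute 0.
valence_deviation <- function(symbol, order_sum) {
  v <- allowed_valences(symbol)
  if (length(v) == 0L) return(0)
  min(abs(order_sum - v))
}
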