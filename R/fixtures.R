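# Programmatic generation of all test inputs: model transition states with
# synthetic imaginary modes, a textbook-geometry equilibrium library, and
# interpolated reaction paths. Geometry parameters are chosen once (textbook
# bond lengths; 2.3/2.0 Angstrom axial distances for the SN2 model so the
# partial bonds appear only under transition-state threshold scaling) and
# frozen here.

deg2rad <- function(x) x * pi / 180

# Tetrahedral substituent positions around `center` pointing away from
# `away`: returns k positions at bond length r, cone angle `ang` from the
# center->away axis, azimuths `phis` (degrees).
cone_positions <- function(center, away, r, ang, phis) {
  axis <- (away - center) / sqrt(sum((away - center)^2))
  # orthonormal frame
  ref <- if (abs(axis[[1]]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(axis, ref); u <- u / sqrt(sum(u^2))
  v <- cross3(axis, u)
  t(vapply(phis, function(phi) {
    center + r * (cos(deg2rad(ang)) * axis +
                    sin(deg2rad(ang)) * (cos(deg2rad(phi)) * u +
                                           sin(deg2rad(phi)) * v))
  }, numeric(3)))
}

# Small deterministic positive "spectator" modes so imaginary-mode selection
# is always exercised on realistic multi-mode input.
dummy_positive_modes <- function(n_atoms) {
  d1 <- matrix(0, n_atoms, 3); d1[1, 1] <- 0.3; d1[min(2, n_atoms), 2] <- -0.2
  d2 <- matrix(0, n_atoms, 3); d2[n_atoms, 3] <- 0.25; d2[1, 2] <- 0.1
  list(new_normal_mode(120, d1), new_normal_mode(340, d2))
}

#' Generate a model transition-state fixture
#'
#' Three archetypal transition-state modes with synthetic imaginary-mode
#' displacement fields:
#' * `"sn2"` — trigonal-planar CH3 with collinear axial Cl (2.3 Angstrom,
#'   elongated) and incoming F (2.0 Angstrom); the mode carries the carbon
#'   along the axis with counter-motion of Cl and F. Expected: C-Cl break +
#'   C-F form.
#' * `"inversion"` — planar NH3 (nitrogen at the centroid, 120-degree H-N-H
#'   angles); the mode is the nitrogen umbrella motion. Expected: pyramidal
#'   inversion at N.
#' * `"rotation"` — eclipsed F-H2C-CH2-F; the mode is a hindered torsion
#'   about the C-C axis contaminated with an overall rigid rotation (the two
#'   ends rotate in the same sense with unequal weights), as is typical of
#'   low-frequency torsional modes. Expected: F-C-C-F rotation.
#'
#' Each fixture carries its imaginary mode at -500 cm^-1 plus two small
#' positive spectator modes.
#'
#' @param kind One of `"sn2"`, `"inversion"`, `"rotation"`.
#' @return A list: `name`, `geometry`, `modes` (imaginary first),
#'   `expected_changes` (reference tibble with `kind`, `a1`..`a4`,
#'   `classification`), `expected_class`, `total_charge`.
#' @export
make_model_ts <- function(kind = c("sn2", "inversion", "rotation")) {
  kind <- match.arg(kind)
  if (kind == "sn2") {
    r_ch <- 1.08
    xyz <- rbind(
      c(0, 0, 0),                               # C
      cone_positions(c(0, 0, 0), c(0, 0, 1), r_ch, 90,
                     c(0, 120, 240)),           # 3 H, trigonal planar
      c(0, 0, 2.30),                            # Cl (elongated)
      c(0, 0, -2.00))                           # F (incoming)
    el <- c("C", "H", "H", "H", "Cl", "F")
    d <- rbind(c(0, 0, -1.0),
               matrix(rep(c(0, 0, -0.30), 3), 3, 3, byrow = TRUE),
               c(0, 0, 0.20),
               c(0, 0, 0.30))
    expected <- tibble::tibble(
      kind = c("bond", "bond"),
      a1 = c(1L, 1L), a2 = c(5L, 6L), a3 = NA_integer_, a4 = NA_integer_,
      classification = c("bond_break", "bond_form"))
    spec <- list(name = "sn2", expected_class = "bond_change",
                 total_charge = -1L)
  } else if (kind == "inversion") {
    r_nh <- 1.01
    xyz <- rbind(c(0, 0, 0),
                 cone_positions(c(0, 0, 0), c(0, 0, 1), r_nh, 90,
                                c(0, 120, 240)))
    el <- c("N", "H", "H", "H")
    d <- rbind(c(0, 0, 1.0),
               matrix(rep(c(0, 0, -0.25), 3), 3, 3, byrow = TRUE))
    expected <- tibble::tibble(
      kind = "improper", a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L,
      classification = "inversion")
    spec <- list(name = "inversion", expected_class = "inversion",
                 total_charge = 0L)
  } else {
    r_cc <- 1.54; r_cf <- 1.39; r_ch <- 1.09; cone <- 109.47
    c1 <- c(0, 0, 0); c2 <- c(0, 0, r_cc)
    # substituents point away from the opposite carbon; eclipsed: same
    # azimuths on both ends
    xyz <- rbind(
      c1, c2,
      cone_positions(c1, c2, r_cf, cone, 0),
      cone_positions(c1, c2, r_ch, cone, c(120, 240)),
      cone_positions(c2, c1, r_cf, cone, 180),
      cone_positions(c2, c1, r_ch, cone, c(60, 300)))
    el <- c("C", "C", "F", "H", "H", "F", "H", "H")
    # hindered torsion about the C-C (z) axis: both ends rotate in the same
    # sense with unequal weights (torsion + rigid-rotation contamination);
    # weight ratio fixed once so the default amplitude lands the F-C-C-F
    # change above the primary 20-degree tier and a 0.4x amplitude lands in
    # the 50% fallback tier
    w <- c(0, 0, 1, 1, 1, 0.27, 0.27, 0.27)
    d <- t(vapply(seq_len(nrow(xyz)), function(k) {
      w[[k]] * c(-xyz[k, 2], xyz[k, 1], 0)
    }, numeric(3)))
    expected <- tibble::tibble(
      kind = "dihedral", a1 = 3L, a2 = 1L, a3 = 2L, a4 = 6L,
      classification = "rotation")
    spec <- list(name = "rotation", expected_class = "rotation",
                 total_charge = 0L)
  }
  geometry <- new_geometry(el, xyz, paste("model", spec$name, "TS fixture"))
  modes <- c(list(new_normal_mode(-500, d)), dummy_positive_modes(nrow(xyz)))
  c(spec, list(geometry = geometry, modes = modes,
               expected_changes = expected))
}

# -- equilibrium molecule library -------------------------------------------

ref_bonds <- function(i, j, order) {
  lo <- as.integer(pmin(i, j))
  hi <- as.integer(pmax(i, j))
  tibble::tibble(i = lo, j = hi, order = as.numeric(order))
}

#' Equilibrium molecules with known graphs
#'
#' Textbook-geometry coordinates for a small library of standard molecules,
#' together with the reference edge set and Lewis bond orders used as the
#' graph-perception oracle.
#'
#' @param name One of `"water"`, `"methane"`, `"ethane"`, `"ethene"`,
#'   `"ethyne"`, `"benzene"`, `"ammonia"`, `"methanol"`, `"co2"`,
#'   `"hexacarbonyl"` (octahedral Cr(CO)6).
#' @return A list: `name`, `geometry`, `bonds` (reference tibble `i`, `j`,
#'   `order`, 1-based), `total_charge`.
#' @export
make_equilibrium_molecule <- function(name) {
  z3 <- c(0, 0, 1)
  o <- c(0, 0, 0)
  m <- switch(
    name,
    water = {
      xyz <- rbind(o, c(0.757, 0, 0.586), c(-0.757, 0, 0.586))
      list(el = c("O", "H", "H"), xyz = xyz,
           bonds = ref_bonds(c(1, 1), c(2, 3), 1))
    },
    methane = {
      h <- 1.09 / sqrt(3)
      xyz <- rbind(o, c(h, h, h), c(h, -h, -h), c(-h, h, -h), c(-h, -h, h))
      list(el = c("C", rep("H", 4)), xyz = xyz,
           bonds = ref_bonds(rep(1, 4), 2:5, 1))
    },
    ethane = {
      c1 <- c(0, 0, 0); c2 <- c(0, 0, 1.536)
      xyz <- rbind(c1, c2,
                   cone_positions(c1, c2, 1.091, 109.47, c(0, 120, 240)),
                   cone_positions(c2, c1, 1.091, 109.47, c(60, 180, 300)))
      list(el = c("C", "C", rep("H", 6)), xyz = xyz,
           bonds = ref_bonds(c(1, 1, 1, 1, 2, 2, 2), c(2, 3, 4, 5, 6, 7, 8),
                             1))
    },
    ethene = {
      c1 <- c(-0.6695, 0, 0); c2 <- c(0.6695, 0, 0)
      xyz <- rbind(c1, c2,
                   cone_positions(c1, c2, 1.086, 121.3, c(90, 270)),
                   cone_positions(c2, c1, 1.086, 121.3, c(90, 270)))
      list(el = c("C", "C", rep("H", 4)), xyz = xyz,
           bonds = ref_bonds(c(1, 1, 1, 2, 2), c(2, 3, 4, 5, 6),
                             c(2, 1, 1, 1, 1)))
    },
    ethyne = {
      xyz <- rbind(c(-0.6015, 0, 0), c(0.6015, 0, 0),
                   c(-1.6615, 0, 0), c(1.6615, 0, 0))
      list(el = c("C", "C", "H", "H"), xyz = xyz,
           bonds = ref_bonds(c(1, 1, 2), c(2, 3, 4), c(3, 1, 1)))
    },
    benzene = {
      ang <- deg2rad(seq(0, 300, by = 60))
      xyz <- rbind(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
                   cbind(2.48 * cos(ang), 2.48 * sin(ang), 0))
      list(el = c(rep("C", 6), rep("H", 6)), xyz = xyz,
           bonds = ref_bonds(c(1:6, 1:6), c(2:6, 1, 7:12),
                             c(rep(1.5, 6), rep(1, 6))))
    },
    ammonia = {
      rho <- 1.012 * 0.9264; h <- 1.012 * 0.3765
      ang <- deg2rad(c(0, 120, 240))
      xyz <- rbind(o, cbind(rho * cos(ang), rho * sin(ang), -h))
      list(el = c("N", "H", "H", "H"), xyz = xyz,
           bonds = ref_bonds(rep(1, 3), 2:4, 1))
    },
    methanol = {
      cpos <- o; opos <- c(1.427, 0, 0)
      xyz <- rbind(cpos, opos,
                   opos + c(0.956 * cos(deg2rad(71.5)),
                            0.956 * sin(deg2rad(71.5)), 0),
                   cone_positions(cpos, opos, 1.09, 109.47, c(60, 180, 300)))
      list(el = c("C", "O", "H", "H", "H", "H"), xyz = xyz,
           bonds = ref_bonds(c(1, 2, 1, 1, 1), c(2, 3, 4, 5, 6), 1))
    },
    co2 = {
      xyz <- rbind(o, c(1.162, 0, 0), c(-1.162, 0, 0))
      list(el = c("C", "O", "O"), xyz = xyz,
           bonds = ref_bonds(c(1, 1), c(2, 3), 2))
    },
    hexacarbonyl = {
      axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))
      xyz <- rbind(o, 1.91 * axes, 3.05 * axes)
      list(el = c("Cr", rep("C", 6), rep("O", 6)), xyz = xyz,
           bonds = ref_bonds(c(rep(1, 6), 2:7), c(2:7, 8:13),
                             c(rep(1, 6), rep(2, 6))))
    },
    stop("unknown equilibrium molecule: ", name, call. = FALSE))
  list(name = name,
       geometry = new_geometry(m$el, m$xyz, paste(name, "fixture")),
       bonds = m$bonds,
       total_charge = 0L)
}

#' Names of the equilibrium fixture library
#' @return Character vector of molecule names accepted by
#'   [make_equilibrium_molecule()].
#' @export
equilibrium_library <- function() {
  c("water", "methane", "ethane", "ethene", "ethyne", "benzene", "ammonia",
    "methanol", "co2", "hexacarbonyl")
}

# Random proper rotation matrix (axis-angle from the supplied RNG stream).
random_rotation <- function() {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Interpolate a reaction path through a model transition state
#'
#' Frames are linear interpolations from the reverse-displaced to the
#' forward-displaced structure (the TS is the midpoint of odd-length paths).
#' Optionally each frame receives a random rigid rotation + translation
#' (seeded), exercising the Kabsch alignment of trajectory analysis.
#'
#' @param fixture A fixture from [make_model_ts()].
#' @param n_frames Number of frames (>= 2).
#' @param amplitude Displacement amplitude of the endpoint structures.
#' @param rigid Apply a random rigid motion per frame?
#' @param seed RNG seed for the rigid motions.
#' @return List of geometry tibbles.
#' @export
make_path <- function(fixture, n_frames = 11L, amplitude = 0.5,
                      rigid = FALSE, seed = 1L) {
  stopifnot(n_frames >= 2L)
  sel <- select_imaginary(fixture$modes)
  pair <- displace_along_mode(fixture$geometry, sel$mode, amplitude)
  A <- coords(pair$reverse); B <- coords(pair$forward)
  fr <- lapply(seq_len(n_frames), function(k) {
    t <- (k - 1) / (n_frames - 1)
    new_geometry(fixture$geometry$element, (1 - t) * A + t * B,
                 sprintf("path frame %d/%d", k, n_frames))
  })
  if (rigid) {
    withr_seed <- function(code) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      code()
    }
    fr <- withr_seed(function() {
      lapply(fr, function(g) {
        R <- random_rotation()
        tr <- stats::runif(3, -2, 2)
        new_geometry(g$element,
                     sweep(coords(g) %*% t(R), 2, tr, "+"),
                     attr(g, "comment"))
      })
    })
  }
  fr
}
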