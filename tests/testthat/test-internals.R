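test_that("internal-coordinate enumeration gives the combinatorial counts", {
  w <- perceive_graph(make_equilibrium_molecule("water")$geometry)
  iw <- enumerate_internals(w)
  expect_equal(table(iw$kind)[["bond"]], 2)
  expect_equal(table(iw$kind)[["angle"]], 1)
  expect_false("dihedral" %in% iw$kind)

  e <- perceive_graph(make_equilibrium_molecule("ethane")$geometry)
  ie <- enumerate_internals(e)
  expect_equal(sum(ie$kind == "bond"), 7)       # 6 C-H + C-C
  expect_equal(sum(ie$kind == "angle"), 12)     # C(4,2) = 6 per carbon
  expect_equal(sum(ie$kind == "dihedral"), 9)   # 3 x 3 about C-C
})

test_that("augmentation unions in edges missing from the TS graph", {
  fx <- make_model_ts("sn2")
  ts_unscaled <- perceive_graph(fx$geometry, -1L)        # no C-F, no C-Cl
  full <- perceive_graph(fx$geometry, -1L, ts_mode = TRUE)
  expect_false(any(ts_unscaled$bonds$i == 1 & ts_unscaled$bonds$j == 6))
  aug <- enumerate_internals(ts_unscaled, augment = list(full))
  expect_true(any(aug$kind == "bond" & aug$a1 == 1 & aug$a2 == 6))
  # mismatched atom count is rejected
  w <- perceive_graph(make_equilibrium_molecule("water")$geometry)
  expect_error(enumerate_internals(ts_unscaled, augment = list(w)),
               "different atom count")
})

test_that("bond, angle and dihedral evaluation match closed-form values", {
  tri <- tibble::tibble(element = c("H", "O", "H"),
                        x = c(1, 0, 0), y = c(0, 0, 1), z = 0)
  ic <- tibble::tibble(kind = c("bond", "angle"),
                       a1 = c(1L, 1L), a2 = c(2L, 2L),
                       a3 = c(NA, 3L), a4 = NA_integer_)
  v <- evaluate_internals(ic, tri)
  expect_equal(v[[1]], 1)
  expect_equal(v[[2]], 90)

  m <- make_equilibrium_molecule("methane")$geometry
  ang <- tibble::tibble(kind = "angle", a1 = 2L, a2 = 1L, a3 = 3L,
                        a4 = NA_integer_)
  expect_equal(evaluate_internals(ang, m), acos(-1 / 3) * 180 / pi,
               tolerance = 1e-6)

  chain <- function(d4) tibble::tibble(
    element = rep("C", 4),
    x = c(0, 0, 1.5, 1.5), y = c(1, 0, 0, d4[1]), z = c(0, 0, 0, d4[2]))
  dih <- tibble::tibble(kind = "dihedral", a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L)
  expect_equal(evaluate_internals(dih, chain(c(-1, 0))), 180)
  expect_equal(evaluate_internals(dih, chain(c(1, 0))), 0)
  expect_error(evaluate_internals(dih, chain(c(0, 0))), "collinear")
})

test_that("dihedral deltas wrap around and are antisymmetric", {
  expect_equal(delta_internal("dihedral", 170, -170), 20)
  expect_equal(delta_internal("dihedral", -170, 170), -20)
  expect_equal(delta_internal("bond", 1.5, 2.0), 0.5)
  set.seed(3)
  for (k in c("bond", "angle", "dihedral")) {
    a <- stats::runif(20, -180, 180); b <- stats::runif(20, -180, 180)
    expect_equal(delta_internal(k, a, b), -delta_internal(k, b, a))
  }
  # circular deltas never exceed half a turn
  a <- stats::runif(200, -180, 180); b <- stats::runif(200, -180, 180)
  expect_true(all(abs(delta_internal("dihedral", a, b)) <= 180))
})

test_that("internal coordinates are rigid-motion invariant and chirality-aware", {
  set.seed(5)
  g <- make_equilibrium_molecule("methanol")$geometry
  graph <- perceive_graph(g)
  ic <- enumerate_internals(graph)
  v0 <- evaluate_internals(ic, g)
  for (s in 1:5) {
    moved <- rigid_motion(g)$geometry
    expect_equal(evaluate_internals(ic, moved), v0, tolerance = 1e-9)
  }
  # mirror reflection flips dihedral signs, preserves bonds/angles
  vm <- evaluate_internals(ic, mirror_geometry(g))
  dih <- ic$kind == "dihedral"
  expect_equal(vm[!dih], v0[!dih], tolerance = 1e-9)
  expect_equal(vm[dih], -v0[dih], tolerance = 1e-9)
})

test_that("dihedrals agree with the Rodrigues rotation-fitting oracle", {
  set.seed(17)
  dih <- tibble::tibble(kind = "dihedral", a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L)
  for (k in seq_len(100)) {
    xyz <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    # reject near-degenerate cases the oracle cannot resolve
    if (min(dist(xyz)) < 0.3) next
    g <- tibble::tibble(element = rep("C", 4),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    got <- evaluate_internals(dih, g)
    want <- oracle_dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
    # compare circularly (identical angles up to 360 wrap)
    expect_lt(abs(delta_internal("dihedral", got, want)), 1e-8)
  }
})
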