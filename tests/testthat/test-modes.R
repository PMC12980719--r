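test_that("mode files parse block-wise with comments ignored", {
  path <- tempfile(fileext = ".modes")
  writeLines(c("# imaginary mode", "freq -512.3",
               "0.1 0.0 0.0", "0.0 0.2 0.0", "0.0 0.0 -0.3",
               "freq 88.0",
               "0.0 0.1 0.0", "0.1 0.0 0.0", "0.0 0.0 0.1"), path)
  modes <- read_modes(path)
  expect_length(modes, 2)
  expect_equal(modes[[1]]$frequency, -512.3)
  expect_equal(modes[[2]]$frequency, 88)
  expect_equal(dim(modes[[1]]$displacements), c(3, 3))

  # round trip through the writer
  path2 <- tempfile(fileext = ".modes")
  write_modes(modes, path2)
  back <- read_modes(path2)
  expect_equal(back[[1]]$displacements, modes[[1]]$displacements,
               tolerance = 1e-7)

  bad <- tempfile(fileext = ".modes")
  writeLines(c("freq -10", "0.1 0.2"), bad)
  expect_error(read_modes(bad), "malformed displacement")
})

test_that("imaginary-mode selection takes the most negative frequency", {
  mk <- function(f) structure(
    list(frequency = f, displacements = matrix(c(1, 0, 0), 1, 3)),
    class = "normal_mode")
  sel <- select_imaginary(list(mk(-500), mk(30), mk(100)))
  expect_equal(sel$mode$frequency, -500)
  expect_length(sel$extra_imaginary, 0)

  sel2 <- select_imaginary(list(mk(-20), mk(-500), mk(100)))
  expect_equal(sel2$mode$frequency, -500)
  expect_equal(sel2$extra_imaginary, -20)

  expect_error(select_imaginary(list(mk(10), mk(100))),
               "not a transition state")
})

test_that("mode displacement is normalized to the max-moving atom", {
  fx <- make_model_ts("sn2")
  mode <- fx$modes[[1]]
  pair <- displace_along_mode(fx$geometry, mode, amplitude = 0.37)
  shift <- coords(pair$forward) - coords(fx$geometry)
  expect_equal(max(sqrt(rowSums(shift^2))), 0.37)
  # midpoint identity for any amplitude
  expect_equal((coords(pair$forward) + coords(pair$reverse)) / 2,
               coords(fx$geometry))
  # degenerate zero amplitude
  p0 <- displace_along_mode(fx$geometry, mode, amplitude = 0)
  expect_equal(coords(p0$forward), coords(fx$geometry))
  expect_equal(coords(p0$reverse), coords(fx$geometry))
  # atom-count mismatch
  w <- make_equilibrium_molecule("water")$geometry
  expect_error(displace_along_mode(w, mode), "displacement vectors")
})

test_that("displacement commutes with rigid motion and negation swaps frames", {
  set.seed(23)
  fx <- make_model_ts("inversion")
  mode <- fx$modes[[1]]
  rm <- rigid_motion(fx$geometry)
  mode_rot <- structure(list(frequency = mode$frequency,
                             displacements = mode$displacements %*%
                               t(rm$rotation)),
                        class = "normal_mode")
  pair <- displace_along_mode(fx$geometry, mode, 0.5)
  pair_rot <- displace_along_mode(rm$geometry, mode_rot, 0.5)
  fwd_expected <- sweep(coords(pair$forward) %*% t(rm$rotation), 2,
                        rm$translation, "+")
  expect_equal(coords(pair_rot$forward), fwd_expected, tolerance = 1e-9,
               ignore_attr = TRUE)

  neg <- structure(list(frequency = mode$frequency,
                        displacements = -mode$displacements),
                   class = "normal_mode")
  pair_neg <- displace_along_mode(fx$geometry, neg, 0.5)
  expect_equal(coords(pair_neg$forward), coords(pair$reverse))
  expect_equal(coords(pair_neg$reverse), coords(pair$forward))
})

test_that("displaced pairs are written as a two-frame XYZ", {
  fx <- make_model_ts("rotation")
  pair <- displace_along_mode(fx$geometry, fx$modes[[1]], 0.5)
  path <- tempfile(fileext = ".xyz")
  write_displaced(pair, path)
  frames <- read_xyz(path)
  expect_length(frames, 2)
  expect_match(attr(frames[[1]], "comment"), "forward a=0.5")
  expect_equal(coords(frames[[2]]), coords(pair$reverse), tolerance = 1e-7,
               ignore_attr = TRUE)
})
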