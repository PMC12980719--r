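mk_deltas <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(kind = r$kind,
                   a1 = r$a[1], a2 = r$a[2],
                   a3 = if (length(r$a) > 2) r$a[3] else NA_integer_,
                   a4 = if (length(r$a) > 3) r$a[4] else NA_integer_,
                   label = r$label %||% paste(r$a, collapse = "-"),
                   delta = r$delta)
  }))
}

test_that("threshold screening flags at the printed defaults", {
  d <- mk_deltas(list(kind = "bond", a = c(1L, 2L), delta = 0.41),
                 list(kind = "bond", a = c(2L, 3L), delta = 0.39),
                 list(kind = "angle", a = c(1L, 2L, 3L), delta = 9.5),
                 list(kind = "dihedral", a = c(1L, 2L, 3L, 4L), delta = 21))
  ch <- detect_changes(d, elements = c("C", "C", "C", "C"))
  expect_setequal(ch$label, c("1-2", "1-2-3-4"))
  expect_identical(ch$classification[ch$kind == "bond"], "bond_break")
  expect_true(all(ch$provenance == "primary"))
  # bond threshold boundary is inclusive
  d2 <- mk_deltas(list(kind = "bond", a = c(1L, 2L), delta = -0.4))
  ch2 <- detect_changes(d2, elements = c("C", "C"))
  expect_identical(ch2$classification, "bond_form")
})

test_that("the 50% fallback tier fires only when the primary tier is empty", {
  d <- mk_deltas(list(kind = "bond", a = c(1L, 2L), delta = 0.1),
                 list(kind = "dihedral", a = c(1L, 2L, 3L, 4L), delta = 12))
  ch <- detect_changes(d, elements = rep("C", 4))
  expect_equal(nrow(ch), 1)
  expect_identical(ch$provenance, "fallback")
  expect_identical(ch$kind, "dihedral")

  # primary hit suppresses the fallback tier entirely
  d2 <- mk_deltas(list(kind = "bond", a = c(1L, 2L), delta = 0.5),
                  list(kind = "dihedral", a = c(1L, 2L, 3L, 4L), delta = 12))
  ch2 <- detect_changes(d2, elements = rep("C", 4))
  expect_equal(nrow(ch2), 1)
  expect_identical(ch2$kind, "bond")

  # fallbacks can be disabled
  ch3 <- detect_changes(d, screen_config(max_fallbacks = 0L),
                        elements = rep("C", 4))
  expect_equal(nrow(ch3), 0)
})

test_that("hydrogen bond breaks are paired with their forming partner", {
  els <- c("O", "H", "N")
  d <- mk_deltas(list(kind = "bond", a = c(1L, 2L), delta = 0.45),
                 list(kind = "bond", a = c(2L, 3L), delta = -0.25))
  ch <- detect_changes(d, elements = els)
  expect_equal(nrow(ch), 2)
  pp <- ch[ch$provenance == "proton_pairing", ]
  expect_equal(nrow(pp), 1)
  expect_identical(pp$classification, "bond_form")
  expect_identical(pp$label, "2-3")

  # partner below the secondary threshold is not paired
  d2 <- mk_deltas(list(kind = "bond", a = c(1L, 2L), delta = 0.45),
                  list(kind = "bond", a = c(2L, 3L), delta = -0.15))
  expect_equal(nrow(detect_changes(d2, elements = els)), 1)

  # a partner already bonded to the hydrogen in the TS graph is skipped
  geom <- tibble::tibble(element = els, x = c(0, 0.97, 2), y = 0, z = 0)
  graph <- new_mol_graph(geom, tibble::tibble(
    i = c(1L, 2L), j = c(2L, 3L), order = 1, dative = FALSE))
  ch3 <- detect_changes(d, graph = graph)
  expect_equal(nrow(ch3), 1)
})

test_that("correlated angles/dihedrals are filtered and axes deduplicated", {
  els <- c("F", "C", "C", "F", "H", "H")
  geom <- tibble::tibble(element = els, x = seq_len(6), y = 0, z = 0)
  graph <- new_mol_graph(geom, empty_bonds())
  ch <- mk_deltas(
    list(kind = "bond", a = c(1L, 2L), delta = 0.6),
    list(kind = "angle", a = c(1L, 2L, 3L), delta = 15),   # shares 1,2
    list(kind = "angle", a = c(4L, 3L, 5L), delta = 15),   # no shared atom
    list(kind = "dihedral", a = c(1L, 2L, 3L, 4L), delta = 30))  # shares 1
  ch$classification <- c("bond_break", "angle_change", "angle_change",
                         "rotation")
  ch$provenance <- "primary"
  out <- filter_correlated(ch, graph)
  expect_setequal(out$label, c("1-2", "4-3-5"))

  # heaviest-terminal dihedral wins within one axis
  ch2 <- mk_deltas(
    list(kind = "dihedral", a = c(1L, 2L, 3L, 4L), delta = 25),  # F...F
    list(kind = "dihedral", a = c(5L, 2L, 3L, 6L), delta = 40),  # H...H
    list(kind = "dihedral", a = c(1L, 2L, 3L, 6L), delta = 30))  # F...H
  ch2$classification <- "rotation"
  ch2$provenance <- "primary"
  out2 <- filter_correlated(ch2, graph)
  expect_identical(out2$label, "1-2-3-4")

  # with no bond changes, all angle/dihedral changes survive step (a)
  ch3 <- ch[-1, ]
  out3 <- filter_correlated(ch3, graph)
  expect_equal(nrow(out3), 3)
})

test_that("detected bond sets are nested as the threshold tightens", {
  fx <- make_model_ts("sn2")
  pair <- displace_along_mode(fx$geometry, fx$modes[[1]], 0.5)
  graph <- perceive_graph(fx$geometry, -1L, ts_mode = TRUE)
  deltas <- tsmode:::internal_deltas(enumerate_internals(graph),
                                     pair$reverse, pair$forward)
  previous <- character(0)
  for (bt in rev(c(0.1, 0.2, 0.3, 0.4, 0.5))) {
    ch <- detect_changes(deltas, screen_config(bond_thresh = bt),
                         graph = graph)
    bonds <- ch$label[ch$kind == "bond" & ch$provenance != "fallback"]
    expect_true(all(previous %in% bonds),
                label = sprintf("bond_thresh=%g", bt))
    previous <- bonds
  }
})

test_that("swapping frames negates deltas and exchanges break/form labels", {
  fx <- make_model_ts("sn2")
  pair <- displace_along_mode(fx$geometry, fx$modes[[1]], 0.5)
  graph <- perceive_graph(fx$geometry, -1L, ts_mode = TRUE)
  ic <- enumerate_internals(graph)
  fwd <- tsmode:::internal_deltas(ic, pair$reverse, pair$forward)
  rev <- tsmode:::internal_deltas(ic, pair$forward, pair$reverse)
  ch_f <- detect_changes(fwd, graph = graph)
  ch_r <- detect_changes(rev, graph = graph)
  ch_r_matched <- ch_r[match(ch_f$label, ch_r$label), ]
  expect_equal(ch_r_matched$delta, -ch_f$delta)
  swap <- c(bond_break = "bond_form", bond_form = "bond_break",
            angle_change = "angle_change", rotation = "rotation")
  expect_identical(ch_r_matched$classification,
                   unname(swap[ch_f$classification]))
})
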