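# Iterative valence-charge optimization of bond orders: Kekulé seeding of
# aromatic candidate rings, beam search over single/double/triple
# adjustments on the worst-described atoms, metal-ligand orders fixed at
# one, and final rewriting of surviving Kekulé rings to aromatic 1.5.

# Bounded simple-cycle enumeration (sizes within [min_size, max_size]).
# Molecular graphs are small and sparse; a bounded DFS from each start atom
# with the start as the smallest ring index avoids duplicates.
find_rings <- function(neighbors, min_size = 5L, max_size = 7L) {
  n <- length(neighbors)
  rings <- list()
  seen <- character(0)
  walk <- function(path) {
    last <- path[[length(path)]]
    for (nx in neighbors[[last]]) {
      if (nx == path[[1]] && length(path) >= min_size) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(nx %in% path) && nx > path[[1]] &&
                 length(path) < max_size) {
        walk(c(path, nx))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  rings
}

ring_planarity <- function(xyz) {
  ctr <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(ctr)
  normal <- sv$v[, 3]
  max(abs(ctr %*% normal))
}

# Candidate aromatic rings: size 5-7, atoms all C/N/O/S with 2-3 neighbors,
# near-planar.
aromatic_candidates <- function(graph, config) {
  nb <- graph_neighbors(graph)
  el <- graph$atoms$element
  deg <- lengths(nb)
  xyz <- coords(graph$atoms)
  rings <- find_rings(nb, 5L, 7L)
  keep <- vapply(rings, function(r) {
    all(el[r] %in% c("C", "N", "O", "S")) &&
      all(deg[r] %in% c(2L, 3L)) &&
      ring_planarity(xyz[r, , drop = FALSE]) <= config$aromatic_planarity
  }, logical(1))
  rings[keep]
}

# Bond row index for an (i, j) pair (canonical order enforced).
bond_row <- function(bonds, i, j) {
  which(bonds$i == pmin(i, j) & bonds$j == pmax(i, j))
}

# Nearest allowed valence (ties toward the smaller valence) and the signed
# intrinsic formal charge s - v*.
nearest_valence <- function(valences, s) {
  if (length(valences) == 0L) return(s)  # metals: no deviation, no charge
  valences[which.min(abs(s - valences))]
}

order_sums <- function(graph, orders) {
  s <- numeric(n_atoms(graph))
  b <- graph$bonds
  for (r in seq_len(nrow(b))) {
    s[b$i[r]] <- s[b$i[r]] + orders[r]
    s[b$j[r]] <- s[b$j[r]] + orders[r]
  }
  s
}

# Per-atom penalty terms for one full order vector.
pattern_terms <- function(graph, orders, config, valence_sets) {
  s <- order_sums(graph, orders)
  n <- n_atoms(graph)
  dev <- numeric(n); q <- numeric(n)
  for (a in seq_len(n)) {
    v <- valence_sets[[a]]
    if (length(v) == 0L) next
    vstar <- nearest_valence(v, s[a])
    dev[a] <- abs(s[a] - vstar)
    q[a] <- s[a] - vstar
  }
  list(dev = dev, q = q)
}

# Penalty over per-atom terms only; the residual needed to meet the total
# charge is bookkeeping (assigned after optimization), not an objective.
pattern_penalty <- function(graph, orders, total_charge, config, valence_sets) {
  t <- pattern_terms(graph, orders, config, valence_sets)
  config$w_valence * sum(t$dev) + config$w_charge * sum(abs(t$q))
}

kekule_seed <- function(graph, rings, orders) {
  has_double <- logical(n_atoms(graph))
  for (ring in rings) {
    m <- length(ring)
    for (k in seq_len(m)) {
      a <- ring[[k]]; b <- ring[[k %% m + 1L]]
      if (!has_double[a] && !has_double[b]) {
        r <- bond_row(graph$bonds, a, b)
        if (length(r) == 1L) {
          orders[r] <- 2
          has_double[a] <- TRUE
          has_double[b] <- TRUE
        }
      }
    }
  }
  orders
}

#' Assign bond orders and formal charges
#'
#' Optimizes the bond orders of a perceived graph by a beam search that
#' minimizes a valence-charge penalty: candidate aromatic rings are seeded
#' with an alternating Kekulé pattern, then at each step the atoms with the
#' worst valence description have their incident (non-metal) bonds adjusted
#' single/double/triple, keeping the `beam_width` best patterns. Patterns
#' minimizing valence deviation are preferred over those minimizing formal
#' charge (`w_valence > w_charge`). Metal-ligand bond orders are fixed at
#' one throughout and labelled dative when the ligand donor atom is
#' valence-satisfied without counting its metal bonds. Kekulé rings whose
#' perimeter alternation survived are rewritten to uniform aromatic order
#' 1.5. Formal charges satisfy `sum == total_charge` (any residual is
#' carried by the metals, else by the most valence-strained atom).
#'
#' @param graph A `mol_graph` from [build_connectivity()].
#' @param total_charge Total molecular charge (integer).
#' @param config A [graph_config()].
#' @return The graph with `order`, `dative` and `formal_charges` set. If the
#'   iteration cap is reached, the best pattern so far is returned and
#'   `metadata$order_warning` is `TRUE`.
#' @export
assign_bond_orders <- function(graph, total_charge = 0L,
                               config = graph_config()) {
  b <- graph$bonds
  n_b <- nrow(b)
  graph$total_charge <- as.integer(total_charge)
  el <- graph$atoms$element
  valence_sets <- lapply(el, allowed_valences)
  metal <- is_metal(el)
  if (n_b == 0L) {
    graph$formal_charges <- finalize_charges(graph, numeric(0), total_charge,
                                             config, valence_sets)
    return(graph)
  }

  adjustable <- !(metal[b$i] | metal[b$j])
  orders0 <- rep(1, n_b)

  rings <- aromatic_candidates(graph, config)
  seeds <- list(orders0)
  if (length(rings)) seeds <- c(seeds, list(kekule_seed(graph, rings, orders0)))

  # incident adjustable bond rows per atom
  incid <- lapply(seq_len(n_atoms(graph)), function(a) {
    which((b$i == a | b$j == a) & adjustable)
  })

  pen <- function(o) pattern_penalty(graph, o, total_charge, config,
                                     valence_sets)
  key <- function(o) paste(o, collapse = ",")

  beam <- unique(seeds)
  beam_pen <- vapply(beam, pen, numeric(1))
  best <- beam[[which.min(beam_pen)]]
  best_pen <- min(beam_pen)
  warned <- FALSE

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > config$max_iter) { warned <- TRUE; break }
    if (best_pen == 0) break
    cand <- list(); cand_pen <- numeric(0); seen <- character(0)
    for (s_i in seq_along(beam)) {
      o <- beam[[s_i]]
      terms <- pattern_terms(graph, o, config, valence_sets)
      atom_pen <- config$w_valence * terms$dev + config$w_charge * abs(terms$q)
      worst <- which(atom_pen == max(atom_pen) & atom_pen > 0)
      if (length(worst) == 0L) next
      for (a in worst) {
        for (r in incid[[a]]) {
          for (step in c(-1, 1)) {
            new_o <- o
            new_o[r] <- o[r] + step
            if (new_o[r] < 1 || new_o[r] > 3) next
            k <- key(new_o)
            if (k %in% seen) next
            seen <- c(seen, k)
            cand[[length(cand) + 1L]] <- new_o
            cand_pen[[length(cand_pen) + 1L]] <- pen(new_o)
          }
        }
      }
    }
    if (length(cand) == 0L || min(cand_pen) >= best_pen) break
    ord <- order(cand_pen)[seq_len(min(config$beam_width, length(cand)))]
    beam <- cand[ord]
    beam_pen <- cand_pen[ord]
    if (beam_pen[[1]] < best_pen) {
      best_pen <- beam_pen[[1]]
      best <- beam[[1]]
    }
  }

  # lexicographic tie-break among minimal-penalty patterns in the final beam
  minimal <- beam[beam_pen == best_pen]
  if (length(minimal) >= 1L) {
    keys <- vapply(minimal, function(o) {
      paste(sprintf("%d", o), collapse = ",")
    }, character(1))
    best <- minimal[[order(keys)[[1]]]]
  }
  # deterministic coordinate descent to the (locally) lexicographically
  # smallest equal-penalty pattern: bonds in canonical order take the
  # smallest order that keeps the penalty minimal
  repeat {
    improved <- FALSE
    for (r in which(adjustable)) {
      for (o_try in seq_len(3)) {
        if (o_try >= best[r]) break
        trial <- best
        trial[r] <- o_try
        if (pen(trial) <= best_pen) {
          best <- trial
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }

  charges <- finalize_charges(graph, best, total_charge, config, valence_sets)

  # dative labelling of metal-ligand bonds
  dative <- rep(FALSE, n_b)
  s_all <- order_sums(graph, best)
  ml <- which(xor(metal[b$i], metal[b$j]))
  for (r in ml) {
    donor <- if (metal[b$i[r]]) b$j[r] else b$i[r]
    metal_rows <- which((b$i == donor & metal[b$j]) |
                          (b$j == donor & metal[b$i]))
    s_wo <- s_all[donor] - sum(best[metal_rows])
    dative[r] <- valence_deviation(el[donor], s_wo) == 0
  }

  # aromatic conversion of rings whose alternation survived
  final_orders <- best
  for (ring in rings) {
    m <- length(ring)
    ring_rows <- vapply(seq_len(m), function(k) {
      r <- bond_row(graph$bonds, ring[[k]], ring[[k %% m + 1L]])
      if (length(r) == 1L) r else NA_integer_
    }, integer(1))
    if (anyNA(ring_rows)) next
    o <- best[ring_rows]
    doubles_per_atom <- vapply(ring, function(a) {
      sum(o[b$i[ring_rows] == a | b$j[ring_rows] == a] == 2)
    }, numeric(1))
    alternating <- all(o %in% c(1, 2)) &&
      sum(o == 2) == floor(m / 2) && all(doubles_per_atom <= 1)
    if (alternating) final_orders[ring_rows] <- 1.5
  }

  graph$bonds$order <- final_orders
  graph$bonds$dative <- dative
  graph$formal_charges <- charges
  graph$metadata$order_warning <- warned
  graph$metadata$penalty <- best_pen
  graph
}

# Intrinsic per-atom charges plus deterministic residual assignment so the
# charges sum exactly to the total charge.
finalize_charges <- function(graph, orders, total_charge, config,
                             valence_sets) {
  n <- n_atoms(graph)
  if (length(orders) == 0L && n_bonds(graph) > 0L) orders <- graph$bonds$order
  terms <- pattern_terms(graph, orders, config, valence_sets)
  q <- terms$q
  residual <- as.integer(round(total_charge - sum(q)))
  if (residual != 0L) {
    metals <- which(is_metal(graph$atoms$element))
    target <- if (length(metals)) {
      metals[[1]]
    } else if (any(terms$dev > 0)) {
      which.max(terms$dev)
    } else {
      1L
    }
    q[target] <- q[target] + residual
  }
  as.integer(round(q))
}

#' Perceive a full molecular graph from a geometry
#'
#' Convenience wrapper: [build_connectivity()] followed by
#' [assign_bond_orders()].
#'
#' @param geometry Geometry tibble.
#' @param total_charge Total molecular charge.
#' @param config A [graph_config()].
#' @param ts_mode Apply transition-state threshold scaling?
#' @return A `mol_graph` with orders, dative flags and formal charges set.
#' @export
perceive_graph <- function(geometry, total_charge = 0L,
                           config = graph_config(), ts_mode = FALSE) {
  g <- build_connectivity(geometry, config, ts_mode = ts_mode)
  assign_bond_orders(g, total_charge = total_charge, config = config)
}
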