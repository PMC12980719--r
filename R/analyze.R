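# The end-to-end pipelines: normal-mode analysis of a TS geometry and
# internal-coordinate analysis of an IRC/QRC trajectory.

#' Analyze a transition state from its imaginary normal mode
#'
#' Full pipeline: select the imaginary mode, displace the geometry along it
#' (forward/reverse), perceive the molecular graph on the TS with
#' transition-state threshold scaling, enumerate internal coordinates
#' (optionally augmented with reactant/product graphs), evaluate and screen
#' the forward-reverse changes, filter correlated motion and classify the
#' mode. Deltas are forward minus reverse. Deterministic for fixed inputs
#' and configuration.
#'
#' @param geometry Geometry tibble of the transition state.
#' @param modes A `normal_mode` or list of them (at least one imaginary).
#' @param amplitude Maximum per-atom displacement in Angstrom.
#' @param screen A [screen_config()].
#' @param config A [graph_config()].
#' @param total_charge Total molecular charge.
#' @param reactant,product Optional geometry tibbles used to augment the
#'   internal-coordinate set with their graph edges.
#' @param displaced_path Optional path: write the forward/reverse pair as a
#'   two-frame XYZ (for subsequent QRC optimization).
#' @param file_paths Optional named list of input file paths recorded in the
#'   report.
#' @return A `ts_report`: screened changes, mode class, graphs, extra
#'   imaginary frequencies and provenance. See [write_report()].
#' @export
analyze_ts <- function(geometry, modes, amplitude = 0.5,
                       screen = screen_config(), config = graph_config(),
                       total_charge = 0L, reactant = NULL, product = NULL,
                       displaced_path = NULL, file_paths = list()) {
  check_geometry(geometry)
  sel <- select_imaginary(modes)
  pair <- displace_along_mode(geometry, sel$mode, amplitude)
  if (!is.null(displaced_path)) write_displaced(pair, displaced_path)

  graph <- perceive_graph(geometry, total_charge = total_charge,
                          config = config, ts_mode = TRUE)
  augment <- list()
  for (g in list(reactant, product)) {
    if (!is.null(g)) {
      augment[[length(augment) + 1L]] <-
        perceive_graph(g, total_charge = total_charge, config = config)
    }
  }
  internals <- enumerate_internals(graph, augment = if (length(augment)) augment)

  deltas <- internal_deltas(internals, pair$reverse, pair$forward)
  changes <- detect_changes(deltas, screen, graph = graph)
  changes <- filter_correlated(changes, graph)
  cls <- classify_mode(changes, graph, pair$forward, pair$reverse, screen)

  new_ts_report(
    changes = cls$changes,
    mode_class = cls$mode_class,
    frames_used = c("reverse", "forward"),
    graph = graph,
    end_graphs = augment,
    extra_imaginaries = sel$extra_imaginary,
    imaginary_frequency = sel$mode$frequency,
    amplitude = amplitude,
    source = "normal_mode",
    file_paths = file_paths)
}

#' Analyze an IRC/QRC trajectory
#'
#' Selects the two frames to compare (maximum pairwise Kabsch RMSD or the
#' endpoints), perceives the molecular graph at the frame nearest the
#' trajectory midpoint (the transition-state proxy) with transition-state
#' threshold scaling, augments the internal coordinates with the endpoint
#' graphs, and runs the same screening/filtering/classification pipeline as
#' [analyze_ts()]. Deltas are later frame minus earlier frame.
#'
#' @param frames List of geometry tibbles (an IRC/QRC trajectory, >= 2
#'   consistent frames).
#' @param strategy Frame selection: `"max_rmsd"` or `"endpoints"`.
#' @param screen A [screen_config()].
#' @param config A [graph_config()].
#' @param total_charge Total molecular charge.
#' @param file_paths Optional named list of input file paths recorded in the
#'   report.
#' @return A `ts_report`.
#' @export
analyze_trajectory <- function(frames, strategy = c("max_rmsd", "endpoints"),
                               screen = screen_config(),
                               config = graph_config(), total_charge = 0L,
                               file_paths = list()) {
  strategy <- match.arg(strategy)
  if (length(frames) < 2L) stop("need at least two frames", call. = FALSE)
  n0 <- nrow(frames[[1]])
  for (f in frames) {
    check_geometry(f)
    if (nrow(f) != n0 || !identical(f$element, frames[[1]]$element)) {
      stop("inconsistent atoms across trajectory frames", call. = FALSE)
    }
  }
  sel <- select_frames(frames, strategy)
  mid <- midpoint_frame(frames)
  graph <- perceive_graph(frames[[mid]], total_charge = total_charge,
                          config = config, ts_mode = TRUE)
  ends <- unique(c(1L, length(frames)))
  end_graphs <- lapply(ends, function(k) {
    perceive_graph(frames[[k]], total_charge = total_charge, config = config)
  })
  internals <- enumerate_internals(graph, augment = end_graphs)

  geom_a <- frames[[sel[[1]]]]
  geom_b <- frames[[sel[[2]]]]
  deltas <- internal_deltas(internals, geom_a, geom_b)
  changes <- detect_changes(deltas, screen, graph = graph)
  changes <- filter_correlated(changes, graph)
  cls <- classify_mode(changes, graph, geom_b, geom_a, screen)

  new_ts_report(
    changes = cls$changes,
    mode_class = cls$mode_class,
    frames_used = sel,
    graph = graph,
    end_graphs = end_graphs,
    extra_imaginaries = numeric(0),
    imaginary_frequency = NA_real_,
    amplitude = NA_real_,
    source = paste0("trajectory_", strategy),
    file_paths = file_paths)
}
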