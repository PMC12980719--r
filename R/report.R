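# Structured change report: container, JSON serialization (versioned
# schema, lossless round-trip) and tidy/plot methods.

REPORT_SCHEMA_VERSION <- 1L

new_ts_report <- function(changes, mode_class, frames_used, graph,
                          end_graphs = list(), extra_imaginaries = numeric(0),
                          imaginary_frequency = NA_real_,
                          amplitude = NA_real_, source = "normal_mode",
                          file_paths = list()) {
  structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    changes = changes,
    mode_class = mode_class,
    frames_used = frames_used,
    graph = graph,
    end_graphs = end_graphs,
    extra_imaginaries = extra_imaginaries,
    imaginary_frequency = imaginary_frequency,
    amplitude = amplitude,
    source = source,
    file_paths = file_paths), class = "ts_report")
}

#' @export
print.ts_report <- function(x, ...) {
  cat("<ts_report> mode class: ", x$mode_class, "\n", sep = "")
  if (!is.na(x$imaginary_frequency)) {
    cat("  imaginary mode: ", x$imaginary_frequency, " cm^-1\n", sep = "")
  }
  if (length(x$extra_imaginaries)) {
    cat("  additional imaginary frequencies: ",
        paste(x$extra_imaginaries, collapse = ", "), " cm^-1\n", sep = "")
  }
  if (nrow(x$changes) == 0L) {
    cat("  no internal-coordinate changes detected\n")
  } else {
    print(tidy(x))
  }
  invisible(x)
}

#' Tidy the screened internal-coordinate changes of a report
#'
#' @param x A `ts_report`.
#' @param ... Unused.
#' @return A tibble: coordinate kind, atom label (element + 0-based index),
#'   signed `delta` (Angstrom for bonds, degrees otherwise),
#'   `classification` and `provenance`.
#' @export
tidy.ts_report <- function(x, ...) {
  ch <- x$changes
  tibble::tibble(kind = ch$kind, coordinate = ch$label, delta = ch$delta,
                 classification = ch$classification,
                 provenance = ch$provenance)
}

#' One-row summary of a report
#'
#' @param x A `ts_report`.
#' @param ... Unused.
#' @return A one-row tibble: mode class, change counts by type, imaginary
#'   frequency and number of additional imaginary modes.
#' @export
glance.ts_report <- function(x, ...) {
  cls <- x$changes$classification
  tibble::tibble(
    mode_class = x$mode_class,
    n_changes = nrow(x$changes),
    n_bond_break = sum(cls == "bond_break"),
    n_bond_form = sum(cls == "bond_form"),
    n_rotation = sum(cls == "rotation"),
    n_inversion = sum(cls == "inversion"),
    imaginary_frequency = x$imaginary_frequency,
    n_extra_imaginary = length(x$extra_imaginaries))
}

#' Plot the screened changes of a report
#'
#' Horizontal bars of the signed changes, faceted by coordinate kind
#' (Angstrom for bonds, degrees for angular coordinates) and colored by
#' classification.
#'
#' @param object A `ts_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ts_report <- function(object, ...) {
  d <- tidy(object)
  if (nrow(d) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no changes") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta,
                                  y = stats::reorder(.data$coordinate,
                                                     abs(.data$delta)),
                                  fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind), scales = "free") +
    ggplot2::labs(x = "signed change (Å / degrees)", y = NULL,
                  fill = NULL,
                  title = paste("mode class:", object$mode_class)) +
    ggplot2::theme_minimal()
}

graph_to_list <- function(graph) {
  list(
    atoms = list(index = seq_len(n_atoms(graph)) - 1L,
                 element = graph$atoms$element,
                 x = graph$atoms$x, y = graph$atoms$y, z = graph$atoms$z,
                 formal_charge = graph$formal_charges),
    bonds = list(i = graph$bonds$i - 1L, j = graph$bonds$j - 1L,
                 order = graph$bonds$order, dative = graph$bonds$dative),
    total_charge = graph$total_charge,
    ts_mode = isTRUE(graph$metadata$ts_mode),
    order_warning = isTRUE(graph$metadata$order_warning))
}

graph_from_list <- function(gl) {
  atoms <- new_geometry(as.character(gl$atoms$element),
                        cbind(gl$atoms$x, gl$atoms$y, gl$atoms$z))
  bonds <- tibble::tibble(i = as.integer(gl$bonds$i) + 1L,
                          j = as.integer(gl$bonds$j) + 1L,
                          order = as.numeric(gl$bonds$order),
                          dative = as.logical(gl$bonds$dative))
  new_mol_graph(atoms, bonds,
                formal_charges = as.integer(gl$atoms$formal_charge),
                total_charge = as.integer(gl$total_charge),
                metadata = list(ts_mode = isTRUE(gl$ts_mode),
                                order_warning = isTRUE(gl$order_warning)))
}

#' Write a change report as versioned JSON
#'
#' The document contains every report field: the change list (coordinate
#' kind, 0-based atom indices, element labels, signed delta, classification,
#' provenance), the mode class, frames used, the perceived graphs (atoms
#' with formal charges, bonds with orders and dative flags), additional
#' imaginary frequencies and input file paths. `schema_version` is bumped on
#' any incompatible change. [read_report()] restores an equal report.
#'
#' @param report A `ts_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ch <- report$changes
  doc <- list(
    schema_version = report$schema_version,
    mode_class = report$mode_class,
    source = report$source,
    frames_used = report$frames_used,
    amplitude = report$amplitude,
    imaginary_frequency = report$imaginary_frequency,
    extra_imaginaries = report$extra_imaginaries,
    changes = list(kind = ch$kind,
                   a1 = ch$a1 - 1L, a2 = ch$a2 - 1L,
                   a3 = ch$a3 - 1L, a4 = ch$a4 - 1L,
                   label = ch$label, delta = ch$delta,
                   classification = ch$classification,
                   provenance = ch$provenance),
    graph = graph_to_list(report$graph),
    end_graphs = lapply(report$end_graphs, graph_to_list),
    file_paths = report$file_paths)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a change report written by [write_report()]
#'
#' @param path Path to a report JSON document.
#' @return A `ts_report`.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(doc$schema_version) ||
      doc$schema_version != REPORT_SCHEMA_VERSION) {
    stop("unsupported report schema version", call. = FALSE)
  }
  ch <- doc$changes
  as_int_na <- function(v) {
    if (is.list(v)) {
      vapply(v, function(x) if (is.null(x)) NA_integer_ else as.integer(x),
             integer(1))
    } else {
      as.integer(v)
    }
  }
  changes <- tibble::tibble(
    kind = as.character(ch$kind %||% character(0)),
    a1 = as_int_na(ch$a1 %||% integer(0)) + 1L,
    a2 = as_int_na(ch$a2 %||% integer(0)) + 1L,
    a3 = as_int_na(ch$a3 %||% integer(0)) + 1L,
    a4 = as_int_na(ch$a4 %||% integer(0)) + 1L,
    label = as.character(ch$label %||% character(0)),
    delta = as.numeric(ch$delta %||% numeric(0)),
    classification = as.character(ch$classification %||% character(0)),
    provenance = as.character(ch$provenance %||% character(0)))
  new_ts_report(
    changes = changes,
    mode_class = doc$mode_class,
    frames_used = doc$frames_used,
    graph = graph_from_list(doc$graph),
    end_graphs = lapply(doc$end_graphs, graph_from_list),
    extra_imaginaries = as.numeric(doc$extra_imaginaries %||% numeric(0)),
    imaginary_frequency = doc$imaginary_frequency %||% NA_real_,
    amplitude = doc$amplitude %||% NA_real_,
    source = doc$source,
    file_paths = doc$file_paths %||% list())
}
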