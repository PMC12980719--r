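# XYZ input/output. A geometry is a tibble with columns element, x, y, z
# (coordinates in Angstrom); the XYZ comment line is kept in attr "comment".

new_geometry <- function(element, xyz, comment = "") {
  g <- tibble::tibble(element = element,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(g, "comment") <- comment
  g
}

#' Coordinate matrix of a geometry
#'
#' @param geometry A geometry tibble (columns `element`, `x`, `y`, `z`).
#' @return An n x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @export
coords <- function(geometry) {
  as.matrix(geometry[, c("x", "y", "z")])
}

check_geometry <- function(geometry) {
  stopifnot(is.data.frame(geometry),
            all(c("element", "x", "y", "z") %in% names(geometry)))
  element_index(geometry$element)
  if (!all(is.finite(coords(geometry)))) {
    stop("geometry contains non-finite coordinates", call. = FALSE)
  }
  invisible(geometry)
}

#' Read (multi-frame) XYZ files
#'
#' Parses the standard XYZ layout: an atom-count line, a comment line, then
#' one `El x y z` line per atom; concatenated blocks form a multi-frame file
#' (e.g. an IRC trajectory). Coordinates are taken as Angstrom.
#'
#' @param path Path to an XYZ file.
#' @return A list of geometry tibbles (columns `element`, `x`, `y`, `z`), one
#'   per frame, each carrying its comment line as attribute `"comment"`.
#'   Atom counts must agree across frames.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[[i]]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[[i]])))
    if (is.na(n) || n < 1L) {
      stop("malformed atom-count line at line ", i, ": '", lines[[i]], "'",
           call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop("truncated XYZ block starting at line ", i, call. = FALSE)
    }
    comment <- lines[[i + 1L]]
    el <- character(n)
    xyz <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
      if (length(tok) < 4L) {
        stop("malformed atom line at line ", ln, ": '", lines[[ln]], "'",
             call. = FALSE)
      }
      val <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(val)) {
        stop("non-numeric coordinates at line ", ln, call. = FALSE)
      }
      el[[k]] <- tok[[1]]
      xyz[k, ] <- val
    }
    bad <- is.na(match(el, .element_symbols))
    if (any(bad)) {
      ln <- i + 1L + which(bad)[[1]]
      stop("unknown element symbol '", el[bad][[1]], "' at line ", ln,
           call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- new_geometry(el, xyz, comment)
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no XYZ frames found in ", path, call. = FALSE)
  counts <- vapply(frames, nrow, integer(1))
  if (length(unique(counts)) > 1L) {
    stop("inconsistent atom counts across frames: ",
         paste(unique(counts), collapse = ", "), call. = FALSE)
  }
  frames
}

#' Write geometries as a (multi-frame) XYZ file
#'
#' @param geometries A geometry tibble or a list of them.
#' @param path Output path.
#' @param comments Optional character vector of comment lines (one per frame);
#'   defaults to each geometry's `"comment"` attribute.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geometries, path, comments = NULL) {
  if (is.data.frame(geometries)) geometries <- list(geometries)
  out <- character(0)
  for (f in seq_along(geometries)) {
    g <- geometries[[f]]
    check_geometry(g)
    cm <- if (!is.null(comments)) comments[[f]] else attr(g, "comment") %||% ""
    out <- c(out, as.character(nrow(g)), cm,
             sprintf("%-3s %14.8f %14.8f %14.8f", g$element, g$x, g$y, g$z))
  }
  writeLines(out, path)
  invisible(path)
}
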