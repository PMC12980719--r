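# Normal-mode input and displacement. The minimal text format: a header
# line "freq <value>" (cm^-1, negative = imaginary), then one "x y z"
# displacement line per atom; multiple blocks allowed; '#' comments ignored.

new_normal_mode <- function(frequency, displacements) {
  stopifnot(is.matrix(displacements), ncol(displacements) == 3)
  if (all(displacements == 0)) {
    stop("normal mode has an all-zero displacement field", call. = FALSE)
  }
  structure(list(frequency = frequency, displacements = displacements),
            class = "normal_mode")
}

#' @export
print.normal_mode <- function(x, ...) {
  cat("<normal_mode> ", x$frequency, " cm^-1, ", nrow(x$displacements),
      " atoms\n", sep = "")
  invisible(x)
}

#' Read normal modes from the plain-text mode format
#'
#' Each block is a line `freq <value>` (frequency in cm^-1; a negative value
#' denotes an imaginary mode) followed by one whitespace-separated `x y z`
#' displacement line per atom. Lines starting with `#` are ignored.
#'
#' @param path Path to a mode file.
#' @return A list of `normal_mode` objects in file order, each with fields
#'   `frequency` and `displacements` (n x 3 matrix).
#' @export
read_modes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  modes <- list()
  i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(lines[[i]], "\\s+")[[1]]
    if (tolower(tok[[1]]) != "freq" || length(tok) < 2L) {
      stop("expected 'freq <value>' header, got: '", lines[[i]], "'",
           call. = FALSE)
    }
    freq <- suppressWarnings(as.numeric(tok[[2]]))
    if (is.na(freq)) stop("non-numeric frequency: '", lines[[i]], "'",
                          call. = FALSE)
    i <- i + 1L
    disp <- list()
    while (i <= length(lines) &&
           tolower(strsplit(lines[[i]], "\\s+")[[1]][[1]]) != "freq") {
      val <- suppressWarnings(as.numeric(strsplit(lines[[i]], "\\s+")[[1]]))
      if (length(val) != 3L || anyNA(val)) {
        stop("malformed displacement line: '", lines[[i]], "'", call. = FALSE)
      }
      disp[[length(disp) + 1L]] <- val
      i <- i + 1L
    }
    if (length(disp) == 0L) stop("mode block with no displacements",
                                 call. = FALSE)
    modes[[length(modes) + 1L]] <- new_normal_mode(freq, do.call(rbind, disp))
  }
  if (length(modes) == 0L) stop("no modes found in ", path, call. = FALSE)
  modes
}

#' Write normal modes in the plain-text mode format
#'
#' @param modes A `normal_mode` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modes <- function(modes, path) {
  if (inherits(modes, "normal_mode")) modes <- list(modes)
  out <- character(0)
  for (m in modes) {
    out <- c(out, sprintf("freq %.6g", m$frequency),
             sprintf("%14.8f %14.8f %14.8f", m$displacements[, 1],
                     m$displacements[, 2], m$displacements[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Select the imaginary mode of a transition state
#'
#' Returns the mode with the most negative frequency; any further negative
#' frequencies are reported as diagnostics (nonequilibrium structures can
#' carry residual small imaginary modes).
#'
#' @param modes A list of `normal_mode` objects.
#' @return A list with `mode` (the selected `normal_mode`) and
#'   `extra_imaginary` (numeric vector of the other negative frequencies).
#' @export
select_imaginary <- function(modes) {
  if (inherits(modes, "normal_mode")) modes <- list(modes)
  stopifnot(length(modes) >= 1L)
  freqs <- vapply(modes, function(m) m$frequency, numeric(1))
  neg <- which(freqs < 0)
  if (length(neg) == 0L) {
    stop("not a transition state: no imaginary (negative) frequency",
         call. = FALSE)
  }
  sel <- neg[[which.min(freqs[neg])]]
  list(mode = modes[[sel]],
       extra_imaginary = freqs[setdiff(neg, sel)])
}

#' Displace a geometry along a normal mode
#'
#' The displacement field is normalized so that its largest per-atom norm is
#' one; `forward = r + amplitude * d`, `reverse = r - amplitude * d`, so the
#' most-moving atom is displaced by exactly `amplitude` Angstrom and the
#' midpoint of the pair is the input geometry.
#'
#' @param geometry Geometry tibble (the transition state).
#' @param mode A `normal_mode` whose atom count matches the geometry.
#' @param amplitude Maximum per-atom displacement in Angstrom (> 0; 0 is
#'   tolerated and returns two copies of the input).
#' @return A list of class `displaced_pair` with `forward`, `reverse`
#'   (geometry tibbles) and `amplitude`.
#' @export
displace_along_mode <- function(geometry, mode, amplitude = 0.5) {
  check_geometry(geometry)
  d <- mode$displacements
  if (nrow(d) != nrow(geometry)) {
    stop("mode has ", nrow(d), " displacement vectors for ", nrow(geometry),
         " atoms", call. = FALSE)
  }
  norms <- sqrt(rowSums(d^2))
  if (max(norms) == 0) stop("zero mode vector", call. = FALSE)
  dhat <- d / max(norms)
  xyz <- coords(geometry)
  fwd <- new_geometry(geometry$element, xyz + amplitude * dhat,
                      sprintf("tsmode forward a=%g", amplitude))
  rev <- new_geometry(geometry$element, xyz - amplitude * dhat,
                      sprintf("tsmode reverse a=%g", amplitude))
  structure(list(forward = fwd, reverse = rev, amplitude = amplitude),
            class = "displaced_pair")
}

#' Write a displaced pair as a two-frame XYZ file
#'
#' @param pair A `displaced_pair` from [displace_along_mode()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_displaced <- function(pair, path) {
  write_xyz(list(pair$forward, pair$reverse), path)
}
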