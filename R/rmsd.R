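# Kabsch-aligned RMSD and trajectory frame selection.

#' Minimum RMSD after optimal superposition (Kabsch)
#'
#' Translates both geometries to their centroids and applies the optimal
#' proper rotation (SVD with determinant correction) before computing the
#' root-mean-square deviation over all atoms. Alignment makes the measure a
#' pure shape difference, insensitive to rigid drift between trajectory
#' frames.
#'
#' @param geom_a,geom_b Geometry tibbles with equal atom counts and order.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(geom_a, geom_b) {
  A <- coords(geom_a); B <- coords(geom_b)
  if (nrow(A) != nrow(B)) stop("atom count mismatch", call. = FALSE)
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  sv <- svd(crossprod(A, B))  # covariance A^T B
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # rotates A onto B
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

#' Select the frame pair to compare from a trajectory
#'
#' Either the first and last frames, or the maximally geometrically diverse
#' pair (largest pairwise Kabsch RMSD; ties broken by the earliest pair in
#' frame order). The earlier frame is returned first.
#'
#' @param frames List of geometry tibbles (>= 2, consistent atoms).
#' @param strategy `"max_rmsd"` or `"endpoints"`.
#' @return Integer vector `c(a, b)` of 1-based frame indices, `a < b`.
#' @export
select_frames <- function(frames, strategy = c("max_rmsd", "endpoints")) {
  strategy <- match.arg(strategy)
  n <- length(frames)
  if (n < 2L) stop("need at least two frames", call. = FALSE)
  if (strategy == "endpoints") return(c(1L, n))
  best <- c(1L, 2L); best_r <- -Inf
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      r <- kabsch_rmsd(frames[[a]], frames[[b]])
      if (r > best_r + 1e-12) {
        best_r <- r
        best <- c(a, b)
      }
    }
  }
  best
}

# Index of the frame nearest the trajectory midpoint by cumulative
# Kabsch-RMSD arc length (the transition-state proxy for IRC input).
midpoint_frame <- function(frames) {
  n <- length(frames)
  if (n == 1L) return(1L)
  steps <- vapply(seq_len(n - 1L), function(k) {
    kabsch_rmsd(frames[[k]], frames[[k + 1L]])
  }, numeric(1))
  arc <- c(0, cumsum(steps))
  which.min(abs(arc - arc[[n]] / 2))
}
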