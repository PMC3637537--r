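#' Rigid-body superposition
#'
#' A superposition is a proper rigid transform `x -> R x + t` mapping model
#' coordinates into the query coordinate system.
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation numeric length-3 translation in Angstrom.
#' @param source_frame_pair optional integer pair `(model frame, query frame)`
#'   recording which reference-frame match produced this transform.
#' @return An object of class `superposition`.
#' @export
new_superposition <- function(rotation = diag(3), translation = c(0, 0, 0),
                              source_frame_pair = NULL) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be proper orthonormal (det = +1)")
  }
  structure(list(rotation = rotation, translation = translation,
                 source_frame_pair = source_frame_pair),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid superposition (model -> query)\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(sprintf("%.4f", x$translation), collapse = " "), "\n")
  invisible(x)
}

#' Optimal least-squares (Kabsch) superposition
#'
#' Finds the proper rigid transform of `coords_b` that minimizes the RMSD to
#' `coords_a` (maps b onto a). The reflection branch of the SVD solution is
#' sign-corrected so the returned rotation always has determinant +1,
#' preserving chirality.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices (equal row counts).
#' @return list with elements `sup` (a [new_superposition()] object) and
#'   `rmsd` (the minimized RMSD in Angstrom).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as_xyz_matrix(coords_a)
  b <- as_xyz_matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("coordinate sets must have equal lengths")
  if (nrow(a) < 1L) stop("need at least one point")
  ca <- colMeans(a)
  cb <- colMeans(b)
  ac <- sweep(a, 2, ca)
  bc <- sweep(b, 2, cb)
  h <- crossprod(bc, ac)                 # 3x3 covariance, b -> a
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1                     # fully degenerate (e.g. single point)
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- ca - as.numeric(rot %*% cb)
  moved <- bc %*% t(rot)
  rmsd <- sqrt(sum((ac - moved)^2) / nrow(a))
  list(sup = new_superposition(rot, trans), rmsd = rmsd)
}

#' Apply a rigid superposition to coordinates
#'
#' @param coords n x 3 coordinate matrix (or length-3 vector).
#' @param sup a `superposition`.
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_superposition <- function(coords, sup) {
  x <- as_xyz_matrix(coords)
  sweep(x %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Invert a rigid superposition
#'
#' @param sup a `superposition`.
#' @return the inverse `superposition`.
#' @export
invert_superposition <- function(sup) {
  rt <- t(sup$rotation)
  new_superposition(rt, -as.numeric(rt %*% sup$translation))
}

# Coerce vectors / data frames to an n x 3 numeric matrix.
as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    if (ncol(x) != 3L) stop("coordinates must have 3 columns")
    return(unname(x))
  }
  x <- as.numeric(unlist(x))
  if (length(x) == 3L) return(matrix(x, 1L, 3L))
  matrix(x, ncol = 3L, byrow = TRUE)
}
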