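#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimise the RMSD between
#' two ordered point sets of equal size, and reports the post-fit RMSD.
#' Reflections are excluded: the returned rotation always has determinant +1,
#' so chirality is preserved even when a reflected fit would score better.
#'
#' The recovered transform maps `mov` onto `ref`:
#' `fitted = mov %*% t(rotation) + translation` (row-vector convention).
#'
#' @param ref numeric matrix, n x 3, reference coordinates in Angstrom.
#' @param mov numeric matrix, n x 3, coordinates to be fitted.
#' @return An object of class `SuperpositionResult`: a list with `rotation`
#'   (3 x 3 orthonormal, det +1), `translation` (length-3), `rmsd` (Angstrom)
#'   and `n_points`.
#' @examples
#' pts <- matrix(rnorm(15), 5, 3)
#' superpose(pts, pts)$rmsd  # 0
#' @export
superpose <- function(ref, mov) {
  ref <- as_coord_matrix(ref, "ref")
  mov <- as_coord_matrix(mov, "mov")
  if (nrow(ref) != nrow(mov)) {
    stop("superpose: point counts differ (", nrow(ref), " vs ", nrow(mov), ")")
  }
  n <- nrow(ref)
  if (n < 3) stop("superpose: need at least 3 points, got ", n)

  cref <- colMeans(ref)
  cmov <- colMeans(mov)
  a <- sweep(ref, 2, cref)
  b <- sweep(mov, 2, cmov)

  h <- crossprod(b, a)          # 3x3 covariance, mov' %*% ref
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1            # degenerate (rank-deficient) covariance
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)

  fitted <- b %*% t(rot)
  rmsd <- sqrt(sum((fitted - a)^2) / n)
  trans <- as.numeric(cref - cmov %*% t(rot))

  structure(
    list(rotation = rot, translation = trans, rmsd = rmsd, n_points = n),
    class = "SuperpositionResult"
  )
}

#' Apply a superposition transform to coordinates
#'
#' @param sp a `SuperpositionResult` from [superpose()].
#' @param xyz numeric matrix, n x 3.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  xyz <- as_coord_matrix(xyz, "xyz")
  sweep(xyz %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition of %d points: RMSD %.4f A\n", x$n_points, x$rmsd))
  invisible(x)
}

# Coerce to an n x 3 numeric matrix with finite entries.
as_coord_matrix <- function(x, what) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop(what, ": coordinates must be n x 3")
  if (!all(is.finite(x))) stop(what, ": coordinates must be finite")
  x
}

# RMSD between already-corresponding coordinate rows, no fitting.
rmsd_inplace <- function(a, b) {
  sqrt(sum((a - b)^2) / nrow(a))
}
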