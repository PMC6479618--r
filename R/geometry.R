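## Low-level vector geometry shared by the design and ensemble modules.
## All coordinates are in Angstrom, all angles in degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Bond angle a-b-c in degrees
#' @param a,b,c 3-vectors (Angstrom); `b` is the vertex.
#' @return angle in degrees in \[0, 180\].
#' @keywords internal
vec_angle <- function(a, b, c) {
  v1 <- vunit(a - b)
  v2 <- vunit(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Signed torsion angle a-b-c-d in degrees
#'
#' Uses the atan2 formulation, which is numerically stable near 0/180.
#' Sign follows the standard right-handed (IUPAC) convention.
#' @param a,b,c,d 3-vectors (Angstrom).
#' @return torsion in degrees in (-180, 180\].
#' @keywords internal
vec_dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Given three previously placed atoms `a`, `b`, `c`, returns the position
#' of a fourth atom `d` with bond length `|c-d| = r`, bond angle
#' `b-c-d = theta` and torsion `a-b-c-d = phi`.
#'
#' @param a,b,c 3-vectors of the reference atoms.
#' @param r bond length (Angstrom).
#' @param theta bond angle (degrees).
#' @param phi torsion (degrees).
#' @return 3-vector position of the new atom.
#' @keywords internal
nerf_place <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- vunit(c - b)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-10) stop("collinear reference atoms: degenerate frame")
  n <- vunit(n)
  m <- vcross(n, bc)
  d2 <- r * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Computes the proper rotation and translation that minimise the
#' (optionally weighted) RMSD between two paired point sets, via SVD of
#' the covariance matrix with the usual determinant correction so that
#' reflections are never returned.
#'
#' @param ref_coords N x 3 matrix of reference coordinates (Angstrom).
#' @param mob_coords N x 3 matrix of mobile coordinates, paired row-wise
#'   with `ref_coords`.
#' @param weights optional non-negative weights of length N.
#' @return list with `rotation` (3 x 3, det +1), `translation`
#'   (length-3; the superposed mobile set is `mob %*% t(R) + t`) and
#'   `rmsd` (Angstrom, weighted RMS residual after superposition).
#' @examples
#' ref <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch_superpose(ref, ref)
#' stopifnot(fit$rmsd < 1e-12)
#' @export
kabsch_superpose <- function(ref_coords, mob_coords, weights = NULL) {
  ref_coords <- as.matrix(ref_coords)
  mob_coords <- as.matrix(mob_coords)
  n <- nrow(ref_coords)
  if (n < 3L) stop("need at least 3 points for superposition")
  if (!all(dim(ref_coords) == dim(mob_coords))) {
    stop("coordinate sets must have identical dimensions")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)

  cen_ref <- colSums(ref_coords * w)
  cen_mob <- colSums(mob_coords * w)
  p <- sweep(ref_coords, 2L, cen_ref)
  q <- sweep(mob_coords, 2L, cen_mob)

  ## collinearity check: rank of the weighted reference spread
  sv_ref <- svd(p * sqrt(w))$d
  if (sv_ref[2L] < 1e-8 * max(sv_ref[1L], 1)) {
    stop("degenerate (collinear) point set: superposition undefined")
  }

  h <- t(q * w) %*% p
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  corr <- diag(c(1, 1, d))
  rot <- s$v %*% corr %*% t(s$u)

  fitted <- q %*% t(rot)
  resid2 <- rowSums((fitted - p)^2)
  rmsd <- sqrt(sum(w * resid2))
  translation <- cen_ref - as.vector(cen_mob %*% t(rot))
  list(rotation = rot, translation = translation, rmsd = rmsd)
}

## Standard atomic masses (u) for the heavy atoms that occur in
## backbone + CB + SG models.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, SE = 78.971)

element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .atomic_masses[el]
  if (anyNA(m)) {
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(el[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance of a point set from its centre of mass:
#' `Rg = sqrt(sum(m_i * |r_i - r_com|^2) / sum(m_i))`.
#'
#' @param coords N x 3 matrix (Angstrom).
#' @param masses positive masses of length N; defaults to uniform.
#' @return Rg in Angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1.0
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("need at least one atom")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (length(masses) != nrow(coords) || any(masses <= 0)) {
    stop("masses must be positive and match the number of atoms")
  }
  total <- sum(masses)
  if (total <= 0) stop("zero total mass")
  com <- colSums(coords * masses) / total
  sq <- rowSums(sweep(coords, 2L, com)^2)
  sqrt(sum(masses * sq) / total)
}

## Deterministic rigid transforms -------------------------------------------

#' Random proper rotation matrix
#'
#' Draws a uniformly distributed rotation from the current RNG stream
#' (quaternion method).
#' @return 3 x 3 rotation matrix with determinant +1.
#' @keywords internal
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / vnorm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

apply_rigid <- function(coords, rotation, translation) {
  sweep(as.matrix(coords) %*% t(rotation), 2L, translation, "+")
}

## Run an expression with a temporary RNG seed, restoring the caller's
## RNG state afterwards. Keeps generators pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
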