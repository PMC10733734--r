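## Shared geometric primitives: distances, bond angles, signed dihedrals and
## internal-to-Cartesian atom placement. All angles are in degrees; dihedrals
## follow the IUPAC sign convention and live in (-180, 180].

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Measure distance, bond angle and dihedral for four points
#'
#' Computes the distance b--c, the bond angle a-b-c and the signed torsion
#' angle a-b-c-d. This single primitive backs the backbone builder, the
#' torsion-library harvester and the gap-closure junction checks, so all
#' three agree on conventions by construction.
#'
#' @param a,b,c,d Numeric 3-vectors (coordinates in Angstrom).
#' @return A list with elements `distance` (Angstrom, b to c), `angle`
#'   (degrees at b) and `dihedral` (degrees, IUPAC sign, in (-180, 180]).
#' @examples
#' measureGeometry(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))$dihedral  # 0
#' @export
measureGeometry <- function(a, b, c, d) {
  stopifnot(length(a) == 3L, length(b) == 3L, length(c) == 3L, length(d) == 3L)
  if (!all(is.finite(c(a, b, c, d)))) {
    stop("measureGeometry: coordinates must be finite")
  }
  list(distance = .vnorm(c - b),
       angle    = bondAngle(a, b, c),
       dihedral = dihedralAngle(a, b, c, d))
}

#' Bond angle at the middle point
#' @param a,b,c Numeric 3-vectors.
#' @return Angle a-b-c in degrees, in [0, 180].
#' @export
bondAngle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- .vnorm(u)
  nv <- .vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) stop("bondAngle: coincident points")
  cosang <- sum(u * v) / (nu * nv)
  .rad2deg(acos(max(-1, min(1, cosang))))
}

#' Signed torsion angle of four points
#' @param a,b,c,d Numeric 3-vectors.
#' @return Dihedral in degrees, IUPAC sign convention, in (-180, 180].
#' @export
dihedralAngle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10) {
    stop("dihedralAngle: collinear points give an undefined torsion")
  }
  ang <- .rad2deg(atan2(sum((b2 / .vnorm(b2)) * .vcross(n1, n2)),
                        sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

## Smallest angular separation of two angles on the circle, in degrees.
angularDistance <- function(x, y) {
  d <- abs(x - y) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Place an atom from internal coordinates
#'
#' Given three previously placed atoms a-b-c, places a new atom bonded to `c`
#' at the stated bond length, with bond angle b-c-new and torsion
#' a-b-c-new (natural extension reference frame).
#'
#' @param a,b,c Numeric 3-vectors of the three reference atoms.
#' @param bond Bond length c--new in Angstrom.
#' @param angle Bond angle b-c-new in degrees.
#' @param dihedral Torsion a-b-c-new in degrees.
#' @return Numeric 3-vector of the new atom.
#' @export
placeAtom <- function(a, b, c, bond, angle, dihedral) {
  th <- .deg2rad(angle)
  ch <- .deg2rad(dihedral)
  bc <- c - b
  bc <- bc / .vnorm(bc)
  ab <- b - a
  n <- .vcross(ab, bc)
  nn <- .vnorm(n)
  if (nn < 1e-10) stop("placeAtom: reference atoms a-b-c are collinear")
  n <- n / nn
  m <- .vcross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}
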