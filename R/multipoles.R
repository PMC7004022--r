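#' Real spherical multipole moments of one atom
#'
#' Moments are stored in the real (tesseral) spherical convention with Racah
#' normalisation, component order (l,0), (l,1c), (l,1s), (l,2c), (l,2s).
#' Rank 0 is the atomic charge (e), rank 1 the dipole (e A), rank 2 the
#' quadrupole (e A^2). A frame tag records whether the components refer to
#' the atom's body-fixed local frame or to the global (laboratory) frame.
#'
#' @param charge scalar, e.
#' @param dipole length-3 numeric, order (Q10, Q11c, Q11s) = (mu_z, mu_x,
#'   mu_y), e A.
#' @param quadrupole length-5 numeric, order (Q20, Q21c, Q21s, Q22c, Q22s),
#'   e A^2.
#' @param frame `"local"` or `"global"`.
#' @return An object of class `multipole_set`.
#' @export
multipole_set <- function(charge, dipole = numeric(3), quadrupole = numeric(5),
                          frame = c("local", "global")) {
  frame <- match.arg(frame)
  stopifnot(length(charge) == 1L, length(dipole) == 3L, length(quadrupole) == 5L)
  structure(list(charge = as.numeric(charge),
                 dipole = as.numeric(dipole),
                 quadrupole = as.numeric(quadrupole),
                 frame = frame),
            class = "multipole_set")
}

#' @export
print.multipole_set <- function(x, ...) {
  cat(sprintf("multipole_set [%s frame]\n", x$frame))
  cat(sprintf("  q   = %+ .6f e\n", x$charge))
  cat(sprintf("  Q1m = (% .5f, % .5f, % .5f) e.A  [10,11c,11s]\n",
              x$dipole[1], x$dipole[2], x$dipole[3]))
  cat(sprintf("  Q2m = (% .5f, % .5f, % .5f, % .5f, % .5f) e.A^2\n",
              x$quadrupole[1], x$quadrupole[2], x$quadrupole[3],
              x$quadrupole[4], x$quadrupole[5]))
  invisible(x)
}

# Spherical dipole (Q10, Q11c, Q11s) <-> Cartesian (mu_x, mu_y, mu_z).
.dip_sph_to_cart <- function(d) c(d[2], d[3], d[1])
.dip_cart_to_sph <- function(m) c(m[3], m[1], m[2])

# Spherical quadrupole (Racah) <-> traceless Cartesian tensor
# Theta_ij = integral rho(r) (3 x_i x_j - r^2 delta_ij)/2.
.quad_sph_to_cart <- function(q) {
  s3h <- sqrt(3) / 2
  matrix(c(-q[1] / 2 + s3h * q[4], s3h * q[5],            s3h * q[2],
           s3h * q[5],            -q[1] / 2 - s3h * q[4], s3h * q[3],
           s3h * q[2],             s3h * q[3],            q[1]),
         3, 3, byrow = TRUE)
}

.quad_cart_to_sph <- function(Th) {
  s3 <- sqrt(3)
  c(Th[3, 3],
    2 * Th[1, 3] / s3,
    2 * Th[2, 3] / s3,
    (Th[1, 1] - Th[2, 2]) / s3,
    2 * Th[1, 2] / s3)
}

#' Rotate a multipole set from its local frame to the global frame
#'
#' The charge is invariant, the dipole transforms as a Cartesian vector and
#' the quadrupole by the rank-2 rotation, implemented via the round trip
#' spherical -> traceless Cartesian -> rotate -> spherical (exact; avoids
#' hand-coded Wigner matrices).
#'
#' @param moments a `multipole_set` tagged `"local"`.
#' @param frame a `local_frame` from [build_local_frame()] (or a bare 3 x 3
#'   proper orthogonal matrix mapping local to global).
#' @return A `multipole_set` tagged `"global"`.
#' @export
rotate_multipoles <- function(moments, frame) {
  stopifnot(inherits(moments, "multipole_set"))
  if (moments$frame != "local")
    stop("moments are already in the global frame")
  R <- if (inherits(frame, "local_frame")) frame$rotation else as.matrix(frame)
  .check_rotation(R)
  mu <- R %*% .dip_sph_to_cart(moments$dipole)
  Th <- R %*% .quad_sph_to_cart(moments$quadrupole) %*% t(R)
  multipole_set(moments$charge,
                .dip_cart_to_sph(as.numeric(mu)),
                .quad_cart_to_sph(Th),
                frame = "global")
}

# Per-rank Euclidean norms (rotation invariants).
.multipole_norms <- function(m) {
  c(l0 = abs(m$charge),
    l1 = sqrt(sum(m$dipole^2)),
    l2 = sqrt(sum(m$quadrupole^2)))
}
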