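#' Water monomer configuration
#'
#' A `water_config` holds the Cartesian coordinates (Angstrom) of one water
#' molecule with fixed atom order O, H1, H2.
#'
#' @param positions numeric 3 x 3 matrix; rows are O, H1, H2, columns x, y, z
#'   in Angstrom.
#' @param molecule_id integer identifier carried through sampling and I/O.
#' @return An object of class `water_config`.
#' @examples
#' cfg <- seed_configuration()
#' compute_features(cfg)
#' @export
water_config <- function(positions, molecule_id = 1L) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || any(dim(positions) != c(3L, 3L)))
    stop("positions must be a numeric 3 x 3 matrix (rows O, H1, H2)")
  if (any(!is.finite(positions))) stop("non-finite coordinates")
  dimnames(positions) <- list(c("O", "H1", "H2"), c("x", "y", "z"))
  obj <- structure(list(positions = positions,
                        molecule_id = as.integer(molecule_id)),
                   class = "water_config")
  .validate_config(obj)
  obj
}

.validate_config <- function(config) {
  p <- config$positions
  r1 <- sqrt(sum((p[2, ] - p[1, ])^2))
  r2 <- sqrt(sum((p[3, ] - p[1, ])^2))
  if (r1 <= 0.3 || r2 <= 0.3)
    stop("degenerate geometry: O-H distance must exceed 0.3 A")
  u1 <- (p[2, ] - p[1, ]) / r1
  u2 <- (p[3, ] - p[1, ]) / r2
  cth <- sum(u1 * u2)
  if (cth >= 1 - 1e-12 || cth <= -1 + 1e-12)
    stop("degenerate geometry: H-O-H angle must lie strictly in (0, 180) degrees")
  invisible(config)
}

#' @export
print.water_config <- function(x, ...) {
  f <- compute_features(x)
  cat(sprintf("water_config #%d: r(O-H1) = %.4f A, r(O-H2) = %.4f A, angle = %.2f deg\n",
              x$molecule_id, f[1], f[2], .rad2deg(f[3])))
  invisible(x)
}

#' Equilibrium seed geometry of the water monomer
#'
#' Returns the gas-phase minimum-energy monomer (r = 0.9619 A,
#' theta = 105.05 deg) placed in the xy-plane with the oxygen at the origin
#' and the H-O-H bisector along +x.
#'
#' @param r_eq O-H bond length, Angstrom.
#' @param theta_eq_deg H-O-H angle, degrees.
#' @return A `water_config`.
#' @export
seed_configuration <- function(r_eq = 0.9619, theta_eq_deg = 105.05) {
  half <- .deg2rad(theta_eq_deg) / 2
  p <- rbind(O  = c(0, 0, 0),
             H1 = r_eq * c(cos(half),  sin(half), 0),
             H2 = r_eq * c(cos(half), -sin(half), 0))
  water_config(p)
}

# Coerce one configuration (or a bare 3x3 matrix) to a 3x3 position matrix.
.pos <- function(config) {
  if (inherits(config, "water_config")) config$positions else as.matrix(config)
}

#' Internal-coordinate features of a configuration
#'
#' The feature vector is (r(O-H1), r(O-H2), H-O-H angle): a complete
#' rotation- and translation-invariant coordinate set for a three-atom
#' molecule, used as the input space of every kriging model.
#'
#' @param config a `water_config` (or 3 x 3 position matrix, rows O, H1, H2).
#' @return Numeric length-3 vector `(r1, r2, theta)`; bond lengths in
#'   Angstrom, angle in radians.
#' @export
compute_features <- function(config) {
  p <- .pos(config)
  v1 <- p[2, ] - p[1, ]
  v2 <- p[3, ] - p[1, ]
  r1 <- sqrt(sum(v1^2))
  r2 <- sqrt(sum(v2^2))
  if (r1 <= 0 || r2 <= 0) stop("zero-length O-H bond")
  cth <- sum(v1 * v2) / (r1 * r2)
  if (abs(cth) >= 1 - 1e-12)
    stop("degenerate geometry: atoms collinear")
  c(r1 = r1, r2 = r2, theta = acos(cth))
}

# Vectorised feature map: coords is n x 9 (x,y,z of O, H1, H2 per row).
# Returns n x 3 matrix (r1, r2, theta in radians).
.features_matrix <- function(coords) {
  d1 <- coords[, 4:6, drop = FALSE] - coords[, 1:3, drop = FALSE]
  d2 <- coords[, 7:9, drop = FALSE] - coords[, 1:3, drop = FALSE]
  r1 <- sqrt(rowSums(d1^2))
  r2 <- sqrt(rowSums(d2^2))
  cth <- rowSums(d1 * d2) / (r1 * r2)
  cth <- pmin(1 - 1e-15, pmax(-1 + 1e-15, cth))
  cbind(r1 = r1, r2 = r2, theta = acos(cth))
}

#' Jacobian of the feature map (Wilson B-matrix)
#'
#' Derivatives of the features (r1, r2, theta) with respect to the nine
#' Cartesian coordinates, ordered (O, H1, H2) x (x, y, z).
#'
#' @param config a `water_config` or 3 x 3 position matrix.
#' @return 3 x 9 numeric matrix.
#' @export
feature_jacobian <- function(config) {
  p <- .pos(config)
  v1 <- p[2, ] - p[1, ]
  v2 <- p[3, ] - p[1, ]
  r1 <- sqrt(sum(v1^2)); r2 <- sqrt(sum(v2^2))
  u1 <- v1 / r1; u2 <- v2 / r2
  cth <- sum(u1 * u2)
  sth <- sqrt(max(1 - cth^2, 1e-30))
  B <- matrix(0, 3, 9)
  B[1, 4:6] <- u1; B[1, 1:3] <- -u1
  B[2, 7:9] <- u2; B[2, 1:3] <- -u2
  dth_dH1 <- (cth * u1 - u2) / (r1 * sth)
  dth_dH2 <- (cth * u2 - u1) / (r2 * sth)
  B[3, 4:6] <- dth_dH1
  B[3, 7:9] <- dth_dH2
  B[3, 1:3] <- -(dth_dH1 + dth_dH2)
  B
}

#' Body-fixed local axis frame of an atom
#'
#' Constructs the right-handed orthonormal frame in which that atom's
#' multipole moments are expressed. Convention: for the oxygen atom the
#' x-axis lies along the H-O-H bisector and the z-axis along
#' (O->H1) x (O->H2); for a hydrogen atom the x-axis points from H to O and
#' the z-axis is normal to the molecular plane. The y-axis completes the
#' right-handed set.
#'
#' @param config a `water_config` or 3 x 3 position matrix.
#' @param atom_index 1 (O), 2 (H1) or 3 (H2).
#' @return A `local_frame`: list with `origin` (length 3) and `rotation`
#'   (3 x 3 proper orthogonal matrix whose columns are the local axes in
#'   global coordinates, i.e. it maps local to global).
#' @export
build_local_frame <- function(config, atom_index) {
  p <- .pos(config)
  stopifnot(atom_index %in% 1:3)
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("collinear atoms: local frame undefined")
    v / n
  }
  if (atom_index == 1L) {
    u1 <- unit(p[2, ] - p[1, ])
    u2 <- unit(p[3, ] - p[1, ])
    xax <- unit(u1 + u2)
    zax <- unit(.cross3(u1, u2))
  } else {
    j <- if (atom_index == 2L) 3L else 2L
    xax <- unit(p[1, ] - p[atom_index, ])
    w <- unit(p[j, ] - p[atom_index, ])
    zax <- unit(.cross3(xax, w))
  }
  yax <- .cross3(zax, xax)
  rot <- unname(cbind(xax, yax, zax, deparse.level = 0))
  structure(list(origin = unname(p[atom_index, ]), rotation = rot),
            class = "local_frame")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.check_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)))
    stop("rotation must be a 3 x 3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    stop("rotation matrix is not proper orthogonal")
  invisible(R)
}

#' Read and write (multi-frame) XYZ files
#'
#' Plain XYZ: an atom count line, a comment line, then `element x y z` per
#' atom (Angstrom). Multiple frames are concatenated.
#'
#' @param path file path.
#' @return `read_xyz`: a list of frames, each a list with `elements`
#'   (character) and `coords` (n x 3 matrix). `write_xyz`: invisibly, `path`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    elements <- vapply(toks, `[`, "", 1L)
    coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- list(elements = elements, coords = coords,
                                          comment = comment)
    i <- i + 2L + n
  }
  frames
}

#' @rdname read_xyz
#' @param frames list of frames (`elements`, `coords`, optional `comment`),
#'   or a list of `water_config` objects.
#' @export
write_xyz <- function(frames, path) {
  if (length(frames) && inherits(frames[[1]], "water_config"))
    frames <- lapply(frames, function(cf)
      list(elements = c("O", "H", "H"), coords = cf$positions,
           comment = sprintf("molecule %d", cf$molecule_id)))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(if (is.null(fr$comment)) "" else fr$comment, con)
    writeLines(sprintf("%-2s %16.8f %16.8f %16.8f",
                       fr$elements, fr$coords[, 1], fr$coords[, 2],
                       fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Convert XYZ frames to water configurations
#'
#' Atoms are grouped into molecules as consecutive O, H, H triples.
#'
#' @param frames output of [read_xyz()].
#' @return A list of `water_config` objects (all molecules of all frames).
#' @export
configurations_from_xyz <- function(frames) {
  out <- list()
  for (fr in frames) {
    n <- nrow(fr$coords)
    if (n %% 3L != 0L) stop("frame atom count is not a multiple of 3")
    for (m in seq_len(n / 3L)) {
      idx <- (m - 1L) * 3L + 1:3
      el <- toupper(substr(fr$elements[idx], 1, 1))
      if (!identical(el, c("O", "H", "H")))
        stop("expected consecutive O, H, H triples")
      out[[length(out) + 1L]] <- water_config(fr$coords[idx, , drop = FALSE],
                                              molecule_id = length(out) + 1L)
    }
  }
  out
}

# Stack a list of water_config into an n x 9 coordinate matrix.
.configs_to_coords <- function(configs) {
  t(vapply(configs, function(cf) as.numeric(t(cf$positions)), numeric(9)))
}
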