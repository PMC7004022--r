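#' Multipole interaction pairs admitted at truncation rank L
#'
#' A pair interaction between moments of ranks l_A and l_B contributes at
#' overall rank \eqn{L = l_A + l_B + 1}; the model carries moments up to rank
#' 2 (quadrupole). At L = 3 the admitted interactions are exactly
#' charge-charge, charge-dipole, dipole-charge, charge-quadrupole,
#' quadrupole-charge and dipole-dipole.
#'
#' @param L integer truncation rank, >= 1.
#' @return Data frame with columns `l_A`, `l_B`.
#' @export
admitted_pairs <- function(L) {
  if (length(L) != 1 || !is.finite(L) || L < 1)
    stop("L must be an integer >= 1")
  g <- expand.grid(l_A = 0:2, l_B = 0:2)
  g <- g[g$l_A + g$l_B + 1 <= L, , drop = FALSE]
  g <- g[order(g$l_A + g$l_B, g$l_A), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Cartesian view of a multipole set: charge, dipole vector, traceless
# quadrupole tensor.
.mp_cart <- function(m) {
  list(q = m$charge,
       mu = .dip_sph_to_cart(m$dipole),
       Th = .quad_sph_to_cart(m$quadrupole))
}

# Pair energy in e^2/A^x units (no Coulomb factor), Cartesian moments,
# R vector from A to B. Terms gated by rank pair admission at L.
.pair_energy_cart <- function(qa, mua, Tha, qb, mub, Thb, Rv, L) {
  r2 <- sum(Rv^2)
  r <- sqrt(r2)
  if (r <= 0) stop("zero interatomic separation")
  e <- 0
  if (L >= 1) e <- e + qa * qb / r
  if (L >= 2) e <- e + (-qa * sum(mub * Rv) + qb * sum(mua * Rv)) / r^3
  if (L >= 3) {
    e <- e + sum(mua * mub) / r^3 - 3 * sum(mua * Rv) * sum(mub * Rv) / r^5
    e <- e + (qa * drop(Rv %*% Thb %*% Rv) + qb * drop(Rv %*% Tha %*% Rv)) / r^5
  }
  e
}

#' Spherical-tensor interaction function between two multipole components
#'
#' The coupling T such that the pair energy is
#' \eqn{E = k \sum Q_{l_A m_A} T^{AB}_{l_A m_A, l_B m_B} Q_{l_B m_B}} (k the
#' Coulomb factor). Components are indexed in the order (l,0), (l,1c),
#' (l,1s), (l,2c), (l,2s). Implemented exactly via the Cartesian equivalents
#' of the real spherical moments; scales as \eqn{|R|^{-(l_A+l_B+1)}}.
#'
#' @param l_A,m_A rank and component index (1-based) on atom A.
#' @param l_B,m_B rank and component index on atom B.
#' @param R_vec vector from A to B, Angstrom.
#' @return Tensor value in Angstrom^-(l_A+l_B+1).
#' @export
interaction_tensor <- function(l_A, m_A, l_B, m_B, R_vec) {
  stopifnot(l_A %in% 0:2, l_B %in% 0:2, l_A + l_B <= 2,
            m_A >= 1, m_A <= 2 * l_A + 1, m_B >= 1, m_B <= 2 * l_B + 1)
  if (sum(R_vec^2) <= 0) stop("zero interatomic separation")
  unitm <- function(l, m) {
    q <- 0; d <- numeric(3); Q <- numeric(5)
    if (l == 0) q <- 1 else if (l == 1) d[m] <- 1 else Q[m] <- 1
    multipole_set(q, d, Q, frame = "global")
  }
  A <- .mp_cart(unitm(l_A, m_A))
  B <- .mp_cart(unitm(l_B, m_B))
  # with a single nonzero rank on each atom, every term of other ranks
  # vanishes, so the full pair energy at L = l_A + l_B + 1 is exactly T
  .pair_energy_cart(A$q, A$mu, A$Th, B$q, B$mu, B$Th, R_vec,
                    L = l_A + l_B + 1)
}

#' Electrostatic energy of one atom pair from spherical multipole moments
#'
#' Evaluates \eqn{E^{AB}_{elec} = k \sum_{l_A l_B m_A m_B}
#' Q_{l_A m_A} T Q_{l_B m_B}} over the rank pairs admitted at truncation L,
#' with k the Coulomb factor 1389.35457644 kJ/mol A/e^2.
#'
#' @param Q_A,Q_B global-frame [multipole_set()]s.
#' @param R_vec vector from atom A to atom B, Angstrom.
#' @param L truncation rank (1, 2 or 3).
#' @return Energy in kJ/mol.
#' @export
pair_electrostatic_energy <- function(Q_A, Q_B, R_vec, L) {
  stopifnot(inherits(Q_A, "multipole_set"), inherits(Q_B, "multipole_set"))
  if (Q_A$frame != "global" || Q_B$frame != "global")
    stop("moments must be rotated to the global frame first")
  admitted_pairs(L)  # validates L
  A <- .mp_cart(Q_A); B <- .mp_cart(Q_B)
  .kw_coulomb * .pair_energy_cart(A$q, A$mu, A$Th, B$q, B$mu, B$Th, R_vec, L)
}

# Vectorised pair electrostatics over a cluster.
#
# pos: natoms x 3; mol: molecule index per atom; q: charges; MU: natoms x 3
# global Cartesian dipoles; TH: natoms x 9 global traceless quadrupoles
# (column-major 3x3 per row). Returns energy (kJ/mol), forces (natoms x 3,
# moments held fixed) and, if want_grads, the energy gradients with respect
# to each atom's global moments (gq, gmu, gTh).
.elec_pairs <- function(pos, mol, q, MU, TH, L, cutoff = 30,
                        want_grads = FALSE) {
  natoms <- nrow(pos)
  ij <- which(upper.tri(matrix(0, natoms, natoms)), arr.ind = TRUE)
  a <- ij[, 1]; b <- ij[, 2]
  keep <- mol[a] != mol[b]
  a <- a[keep]; b <- b[keep]
  zero <- list(energy = 0, forces = matrix(0, natoms, 3),
               gq = numeric(natoms), gmu = matrix(0, natoms, 3),
               gTh = matrix(0, natoms, 9))
  if (!length(a)) return(zero)
  Rv <- pos[b, , drop = FALSE] - pos[a, , drop = FALSE]
  r2 <- rowSums(Rv^2)
  keep <- r2 <= cutoff^2
  a <- a[keep]; b <- b[keep]; Rv <- Rv[keep, , drop = FALSE]
  r2 <- r2[keep]
  if (!length(a)) return(zero)
  r <- sqrt(r2); r3 <- r * r2; r5 <- r3 * r2; r7 <- r5 * r2
  qa <- q[a]; qb <- q[b]
  np <- length(a)
  E <- qa * qb / r
  dE <- -(qa * qb / r3) * Rv                     # gradient wrt Rv
  gq_a <- qb / r; gq_b <- qa / r
  gmu_a <- matrix(0, np, 3); gmu_b <- matrix(0, np, 3)
  gTh_a <- matrix(0, np, 9); gTh_b <- matrix(0, np, 9)
  if (L >= 2) {
    mua <- MU[a, , drop = FALSE]; mub <- MU[b, , drop = FALSE]
    muaR <- rowSums(mua * Rv); mubR <- rowSums(mub * Rv)
    E <- E + (-qa * mubR + qb * muaR) / r3
    dE <- dE + (-qa / r3) * mub + (3 * qa * mubR / r5) * Rv +
      (qb / r3) * mua - (3 * qb * muaR / r5) * Rv
    gq_a <- gq_a - mubR / r3
    gq_b <- gq_b + muaR / r3
    gmu_a <- gmu_a + (qb / r3) * Rv
    gmu_b <- gmu_b - (qa / r3) * Rv
    if (L >= 3) {
      mumu <- rowSums(mua * mub)
      E <- E + mumu / r3 - 3 * muaR * mubR / r5
      dE <- dE - (3 * mumu / r5) * Rv -
        (3 / r5) * (mubR * mua + muaR * mub) +
        (15 * muaR * mubR / r7) * Rv
      gmu_a <- gmu_a + mub / r3 - (3 * mubR / r5) * Rv
      gmu_b <- gmu_b + mua / r3 - (3 * muaR / r5) * Rv
      # charge-quadrupole terms; TH rows are vec(3x3)
      ThR_b <- .th_times_vec(TH[b, , drop = FALSE], Rv)
      ThR_a <- .th_times_vec(TH[a, , drop = FALSE], Rv)
      RThR_b <- rowSums(Rv * ThR_b)
      RThR_a <- rowSums(Rv * ThR_a)
      E <- E + (qa * RThR_b + qb * RThR_a) / r5
      dE <- dE + (2 * qa / r5) * ThR_b - (5 * qa * RThR_b / r7) * Rv +
        (2 * qb / r5) * ThR_a - (5 * qb * RThR_a / r7) * Rv
      gq_a <- gq_a + RThR_b / r5
      gq_b <- gq_b + RThR_a / r5
      RR <- .vec_outer(Rv)
      gTh_a <- gTh_a + (qb / r5) * RR
      gTh_b <- gTh_b + (qa / r5) * RR
    }
  }
  k <- .kw_coulomb
  # scatter-add pair quantities onto atoms
  acc <- function(M, idx, V) {
    S <- rowsum(V, idx, reorder = FALSE)
    rows <- as.integer(rownames(S))
    M[rows, ] <- M[rows, , drop = FALSE] + S
    M
  }
  # force on a = +dE/dRv, on b = -dE/dRv (Rv = x_b - x_a), times Coulomb k
  forces <- matrix(0, natoms, 3)
  forces <- acc(forces, a, k * dE)
  forces <- acc(forces, b, -k * dE)
  out <- list(energy = k * sum(E), forces = forces)
  if (want_grads) {
    gq <- matrix(0, natoms, 1)
    gq <- acc(acc(gq, a, cbind(gq_a)), b, cbind(gq_b))
    out$gq <- k * as.numeric(gq)
    out$gmu <- k * acc(acc(matrix(0, natoms, 3), a, gmu_a), b, gmu_b)
    out$gTh <- k * acc(acc(matrix(0, natoms, 9), a, gTh_a), b, gTh_b)
  }
  out
}

# rowwise Theta %*% v for TH stored as natoms x 9 (column-major 3x3 rows).
.th_times_vec <- function(TH, V) {
  cbind(TH[, 1] * V[, 1] + TH[, 4] * V[, 2] + TH[, 7] * V[, 3],
        TH[, 2] * V[, 1] + TH[, 5] * V[, 2] + TH[, 8] * V[, 3],
        TH[, 3] * V[, 1] + TH[, 6] * V[, 2] + TH[, 9] * V[, 3])
}

# rowwise outer products v v', flattened column-major.
.vec_outer <- function(V) {
  cbind(V[, 1] * V[, 1], V[, 2] * V[, 1], V[, 3] * V[, 1],
        V[, 1] * V[, 2], V[, 2] * V[, 2], V[, 3] * V[, 2],
        V[, 1] * V[, 3], V[, 2] * V[, 3], V[, 3] * V[, 3])
}

#' Total electrostatic energy of a cluster
#'
#' Direct-space sum of [pair_electrostatic_energy()] over all intermolecular
#' atom pairs within the cutoff (intramolecular pairs are excluded: the
#' intramolecular physics lives in the atomic-energy models). Nonperiodic.
#'
#' @param positions natoms x 3 matrix, Angstrom, atoms ordered O, H1, H2 per
#'   molecule.
#' @param moments list of global-frame [multipole_set()]s, one per atom.
#' @param L truncation rank (1, 2 or 3).
#' @param cutoff pair cutoff on nuclear separation, Angstrom (default 30).
#' @param molecule optional molecule index per atom; default consecutive
#'   O,H,H triples.
#' @return Energy in kJ/mol.
#' @export
total_electrostatic_energy <- function(positions, moments, L, cutoff = 30,
                                       molecule = NULL) {
  positions <- as.matrix(positions)
  natoms <- nrow(positions)
  stopifnot(length(moments) == natoms)
  if (is.null(molecule)) molecule <- rep(seq_len(natoms / 3), each = 3)
  if (any(vapply(moments, function(m) m$frame, "") != "global"))
    stop("moments must be rotated to the global frame first")
  q <- vapply(moments, `[[`, 0, "charge")
  MU <- t(vapply(moments, function(m) .dip_sph_to_cart(m$dipole), numeric(3)))
  TH <- t(vapply(moments, function(m)
    as.numeric(.quad_sph_to_cart(m$quadrupole)), numeric(9)))
  .elec_pairs(positions, molecule, q, MU, TH, L, cutoff)$energy
}
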