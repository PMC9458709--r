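# Independent oracles and small builders used across the suite.

# Horn quaternion-based optimal superposition RMSD: independent of the
# SVD/Kabsch route in the package.
quaternion_rmsd <- function(P, Q) {
  Pc <- scale(P, scale = FALSE)
  Qc <- scale(Q, scale = FALSE)
  M <- t(Pc) %*% Qc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  sqrt(max(0, sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Apply a rigid transform to all atoms of a structure.
transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + t[1]
  s$atoms$y <- xyz[, 2] + t[2]
  s$atoms$z <- xyz[, 3] + t[3]
  s
}

# Brute-force numerical convolution of exp(-u/tau)/tau-free decay with a
# Gaussian IRF, by adaptive quadrature; oracle for the closed-form model.
quadrature_decay <- function(t, tau, mu, sigma) {
  vapply(t, function(ti) {
    tm <- ti - mu
    lo <- max(0, tm - 12 * sigma)
    hi <- max(tm + 12 * sigma, lo + sigma)
    stats::integrate(function(u) exp(-u / tau) *
                       stats::dnorm(tm - u, sd = sigma),
                     lower = lo, upper = hi, rel.tol = 1e-12,
                     abs.tol = 0)$value
  }, numeric(1))
}

# Quartet with a prescribed torsion angle (degrees): A and D hang off the
# B-C axis; D is rotated by `angle` about that axis from the A half-plane.
quartet_with_torsion <- function(angle_deg) {
  th <- angle_deg * pi / 180
  rbind(c(-0.5, 1.0, 0),
        c(0, 0, 0),
        c(1.5, 0, 0),
        c(2.0, cos(th), sin(th)))
}

toy_sites <- function(traj) classify_pockets(traj$topology)

# Single alpha-beta monomer with one buried bilin, cut out of the toy trimer.
toy_single_monomer <- function() {
  s <- build_toy_trimer()
  keep <- s$atoms$chain %in% c("A", "B") &
    !(s$atoms$het & s$atoms$chain == "A")      # drop the interface bilin
  phycofret:::new_structure(s$atoms[keep, , drop = FALSE], "toy-monomer")
}
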