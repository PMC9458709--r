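## Seeded synthetic generators: a C3-symmetric pseudo-trimer, two-state
## (apo / CO2-bound) trajectories with Gaussian positional fluctuation, and
## TCSPC / transient-absorption traces from the decay model.
##
## The pseudo-trimer is a schematic of an (alpha-beta)3 ring: six minimal
## protein chains (A+B, C+D, E+F forming three monomers), six pseudo-bilins
## (4 collinear heavy atoms 1.4 A apart) of which three sit in monomeric
## pockets and three in interface pockets, and per alpha chain a K6/D100
## lysine-aspartate pair at the formed salt-bridge distance.

#' Specification for a synthetic two-state trajectory
#'
#' @param state \code{"apo"} (all three monomer-interface pair distances at
#'   their common mean, salt bridge formed) or \code{"co2"} (one designated
#'   pair contracted, that monomer's K6-D100 salt bridge broken).
#' @param n_frames Number of frames (default 2000).
#' @param frame_spacing Frame spacing, ps (default 10).
#' @param pair_means Mean distances of the three designated pairs, Angstrom.
#'   Defaults: apo c(24.5, 24.5, 24.5); co2 c(22.0, 24.5, 24.5).
#' @param fluctuation_sigma Isotropic Gaussian positional fluctuation of
#'   each chromophore, per coordinate, Angstrom (default 0.4).
#' @param salt_bridge Named vector \code{c(formed = , broken = )} of NZ-O
#'   distances, Angstrom (defaults 2.8 and 8.0).
#' @param shifted_pair Index (1-3) of the pair carrying the co2 contraction.
#' @param ar1 Optional AR(1) autocorrelation of the fluctuations (default 0,
#'   i.e. frame-independent noise).
#' @param seed Integer seed; identical specs give identical trajectories.
#' @return List of class \code{"trajectory_spec"}.
#' @export
trajectory_spec <- function(state = c("apo", "co2"), n_frames = 2000,
                            frame_spacing = 10, pair_means = NULL,
                            fluctuation_sigma = 0.4,
                            salt_bridge = c(formed = 2.8, broken = 8.0),
                            shifted_pair = 1, ar1 = 0, seed = 1) {
  state <- match.arg(state)
  pair_means <- pair_means %||%
    (if (state == "apo") rep(24.5, 3) else { p <- rep(24.5, 3); p[shifted_pair] <- 22.0; p })
  stopifnot(n_frames >= 1, frame_spacing > 0, fluctuation_sigma >= 0,
            length(pair_means) == 3, all(pair_means > 0),
            shifted_pair %in% 1:3, abs(ar1) < 1)
  structure(list(state = state, n_frames = as.integer(n_frames),
                 frame_spacing = frame_spacing, pair_means = pair_means,
                 fluctuation_sigma = fluctuation_sigma,
                 salt_bridge = salt_bridge, shifted_pair = shifted_pair,
                 ar1 = ar1, seed = seed),
            class = "trajectory_spec")
}

## --- toy trimer geometry -------------------------------------------------
## Ring of three monomers at 0/120/240 deg. Monomer-pocket bilin M_k at
## angle theta_k, interface bilin I_k at theta_k + 70 deg, both on a ring of
## radius R chosen so the designated pair distance |I_k - M_(k+1)| (50 deg
## chord) equals the 24.5 A base; pair-specific means are applied as
## symmetric shifts along the pair axis. K6/D100 sit far outside the
## pockets so they never enter the contact classification.

TOY_BASE_DISTANCE <- 24.5

toy_ring_radius <- function() TOY_BASE_DISTANCE / (2 * sin(25 * pi / 180))

toy_unit <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
toy_tang <- function(deg) c(-sin(deg * pi / 180), cos(deg * pi / 180), 0)

## rows of a minimal 5-atom alanine-like residue around point P
toy_ala <- function(chain, resno, P) {
  off <- rbind(N = c(-1.23, 0.50, 0), CA = c(0, 0, 0), C = c(1.20, 0.50, 0),
               O = c(1.90, -0.50, 0.40), CB = c(0, -0.80, 1.20))
  data.frame(elety = rownames(off), elesy = c("N", "C", "C", "O", "C"),
             resid = "ALA", resno = resno, chain = chain,
             x = P[1] + off[, 1], y = P[2] + off[, 2], z = P[3] + off[, 3],
             het = FALSE, stringsAsFactors = FALSE)
}

## lysine (resno 6) + aspartate (resno 100) pair in a local frame at G with
## axes (ex, ey, ez); planar all-anti side chain, OD1 at `formed` from NZ
toy_k6_d100 <- function(chain, G, ex, ey, ez, formed) {
  place <- function(l) G + l[1] * ex + l[2] * ey + l[3] * ez
  lys <- rbind(N = c(-1.24, 0.90, 0), CA = c(0, 0, 0), C = c(-0.40, -1.20, 0.60),
               O = c(-1.40, -1.70, 0.90), CB = c(1.24, 0.90, 0),
               CG = c(2.48, 0, 0), CD = c(3.72, 0.90, 0),
               CE = c(4.96, 0, 0), NZ = c(6.20, 0.90, 0))
  od1 <- c(6.20 + formed, 0.90, 0)
  asp <- rbind(OD1 = od1, CG = od1 + c(0.90, 0.90, 0),
               OD2 = od1 + c(2.00, 0.30, 0), CB = od1 + c(0.90, 2.40, 0),
               CA = od1 + c(2.10, 3.10, 0), N = od1 + c(3.30, 2.50, 0),
               C = od1 + c(2.30, 4.60, 0), O = od1 + c(3.30, 5.20, 0))
  xyz <- rbind(lys, asp)
  pts <- t(apply(xyz, 1, place))
  data.frame(elety = rownames(xyz),
             elesy = substr(rownames(xyz), 1, 1),
             resid = rep(c("LYS", "ASP"), c(nrow(lys), nrow(asp))),
             resno = rep(c(6L, 100L), c(nrow(lys), nrow(asp))),
             chain = chain, x = pts[, 1], y = pts[, 2], z = pts[, 3],
             het = FALSE, stringsAsFactors = FALSE)
}

toy_bilin <- function(chain, resno, center, axis) {
  off <- c(-2.1, -0.7, 0.7, 2.1)
  data.frame(elety = c("N1", "C2", "C3", "N4"),
             elesy = c("N", "C", "C", "N"), resid = "BLA", resno = resno,
             chain = chain,
             x = center[1] + off * axis[1], y = center[2] + off * axis[2],
             z = center[3] + off * axis[3], het = TRUE,
             stringsAsFactors = FALSE)
}

## Mean-geometry atom table for a state: base C3 trimer, then pair-specific
## symmetric shifts along each designated pair axis, then (co2) the broken
## salt bridge on the alpha chain hosting the shifted interface site.
toy_mean_atoms <- function(spec) {
  R <- toy_ring_radius()
  alpha <- c("A", "C", "E"); beta <- c("B", "D", "F")
  rows <- list()
  for (k in 0:2) {
    th <- 120 * k
    cm <- R * toy_unit(th)            # monomer-pocket bilin centre
    ci <- R * toy_unit(th + 70)       # interface bilin centre
    ci_prev <- R * toy_unit(th - 120 + 70)
    a <- alpha[k + 1]; b <- beta[k + 1]
    G <- 40 * toy_unit(th + 100) + c(0, 0, 6)
    rows[[length(rows) + 1]] <- toy_k6_d100(
      a, G, toy_tang(th + 100), toy_unit(th + 100), c(0, 0, 1),
      spec$salt_bridge[["formed"]])
    rows[[length(rows) + 1]] <- toy_ala(a, 50L, cm + c(0, 0, 3.0))
    rows[[length(rows) + 1]] <- toy_ala(a, 60L, ci + c(0, 0, 3.0))
    rows[[length(rows) + 1]] <- toy_ala(a, 61L, ci_prev - c(0, 0, 3.0))
    rows[[length(rows) + 1]] <- toy_bilin(a, 202L, ci, toy_tang(th + 70))
    rows[[length(rows) + 1]] <- toy_ala(b, 50L, cm - c(0, 0, 3.0))
    rows[[length(rows) + 1]] <- toy_ala(b, 60L, ci + 3.0 * toy_unit(th + 70))
    rows[[length(rows) + 1]] <- toy_bilin(b, 201L, cm, toy_tang(th))
  }
  at <- do.call(rbind, rows)
  at <- at[order(match(at$chain, LETTERS)), , drop = FALSE]
  rownames(at) <- NULL

  ## designated pair p: interface bilin of monomer p-1 (chain alpha[p]) and
  ## monomer bilin of monomer p (chain beta[(p %% 3) + 1])
  for (p in 1:3) {
    target <- spec$pair_means[p]
    if (abs(target - TOY_BASE_DISTANCE) < 1e-12) next
    ia <- which(at$chain == alpha[p] & at$resno == 202L & at$het)
    ma <- which(at$chain == beta[(p %% 3) + 1] & at$resno == 201L & at$het)
    ci <- colMeans(at[ia, c("x", "y", "z")])
    cm <- colMeans(at[ma, c("x", "y", "z")])
    axis <- unit(cm - ci)
    half <- (TOY_BASE_DISTANCE - target) / 2
    at[ia, c("x", "y", "z")] <- sweep(as.matrix(at[ia, c("x", "y", "z")]), 2,
                                      half * axis, "+")
    at[ma, c("x", "y", "z")] <- sweep(as.matrix(at[ma, c("x", "y", "z")]), 2,
                                      half * axis, "-")
  }

  if (spec$state == "co2") {
    ch <- alpha[spec$shifted_pair]
    nz <- which(at$chain == ch & at$resno == 6L & at$elety == "NZ")
    f <- spec$salt_bridge[["formed"]]; b <- spec$salt_bridge[["broken"]]
    at[nz, "z"] <- at[nz, "z"] + sqrt(max(b^2 - f^2, 0))
  }
  at
}

#' Build the C3-symmetric pseudo-trimer
#'
#' Constructs the minimal six-chain, six-chromophore trimer described above
#' at the mean geometry of the spec's state (zero fluctuation). The
#' structure passes the trimer invariants, classifies into 3 monomer + 3
#' interface pockets at the default contact cutoff, and carries a K6/D100
#' salt-bridge pair on every alpha chain.
#'
#' @param spec A \code{\link{trajectory_spec}} (default apo).
#' @return An \code{"apc_structure"}.
#' @export
build_toy_trimer <- function(spec = trajectory_spec()) {
  stopifnot(inherits(spec, "trajectory_spec"))
  new_structure(toy_mean_atoms(spec), assembly = paste0("toy-trimer-", spec$state))
}

#' Simulate a two-state pseudo-trimer trajectory
#'
#' Frames are the state's mean geometry with each chromophore group rigidly
#' displaced by a seeded isotropic Gaussian (sd \code{fluctuation_sigma} per
#' coordinate, optionally AR(1)-correlated in time); protein atoms are held
#' fixed. The topology is always the apo mean geometry, so RMSD against the
#' topology reads out the co2-state rearrangement. Deterministic given the
#' spec (seed included).
#'
#' @param spec A \code{\link{trajectory_spec}}.
#' @return An \code{"apc_trajectory"}.
#' @examples
#' tr <- simulate_trajectory(trajectory_spec(n_frames = 5, seed = 42))
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  topo_spec <- spec
  topo_spec$state <- "apo"
  topo_spec$pair_means <- rep(TOY_BASE_DISTANCE, 3)
  topo <- build_toy_trimer(topo_spec)
  mean_at <- toy_mean_atoms(spec)
  mean_vec <- as.vector(t(as.matrix(mean_at[, c("x", "y", "z")])))
  nf <- spec$n_frames
  xyz <- matrix(mean_vec, nrow = nf, ncol = length(mean_vec), byrow = TRUE)
  if (spec$fluctuation_sigma > 0) {
    groups <- hetero_groups(topo)
    disp <- with_seed(spec$seed, lapply(seq_along(groups), function(g) {
      e <- matrix(stats::rnorm(nf * 3, sd = spec$fluctuation_sigma), nf, 3)
      if (spec$ar1 != 0) {
        phi <- spec$ar1
        e <- apply(e * sqrt(1 - phi^2), 2, function(col)
          as.numeric(stats::filter(col, phi, method = "recursive",
                                   init = col[1] / sqrt(1 - phi^2))))
        e <- matrix(e, nf, 3)
      }
      e
    }))
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      for (ax in 1:3)
        xyz[, 3 * (idx - 1) + ax] <- xyz[, 3 * (idx - 1) + ax] + disp[[g]][, ax]
    }
  }
  new_trajectory(topo, xyz, spec$frame_spacing)
}

#' Specification for a synthetic decay or transient trace
#'
#' @param components List of \code{c(fraction, lifetime_ps)} pairs (or a
#'   two-column data frame); amplitude fractions must sum to 1.
#' @param irf_fwhm Gaussian IRF FWHM, ps.
#' @param irf_center IRF centre, ps; default 3 x FWHM so the full rise is
#'   on-axis (use 0 with a negative \code{t_min} for pump-probe traces).
#' @param n_channels Number of channels / delay points.
#' @param channel_width Channel width, ps.
#' @param t_min Time-axis origin, ps (default 0).
#' @param total_counts Total expected signal counts over the axis (TCSPC
#'   scaling; ignored by \code{simulate_transient}).
#' @param background Constant background per channel (counts, or signal
#'   units for transients).
#' @param noise \code{"poisson"}, \code{"gaussian"}, or \code{"none"}.
#' @param noise_sigma Gaussian noise sd as a fraction of the peak signal
#'   (default 0.01).
#' @param seed Integer seed.
#' @return List of class \code{"decay_spec"}.
#' @export
decay_spec <- function(components = list(c(0.82, 164), c(0.18, 410)),
                       irf_fwhm = 200, irf_center = NULL, n_channels = 4096,
                       channel_width = 2, t_min = 0, total_counts = 1e6,
                       background = 0, noise = c("poisson", "gaussian", "none"),
                       noise_sigma = 0.01, seed = 1) {
  noise <- match.arg(noise)
  if (is.data.frame(components))
    components <- lapply(seq_len(nrow(components)),
                         function(i) as.numeric(components[i, 1:2]))
  fr <- vapply(components, `[`, numeric(1), 1)
  tau <- vapply(components, `[`, numeric(1), 2)
  if (abs(sum(fr) - 1) > 1e-9) stop("amplitude fractions must sum to 1")
  if (any(tau <= 0)) stop("lifetimes must be > 0")
  stopifnot(n_channels >= 2, channel_width > 0, total_counts > 0,
            irf_fwhm >= 0, noise_sigma >= 0)
  structure(list(fractions = fr, lifetimes = tau, irf_fwhm = irf_fwhm,
                 irf_center = irf_center %||% (3 * irf_fwhm),
                 n_channels = as.integer(n_channels),
                 channel_width = channel_width, t_min = t_min,
                 total_counts = total_counts, background = background,
                 noise = noise, noise_sigma = noise_sigma, seed = seed),
            class = "decay_spec")
}

decay_spec_axis <- function(spec)
  spec$t_min + (seq_len(spec$n_channels) - 1) * spec$channel_width

#' Simulate a TCSPC decay histogram
#'
#' Expected curve from the IRF-convolved multi-exponential model, scaled so
#' its channel sum equals \code{total_counts}, plus background, with noise
#' applied per the spec (seeded Poisson draws by default).
#'
#' @param spec A \code{\link{decay_spec}}.
#' @return Data frame with \code{time_ps} and \code{counts}; the spec, the
#'   noiseless expectation and the IRF centre are attached as attributes
#'   (\code{"spec"}, \code{"expected"}, \code{"irf_center"}).
#' @export
simulate_decay <- function(spec) {
  stopifnot(inherits(spec, "decay_spec"))
  t <- decay_spec_axis(spec)
  m <- decay_model(spec$fractions, spec$lifetimes, spec$irf_fwhm,
                   spec$irf_center, background = 0)
  curve <- model_decay(m, t)
  expected <- curve * (spec$total_counts / sum(curve)) + spec$background
  counts <- switch(spec$noise,
    none = expected,
    poisson = with_seed(spec$seed, stats::rpois(length(expected), expected)),
    gaussian = with_seed(spec$seed,
      expected + stats::rnorm(length(expected),
                              sd = spec$noise_sigma * max(expected))))
  out <- data.frame(time_ps = t, counts = counts)
  attr(out, "spec") <- spec
  attr(out, "expected") <- expected
  attr(out, "irf_center") <- spec$irf_center
  out
}

#' Simulate a transient-absorption trace
#'
#' Real-valued delta-transmission trace: amplitude fractions times the
#' IRF-convolved exponentials (stimulated emission positive), plus seeded
#' Gaussian noise scaled to the peak.
#'
#' @param spec A \code{\link{decay_spec}} with ps-scale channel widths; use
#'   \code{noise = "gaussian"} and a negative \code{t_min} with
#'   \code{irf_center = 0} for the usual pump-probe axis.
#' @return Data frame with \code{time_ps} and \code{dT}; spec and noiseless
#'   expectation attached as attributes.
#' @export
simulate_transient <- function(spec) {
  stopifnot(inherits(spec, "decay_spec"))
  t <- decay_spec_axis(spec)
  m <- decay_model(spec$fractions, spec$lifetimes, spec$irf_fwhm,
                   spec$irf_center, background = spec$background)
  expected <- model_decay(m, t)
  dT <- if (spec$noise == "none") expected else
    with_seed(spec$seed,
              expected + stats::rnorm(length(expected),
                                      sd = spec$noise_sigma * max(expected)))
  out <- data.frame(time_ps = t, dT = dT)
  attr(out, "spec") <- spec
  attr(out, "expected") <- expected
  attr(out, "irf_center") <- spec$irf_center
  out
}
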