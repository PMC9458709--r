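## Trajectory-derived geometric observables: RMSD series, side-chain
## rotamers, contact frequencies, salt bridges, inter-chromophore distances.

resolve_window <- function(traj, window) {
  n <- n_frames(traj)
  if (is.null(window)) {
    ## default equilibration window: final 30% of frames
    w <- seq.int(max(1L, floor(0.7 * n) + 1L), n)
  } else {
    w <- as.integer(window)
    if (length(w) == 2 && w[2] > w[1] + 1) w <- seq.int(w[1], w[2])
    if (length(w) == 0) stop("empty frame window")
    if (any(w < 1 | w > n)) stop("window outside trajectory (1..", n, ")")
  }
  w
}

#' Per-frame RMSD against a reference structure
#'
#' Each frame is least-squares superposed (proper rotation, Kabsch) onto the
#' reference over the selected atoms, and the post-fit RMSD reported, as in
#' standard trajectory RMSD-vs-initial-state analyses.
#'
#' @param traj An \code{"apc_trajectory"}.
#' @param reference Reference structure; default the trajectory topology.
#' @param selection Atom selection (see \code{\link{superpose}}).
#' @param fit Superpose each frame before measuring (default TRUE); with
#'   \code{fit = FALSE} the raw coordinate RMSD is reported.
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL, selection = "all", fit = TRUE) {
  reference <- reference %||% traj$topology
  sel <- resolve_selection(traj$topology$atoms, selection)
  if (length(sel) == 0) stop("empty atom selection")
  ref <- as.matrix(reference$atoms[sel, c("x", "y", "z"), drop = FALSE])
  vapply(seq_len(n_frames(traj)), function(i) {
    P <- frame_coords(traj, i)[sel, , drop = FALSE]
    if (fit) kabsch_fit(P, ref)$rmsd
    else sqrt(mean(rowSums((P - ref)^2)))
  }, numeric(1))
}

## Signed torsion angle (degrees, IUPAC convention, range (-180, 180]) for
## coordinate matrices of the four atoms, one row per frame.
torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m  <- sqrt(rowSums(b2^2))
  y <- m * rowSums(b1 * n2)
  x <- rowSums(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

## g+ = (0,120], t = (120,180] u (-180,-120], g- = (-120,0]
chi_state <- function(chi) {
  ifelse(chi > 0 & chi <= 120, "g+",
         ifelse(chi > 120 | chi <= -120, "t", "g-"))
}

lysine_chi_quartets <- list(
  chi1 = c("N", "CA", "CB", "CG"),
  chi2 = c("CA", "CB", "CG", "CD"),
  chi3 = c("CB", "CG", "CD", "CE"),
  chi4 = c("CG", "CD", "CE", "NZ"))

#' Side-chain chi dihedrals and rotamer states of a lysine
#'
#' Computes the four side-chain torsions chi1..chi4 (N-CA-CB-CG, CA-CB-CG-CD,
#' CB-CG-CD-CE, CG-CD-CE-NZ) for every frame and assigns each frame a
#' discrete rotamer label from the standard tercile bins: g+ for chi in
#' (0, 120], t for (120, 180] or (-180, -120], g- for (-120, 0]. The label
#' is the tuple over chi1..chi4 (e.g. \code{"g+|t|t|t"}).
#'
#' @param traj An \code{"apc_trajectory"}.
#' @param chain,resno Residue identity (author numbering, e.g. K6).
#' @return A list of class \code{"rotamer_series"}: \code{chi} (frames x 4
#'   matrix, degrees in (-180, 180]), \code{states} (per-frame label),
#'   \code{occupancy} (named fractions summing to 1), \code{residue}.
#' @export
chi_dihedrals <- function(traj, chain, resno) {
  a <- traj$topology$atoms
  rsel <- which(!a$het & a$chain == chain & a$resno == resno)
  if (length(rsel) == 0) stop("residue ", chain, "/", resno, " not found")
  atom_at <- function(name) {
    i <- rsel[a$elety[rsel] == name]
    if (length(i) != 1)
      stop("missing side-chain atom '", name, "' in residue ", chain, "/", resno)
    i
  }
  chi <- sapply(lysine_chi_quartets, function(q) {
    idx <- vapply(q, atom_at, integer(1))
    cols <- function(i) traj$xyz[, c(3 * i - 2, 3 * i - 1, 3 * i), drop = FALSE]
    torsion_deg(cols(idx[1]), cols(idx[2]), cols(idx[3]), cols(idx[4]))
  })
  if (is.null(dim(chi))) chi <- matrix(chi, nrow = 1,
                                       dimnames = list(NULL, names(lysine_chi_quartets)))
  states <- apply(chi, 1, function(r) paste(chi_state(r), collapse = "|"))
  occ <- table(states) / length(states)
  structure(list(chi = chi, states = states,
                 occupancy = stats::setNames(as.numeric(occ), names(occ)),
                 residue = list(chain = chain, resno = resno)),
            class = "rotamer_series")
}

#' @export
print.rotamer_series <- function(x, ...) {
  cat("rotamer_series for", x$residue$chain, x$residue$resno, "over",
      nrow(x$chi), "frames\n")
  occ <- sort(x$occupancy, decreasing = TRUE)
  for (i in seq_along(occ))
    cat(sprintf("  %-12s %.3f\n", names(occ)[i], occ[i]))
  invisible(x)
}

#' Per-residue contact frequency with a chromophore
#'
#' For each protein residue, the fraction of window frames in which any of
#' its heavy atoms lies within \code{cutoff} of any heavy atom of the
#' chromophore.
#'
#' @param traj An \code{"apc_trajectory"}.
#' @param site One row of a \code{"chromophore_sites"} table (subset with
#'   \code{sites[i, ]}) or a site_id string.
#' @param sites The full \code{"chromophore_sites"} table (needed when
#'   \code{site} is given as an id, to recover atom indices).
#' @param window Frame window; default the final 30% of frames.
#' @param cutoff Heavy-atom contact cutoff, Angstrom (default 4.0).
#' @return Data frame of class \code{"contact_map"}: \code{chain},
#'   \code{resno}, \code{resid}, \code{frequency} in [0, 1].
#' @export
contact_frequency <- function(traj, site, sites = NULL, window = NULL,
                              cutoff = 4.0) {
  stopifnot(cutoff > 0)
  w <- resolve_window(traj, window)
  a <- traj$topology$atoms
  cidx <- site_atom_idx(site, sites)
  cidx <- cidx[a$elesy[cidx] != "H"]
  prot <- which(!a$het & a$elesy != "H")
  rkey <- paste(a$chain[prot], a$resno[prot], a$resid[prot])
  rfac <- factor(rkey, levels = unique(rkey))
  hits <- numeric(nlevels(rfac))
  for (f in w) {
    m <- frame_coords(traj, f)
    cx <- m[cidx, , drop = FALSE]
    d2min <- rep(Inf, length(prot))
    for (k in seq_len(nrow(cx)))
      d2min <- pmin(d2min, (m[prot, 1] - cx[k, 1])^2 +
                            (m[prot, 2] - cx[k, 2])^2 +
                            (m[prot, 3] - cx[k, 3])^2)
    inc <- tapply(d2min <= cutoff^2, rfac, any)
    hits <- hits + as.numeric(inc)
  }
  lev1 <- match(levels(rfac), rkey)
  out <- data.frame(chain = a$chain[prot][lev1], resno = a$resno[prot][lev1],
                    resid = a$resid[prot][lev1],
                    frequency = hits / length(w), stringsAsFactors = FALSE)
  class(out) <- c("contact_map", "data.frame")
  attr(out, "cutoff") <- cutoff
  attr(out, "window") <- range(w)
  out
}

site_atom_idx <- function(site, sites = NULL) {
  if (is.character(site)) {
    if (is.null(sites)) stop("supply `sites` when identifying a site by id")
    i <- match(site, sites$site_id)
    if (is.na(i)) stop("unknown site_id: ", site)
    return(attr(sites, "atom_idx")[[i]])
  }
  idx <- attr(site, "atom_idx")
  if (is.null(idx)) stop("site carries no atom indices; pass sites[i, ] or an id")
  if (is.list(idx)) {
    if (length(idx) != 1) stop("pass a single site (one row), not ", length(idx))
    idx <- idx[[1]]
  }
  idx
}

#' Salt-bridge distance series between a lysine and a carboxylate
#'
#' Per-frame minimum distance between the donor lysine NZ and the acceptor
#' carboxylate oxygens (OD1/OD2 for aspartate, OE1/OE2 for glutamate), and
#' the fraction of frames at or below the bound criterion.
#'
#' @param traj An \code{"apc_trajectory"}.
#' @param donor,acceptor Length-2 vectors \code{c(chain, resno)}.
#' @param criterion Bound N-O distance criterion, Angstrom (default 4.0).
#' @param window Frame window; default all frames.
#' @return List of class \code{"salt_bridge_series"}: \code{min_NO_distance}
#'   per frame, \code{bound_fraction}, \code{criterion}, \code{donor},
#'   \code{acceptor}.
#' @export
salt_bridge_series <- function(traj, donor, acceptor, criterion = 4.0,
                               window = NULL) {
  w <- if (is.null(window)) seq_len(n_frames(traj)) else resolve_window(traj, window)
  a <- traj$topology$atoms
  don <- which(!a$het & a$chain == donor[1] & a$resno == as.integer(donor[2]) &
                 a$elety == "NZ")
  if (length(don) != 1)
    stop("donor ", donor[1], "/", donor[2], " has no NZ atom")
  acc <- which(!a$het & a$chain == acceptor[1] &
                 a$resno == as.integer(acceptor[2]) &
                 a$elety %in% c("OD1", "OD2", "OE1", "OE2"))
  if (length(acc) == 0)
    stop("acceptor ", acceptor[1], "/", acceptor[2],
         " has no carboxylate oxygens (OD1/OD2/OE1/OE2)")
  dmin <- vapply(w, function(f) {
    m <- frame_coords(traj, f)
    min(sqrt((m[acc, 1] - m[don, 1])^2 + (m[acc, 2] - m[don, 2])^2 +
               (m[acc, 3] - m[don, 3])^2))
  }, numeric(1))
  structure(list(min_NO_distance = dmin,
                 bound_fraction = mean(dmin <= criterion),
                 criterion = criterion, donor = donor, acceptor = acceptor),
            class = "salt_bridge_series")
}

#' @export
print.salt_bridge_series <- function(x, ...) {
  cat(sprintf("salt bridge %s%s-%s%s: bound fraction %.3f (criterion %.1f A, %d frames)\n",
              x$donor[1], x$donor[2], x$acceptor[1], x$acceptor[2],
              x$bound_fraction, x$criterion, length(x$min_NO_distance)))
  invisible(x)
}

## Designated monomer-interface chromophore pairs on a trimer: each
## interface site is paired with the nearest monomer-pocket site hosted by a
## *different* monomer (in the topology). Errors unless this yields a
## bijection (3 pairs on a trimer).
designated_pairs <- function(sites) {
  if (anyNA(sites$pocket)) stop("sites are unclassified; run classify_pockets first")
  im <- which(sites$pocket == "interface")
  mm <- which(sites$pocket == "monomer")
  if (length(im) == 0 || length(mm) == 0)
    stop("need both interface and monomer sites to enumerate pairs")
  ctr <- as.matrix(sites[, c("cx", "cy", "cz")])
  pairs <- lapply(im, function(i) {
    cand <- mm[sites$monomer[mm] != sites$monomer[i]]
    if (length(cand) == 0) stop("no monomer site outside the host monomer of ",
                                sites$site_id[i])
    d <- sqrt(rowSums((ctr[cand, , drop = FALSE] -
                         matrix(ctr[i, ], length(cand), 3, byrow = TRUE))^2))
    c(interface = i, monomer = cand[which.min(d)])
  })
  mono_used <- vapply(pairs, `[[`, integer(1), "monomer")
  if (anyDuplicated(mono_used))
    stop("pair enumeration is not a bijection; check site classification")
  pairs
}

#' Inter-chromophore distance series for monomer-interface pairs
#'
#' Enumerates the designated chromophore pairs of a trimer (one chromophore
#' in an interface pocket, one in the monomer pocket of an adjacent
#' alpha-beta monomer; three pairs on a trimer) and returns the per-frame
#' distance between their centres of geometry, recomputed per frame from the
#' conjugated-atom sets.
#'
#' @param traj An \code{"apc_trajectory"}.
#' @param sites A classified \code{"chromophore_sites"} table.
#' @param window Frame window; default all frames.
#' @return Named list of numeric per-frame distance vectors (class
#'   \code{"distance_series"}, attribute \code{pair_id}), one per pair,
#'   named \code{"<interface_id>--<monomer_id>"}.
#' @export
pair_distances <- function(traj, sites, window = NULL) {
  w <- if (is.null(window)) seq_len(n_frames(traj)) else resolve_window(traj, window)
  pr <- designated_pairs(sites)
  idx <- attr(sites, "atom_idx")
  out <- lapply(pr, function(p) {
    ii <- idx[[p["interface"]]]; mi <- idx[[p["monomer"]]]
    ci <- cbind(rowMeans(traj$xyz[w, 3 * ii - 2, drop = FALSE]),
                rowMeans(traj$xyz[w, 3 * ii - 1, drop = FALSE]),
                rowMeans(traj$xyz[w, 3 * ii, drop = FALSE]))
    cm <- cbind(rowMeans(traj$xyz[w, 3 * mi - 2, drop = FALSE]),
                rowMeans(traj$xyz[w, 3 * mi - 1, drop = FALSE]),
                rowMeans(traj$xyz[w, 3 * mi, drop = FALSE]))
    d <- sqrt(rowSums((ci - cm)^2))
    structure(d, pair_id = paste0(sites$site_id[p["interface"]], "--",
                                  sites$site_id[p["monomer"]]),
              frame_spacing = traj$frame_spacing, window = range(w),
              class = "distance_series")
  })
  names(out) <- vapply(out, attr, character(1), "pair_id")
  out
}

#' Histogram of an inter-chromophore distance series
#'
#' @param series Numeric distance series (Angstrom).
#' @param bin_width Bin width, Angstrom (default 0.25).
#' @param normalised Report fractions summing to 1 (default TRUE) rather
#'   than raw counts.
#' @return List of class \code{"distance_distribution"}: \code{bin_edges},
#'   \code{frequencies}, \code{summary} (mean, median, mode = centre of the
#'   fullest bin), \code{pair_id}.
#' @export
distance_histogram <- function(series, bin_width = 0.25, normalised = TRUE) {
  if (length(series) == 0) stop("empty distance series")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  x <- as.numeric(series)
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE,
                           right = FALSE, include.lowest = TRUE)$counts
  freq <- if (normalised) counts / sum(counts) else counts
  ctr <- edges[-length(edges)] + bin_width / 2
  structure(list(bin_edges = edges, frequencies = freq,
                 normalised = normalised,
                 summary = list(mean = mean(x), median = stats::median(x),
                                mode = ctr[which.max(counts)]),
                 pair_id = attr(series, "pair_id")),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("distance_distribution", if (!is.null(x$pair_id)) x$pair_id else "",
      sprintf(": mean %.2f, median %.2f, mode %.2f A over %d bins\n",
              x$summary$mean, x$summary$median, x$summary$mode,
              length(x$frequencies)))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, ...) {
  bw <- diff(x$bin_edges[1:2])
  graphics::barplot(x$frequencies, width = bw, space = 0,
                    names.arg = round(x$bin_edges[-length(x$bin_edges)] + bw / 2, 2),
                    xlab = "inter-chromophore distance (A)",
                    ylab = if (x$normalised) "fraction" else "count", ...)
  invisible(x)
}
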