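## Structure container and PDB I/O.
##
## A structure is a light wrapper around an atom table in the bio3d column
## dialect (elety = atom name, elesy = element, resid = residue name, resno =
## author residue number). Author numbering is preserved exactly as read:
## residue identities such as K6 and D100 refer to it.

#' Default bilin chromophore residue names
#'
#' Residue-name allowlist used to recognise bilin chromophores among HETATM
#' groups. Covers phycocyanobilin as deposited in phycobiliprotein entries
#' (CYC, PCB), the mesobiliverdin-adjacent code MEN, and the pseudo-bilin
#' (BLA) written by the synthetic trimer generator.
#'
#' @export
BILIN_RESIDUES <- c("CYC", "MEN", "PCB", "BLA")

new_structure <- function(atoms, assembly = "") {
  need <- c("elety", "elesy", "resid", "resno", "chain", "x", "y", "z", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, assembly = assembly), class = "apc_structure")
}

infer_element <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    elesy <- toupper(trimws(elesy))
    known <- !is.na(elesy) & nzchar(elesy)
    out <- ifelse(known, elesy, NA_character_)
  } else out <- rep(NA_character_, length(elety))
  fix <- is.na(out)
  if (any(fix)) {
    stripped <- sub("^[0-9']+", "", toupper(trimws(elety[fix])))
    out[fix] <- substr(stripped, 1, 1)
  }
  out
}

#' Read a structure from a PDB file
#'
#' Parses a (possibly multi-model) PDB file and returns the atom table with
#' author residue numbering intact. HETATM groups whose residue name is on
#' the bilin allowlist are retained as chromophores; other hetero residues
#' (waters, ions, unknown ligands) are dropped with a warning naming them.
#'
#' @param path Path to a PDB file.
#' @param model_index For multi-model files, which MODEL block to take
#'   (default 1).
#' @param bilin_names Residue-name allowlist for chromophore recognition.
#' @param keep_unknown_het Keep hetero residues not on the allowlist
#'   (default FALSE).
#' @return An object of class \code{"apc_structure"}: a list with an
#'   \code{atoms} data frame (columns \code{elety}, \code{elesy},
#'   \code{resid}, \code{resno}, \code{chain}, \code{x}, \code{y}, \code{z},
#'   \code{het}) and an \code{assembly} label.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_structure(build_toy_trimer(), pdb)
#' s <- read_structure(pdb)
#' length(unique(s$atoms$chain[!s$atoms$het]))  # 6 protein chains
#' @export
read_structure <- function(path, model_index = NULL,
                           bilin_names = BILIN_RESIDUES,
                           keep_unknown_het = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  multi <- !is.null(model_index)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = multi, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: no ATOM/HETATM records in ", path)
  if (multi) {
    nm <- nrow(pdb$xyz)
    if (model_index < 1 || model_index > nm)
      stop("model_index ", model_index, " out of range (file has ", nm, " models)")
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at$chain[is.na(at$chain)] <- " "
  atoms <- data.frame(
    elety = at$elety,
    elesy = infer_element(at$elety, at$elesy),
    resid = at$resid,
    resno = at$resno,
    chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  ## drop waters silently; warn once per unknown hetero residue name
  atoms <- atoms[!(atoms$het & atoms$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  unk <- atoms$het & !(atoms$resid %in% bilin_names)
  if (any(unk) && !keep_unknown_het) {
    warning("ignoring hetero residues not on the bilin allowlist: ",
            paste(sort(unique(atoms$resid[unk])), collapse = ", "))
    atoms <- atoms[!unk, , drop = FALSE]
  }
  if (nrow(atoms) == 0 || all(atoms$het)) {
    if (sum(!atoms$het) == 0) stop("empty structure: no protein chains in ", path)
  }
  new_structure(atoms, assembly = basename(path))
}

#' Write a structure to a PDB file
#'
#' @param x An \code{"apc_structure"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "apc_structure"))
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, elesy = a$elesy,
                   eleno = seq_len(nrow(a)))
  invisible(path)
}

#' @export
print.apc_structure <- function(x, ...) {
  a <- x$atoms
  pc <- unique(a$chain[!a$het])
  hg <- hetero_groups(x)
  cat("apc_structure:", nrow(a), "atoms,", length(pc), "protein chains (",
      paste(pc, collapse = ","), "),", length(hg), "bilin hetero-groups\n")
  invisible(x)
}

coords_matrix <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])

#' Bilin hetero-groups of a structure
#'
#' @param x An \code{"apc_structure"}.
#' @param bilin_names Residue-name allowlist.
#' @return Named list of atom-index vectors, one per hetero-group, named
#'   \code{"<chain>/<resid><resno>"}.
#' @export
hetero_groups <- function(x, bilin_names = BILIN_RESIDUES) {
  a <- x$atoms
  sel <- which(a$het & a$resid %in% bilin_names)
  if (length(sel) == 0) return(list())
  key <- paste0(a$chain[sel], "/", a$resid[sel], a$resno[sel])
  split(sel, factor(key, levels = unique(key)))
}

## Default chain -> monomer pairing: consecutive chains in order of first
## appearance form an alpha-beta monomer (A+B, C+D, E+F). Overridable
## wherever monomer identity matters.
default_monomers <- function(x) {
  ch <- sort(unique(x$atoms$chain[!x$atoms$het]))  # canonical, order-independent
  if (length(ch) %% 2 != 0)
    stop("cannot pair ", length(ch), " protein chains into alpha-beta monomers; ",
         "supply `monomers` explicitly")
  split(ch, rep(seq_len(length(ch) / 2), each = 2))
}

#' Identify chromophore sites
#'
#' Collects each bilin hetero-group into a chromophore site with a
#' conjugated-atom set, a centre of geometry and a transition-dipole unit
#' vector. The dipole is taken along the vector between the two terminal
#' pyrrole nitrogens of the conjugated system (atom pair configurable);
#' when the named pair is absent, the first and last nitrogen atoms of the
#' group are used.
#'
#' @param x An \code{"apc_structure"}.
#' @param bilin_names Residue-name allowlist.
#' @param dipole_atoms Character vector of two atom names defining the
#'   dipole axis (default \code{c("NA","ND")}, the terminal pyrrole
#'   nitrogens of a bilin as deposited).
#' @return A data frame of class \code{"chromophore_sites"} with one row per
#'   site: \code{site_id}, \code{chain}, \code{resno}, \code{resid},
#'   \code{pocket} (NA until classified), centre coordinates \code{cx, cy,
#'   cz} and dipole components \code{dx, dy, dz}; atom indices in
#'   \code{attr(, "atom_idx")}.
#' @export
chromophore_sites <- function(x, bilin_names = BILIN_RESIDUES,
                              dipole_atoms = c("NA", "ND")) {
  grp <- hetero_groups(x, bilin_names)
  if (length(grp) == 0) stop("no bilin hetero-groups found")
  a <- x$atoms
  rows <- lapply(names(grp), function(id) {
    idx <- grp[[id]]
    xyz <- as.matrix(a[idx, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    nm <- a$elety[idx]
    i1 <- match(dipole_atoms[1], nm)
    i2 <- match(dipole_atoms[2], nm)
    if (is.na(i1) || is.na(i2)) {
      nn <- which(a$elesy[idx] == "N")
      if (length(nn) < 2)
        stop("cannot define dipole for site ", id,
             ": dipole atoms absent and fewer than two nitrogens")
      i1 <- nn[1]; i2 <- nn[length(nn)]
    }
    dip <- unit(xyz[i2, ] - xyz[i1, ])
    data.frame(site_id = id, chain = a$chain[idx[1]], resno = a$resno[idx[1]],
               resid = a$resid[idx[1]], pocket = NA_character_,
               cx = ctr[1], cy = ctr[2], cz = ctr[3],
               dx = dip[1], dy = dip[2], dz = dip[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "atom_idx") <- unname(grp)
  class(out) <- c("chromophore_sites", "data.frame")
  out
}

#' @export
`[.chromophore_sites` <- function(x, i, j, ...) {
  idx <- attr(x, "atom_idx")
  out <- NextMethod()
  if (is.data.frame(out) && !missing(i)) {
    attr(out, "atom_idx") <- idx[i]
    class(out) <- class(x)
  }
  out
}

#' Classify chromophore-binding pockets as monomeric or interface
#'
#' A site is \emph{monomeric} when every protein residue with any heavy atom
#' within \code{contact_cutoff} of any heavy atom of the chromophore belongs
#' to the host alpha-beta monomer, and \emph{interface} when residues of an
#' adjacent monomer also enclose it. On a C3-symmetric trimer this yields
#' exactly three sites of each class.
#'
#' @param x An \code{"apc_structure"}.
#' @param contact_cutoff Heavy-atom contact cutoff in Angstrom (default 4.5).
#' @param monomers List of chain-id vectors defining the alpha-beta
#'   monomers; default pairs consecutive chains.
#' @param bilin_names,dipole_atoms Passed to \code{chromophore_sites}.
#' @return A \code{"chromophore_sites"} data frame with the \code{pocket}
#'   column filled in (\code{"monomer"} or \code{"interface"}) and the host
#'   monomer index in \code{monomer}.
#' @export
classify_pockets <- function(x, contact_cutoff = 4.5, monomers = NULL,
                             bilin_names = BILIN_RESIDUES,
                             dipole_atoms = c("NA", "ND")) {
  stopifnot(contact_cutoff > 0)
  sites <- chromophore_sites(x, bilin_names, dipole_atoms)
  monomers <- monomers %||% default_monomers(x)
  a <- x$atoms
  prot <- which(!a$het & a$elesy != "H")
  pxyz <- as.matrix(a[prot, c("x", "y", "z")])
  chain2mon <- stats::setNames(rep(seq_along(monomers), lengths(monomers)),
                               unlist(monomers))
  idx_list <- attr(sites, "atom_idx")
  pocket <- character(nrow(sites)); hostmon <- integer(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    idx <- idx_list[[i]]
    idx <- idx[a$elesy[idx] != "H"]
    cxyz <- as.matrix(a[idx, c("x", "y", "z"), drop = FALSE])
    ## min distance from each protein atom to the chromophore
    d2min <- rep(Inf, nrow(pxyz))
    for (k in seq_len(nrow(cxyz))) {
      d2 <- (pxyz[, 1] - cxyz[k, 1])^2 + (pxyz[, 2] - cxyz[k, 2])^2 +
            (pxyz[, 3] - cxyz[k, 3])^2
      d2min <- pmin(d2min, d2)
    }
    touch <- prot[d2min <= contact_cutoff^2]
    if (length(touch) == 0)
      stop("isolated chromophore: site ", sites$site_id[i],
           " has no contacting residue within ", contact_cutoff, " A")
    tch <- unique(a$chain[touch])
    mons <- unique(chain2mon[tch])
    if (anyNA(mons))
      stop("chain(s) ", paste(setdiff(tch, names(chain2mon)), collapse = ","),
           " not assigned to any monomer")
    host <- chain2mon[[sites$chain[i]]]
    if (is.null(host) || is.na(host)) host <- mons[1]
    hostmon[i] <- host
    pocket[i] <- if (all(mons == host)) "monomer" else "interface"
  }
  sites$pocket <- pocket
  sites$monomer <- hostmon
  sites
}
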