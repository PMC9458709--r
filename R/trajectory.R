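## Trajectory container and I/O.
##
## Frames are stored in the bio3d xyz convention: one row per frame, columns
## x1,y1,z1,x2,... over the topology's atoms. Two on-disk dialects are
## supported: multi-model PDB (canonical, interoperable) and a plain-text
## per-frame XYZ dialect for large synthetic runs:
##
##   line 1:  <n_atoms> <frame_spacing_ps>
##   then, per frame: a line "frame <i>" followed by n_atoms lines "x y z".
##   '#' lines are comments.

new_trajectory <- function(topology, xyz, frame_spacing = 10) {
  stopifnot(inherits(topology, "apc_structure"))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_at <- nrow(topology$atoms)
  if (ncol(xyz) != 3 * n_at)
    stop("frame width ", ncol(xyz), " does not match topology (", n_at, " atoms)")
  if (frame_spacing <= 0) stop("frame_spacing must be > 0")
  structure(list(topology = topology, xyz = xyz,
                 frame_spacing = frame_spacing),
            class = "apc_trajectory")
}

#' @export
print.apc_trajectory <- function(x, ...) {
  cat("apc_trajectory:", nrow(x$xyz), "frames x",
      ncol(x$xyz) / 3, "atoms, spacing", x$frame_spacing, "ps\n")
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

## n_atoms x 3 coordinate matrix of frame i
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Read a trajectory
#'
#' Reads either a multi-model PDB file (extension \code{.pdb}) or the
#' plain-text XYZ-per-frame dialect documented in
#' \code{\link{write_trajectory}}. Every frame must carry the same atom
#' count as the topology; a malformed frame is reported by index.
#'
#' @param path Input file.
#' @param topology An \code{"apc_structure"} giving the atom order.
#' @param frame_spacing Frame spacing in ps; for the text dialect the header
#'   value is used and this argument must agree if supplied.
#' @return An object of class \code{"apc_trajectory"}.
#' @export
read_trajectory <- function(path, topology, frame_spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  n_at <- nrow(topology$atoms)
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3 * n_at)
      stop("aligned-topology error: file has ", ncol(xyz) / 3,
           " atoms per model, topology has ", n_at)
    return(new_trajectory(topology, xyz, frame_spacing %||% 10))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) < 2 || anyNA(hdr)) stop("malformed trajectory header: ", lines[1])
  file_nat <- as.integer(hdr[1]); spacing <- hdr[2]
  if (file_nat != n_at)
    stop("aligned-topology error: header declares ", file_nat,
         " atoms, topology has ", n_at)
  if (!is.null(frame_spacing) && abs(frame_spacing - spacing) > 1e-9)
    stop("frame_spacing ", frame_spacing, " conflicts with file header ", spacing)
  body <- lines[-1]
  starts <- grep("^\\s*frame\\b", body)
  if (length(starts) == 0) stop("no frames found in ", path)
  ends <- c(starts[-1] - 1, length(body))
  frames <- vector("list", length(starts))
  for (f in seq_along(starts)) {
    blk <- body[(starts[f] + 1):ends[f]]
    if (length(blk) != n_at)
      stop("aligned-topology error in frame ", f, ": ", length(blk),
           " atom lines, expected ", n_at)
    m <- matrix(scan(text = blk, quiet = TRUE), ncol = 3, byrow = TRUE)
    if (nrow(m) != n_at || anyNA(m))
      stop("aligned-topology error in frame ", f, ": malformed coordinates")
    frames[[f]] <- as.vector(t(m))
  }
  new_trajectory(topology, do.call(rbind, frames), spacing)
}

#' Write a trajectory
#'
#' Writes either a multi-model PDB (\code{format = "pdb"}) or the plain-text
#' XYZ-per-frame dialect (\code{format = "xyz"}; header line
#' \code{"<n_atoms> <frame_spacing_ps>"}, then per frame a \code{"frame i"}
#' line followed by one \code{"x y z"} line per atom, written with 6
#' decimals).
#'
#' @param traj An \code{"apc_trajectory"}.
#' @param path Output file.
#' @param format \code{"xyz"} (default) or \code{"pdb"}.
#' @return Invisibly, \code{path}.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  if (format == "pdb") {
    a <- traj$topology$atoms
    bio3d::write.pdb(file = path, xyz = traj$xyz,
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     elety = a$elety, elesy = a$elesy,
                     eleno = seq_len(nrow(a)))
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  n_at <- ncol(traj$xyz) / 3
  writeLines(sprintf("%d %g", n_at, traj$frame_spacing), con)
  for (f in seq_len(nrow(traj$xyz))) {
    writeLines(paste("frame", f), con)
    m <- frame_coords(traj, f)
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
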