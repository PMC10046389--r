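#' Conformational-ensemble container
#'
#' A `trajectory` bundles a static topology (chains, residues, atoms) with
#' an ordered stack of coordinate frames.  Coordinates are Angstrom, times
#' picoseconds, and residue numbers are author numbers (e.g. the 352-based
#' numbering of the calreticulin C-domain), preserved end-to-end so that
#' every report can be read against the literature numbering.
#'
#' @param atoms data.frame with one row per atom and columns `chain`
#'   (character), `resno` (integer author number), `resname` (3-letter
#'   residue or ion/water code), `atom` (atom name, e.g. `"CA"`), `element`
#'   (element symbol, e.g. `"C"`, `"Ca"`), `polymer` (logical; `TRUE` for
#'   amino-acid residues, `FALSE` for ions/water).
#' @param xyz numeric matrix, one row per frame, `3 * natoms` columns in
#'   topology order (x1, y1, z1, x2, ...).
#' @param time_ps numeric vector of frame times in picoseconds, strictly
#'   increasing.
#' @param label free-form system label.
#'
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, xyz, time_ps = NULL, label = "") {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  natoms <- nrow(atoms)
  if (ncol(xyz) != 3L * natoms)
    stop("coordinate columns (", ncol(xyz), ") do not match 3 x ",
         natoms, " topology atoms")
  if (nrow(xyz) < 1L) stop("a trajectory needs at least one frame")
  if (any(!is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (is.null(time_ps)) time_ps <- 100 * (seq_len(nrow(xyz)) - 1)
  if (length(time_ps) != nrow(xyz))
    stop("time_ps length does not match the number of frames")
  if (any(diff(time_ps) <= 0))
    stop("time_ps must be strictly increasing across frames")
  need <- c("chain", "resno", "resname", "atom", "element", "polymer")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (any(!nzchar(atoms$element))) stop("empty element symbol in topology")
  # author numbering must increase within a chain for polymer residues
  pol <- atoms[atoms$polymer, , drop = FALSE]
  for (ch in unique(pol$chain)) {
    rn <- unique(pol$resno[pol$chain == ch])
    if (any(diff(rn) <= 0))
      stop("author residue numbers not strictly increasing in chain ", ch)
  }
  structure(list(atoms = atoms, xyz = xyz,
                 time_ps = as.numeric(time_ps), label = label),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  pol <- x$atoms[x$atoms$polymer, ]
  nres <- nrow(unique(pol[, c("chain", "resno")]))
  nion <- sum(!x$atoms$polymer)
  cat("trajectory", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "\n  frames:  ", n_frames(x),
      " (", x$time_ps[1], "..", x$time_ps[length(x$time_ps)], " ps)",
      "\n  chains:  ", paste(unique(x$atoms$chain[x$atoms$polymer]), collapse = ", "),
      "\n  atoms:   ", n_atoms(x), " (", nres, " polymer residues, ",
      nion, " het atoms)\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a [trajectory()].
#' @return integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Coordinates of one frame
#'
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return `natoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Select atoms from a trajectory topology
#'
#' Selection is purely topological (independent of frame content) and
#' returns stable topology-order indices.  The alpha-carbon selection
#' (`atom = "CA"`) is restricted to polymer residues, so it can never pick
#' up a calcium ion, whose atom name is also `"CA"` but which is a
#' non-polymer residue with element `"Ca"`.
#'
#' @param traj a [trajectory()].
#' @param chain chain identifier, or `"all"`.
#' @param atom atom name (e.g. `"CA"`), or `"all"`.  Atom-name matching
#'   applies to polymer residues only.
#' @param element element symbol (e.g. `"Ca"`), or `"all"`.
#' @return integer vector of atom indices (possibly empty).
#' @examples
#' ## alpha-carbons of chain A:
#' ## select_atoms(traj, chain = "A", atom = "CA")
#' ## calcium ions, regardless of chain:
#' ## select_atoms(traj, element = "Ca")
#' @export
select_atoms <- function(traj, chain = "all", atom = "all", element = "all") {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!identical(chain, "all")) keep <- keep & a$chain == chain
  if (!identical(atom, "all"))  keep <- keep & a$atom == atom & a$polymer
  if (!identical(element, "all")) keep <- keep & a$element == element
  which(keep)
}

#' Drop equilibration frames
#'
#' Removes every frame with `time_ps < t_cut_ps`; the topology is left
#' untouched.  The conventional cut for 100 ps-stride production runs is
#' 5000 ps (the first 5 ns).
#'
#' @param traj a [trajectory()].
#' @param t_cut_ps time cut in picoseconds (>= 0).
#' @return a [trajectory()] containing the retained frames.
#' @export
discard_equilibration <- function(traj, t_cut_ps = 5000) {
  stopifnot(t_cut_ps >= 0)
  keep <- traj$time_ps >= t_cut_ps
  if (!any(keep))
    stop("equilibration cut at ", t_cut_ps,
         " ps removes every frame (last frame is at ",
         traj$time_ps[length(traj$time_ps)], " ps)")
  trajectory(traj$atoms, traj$xyz[keep, , drop = FALSE],
             traj$time_ps[keep], traj$label)
}

#' Table of polymer residues in a chain
#'
#' @param traj a [trajectory()].
#' @param chain chain id, or `"all"`.
#' @return data.frame with columns `chain`, `resno`, `resname`, one row
#'   per polymer residue in topology order.
#' @export
polymer_residues <- function(traj, chain = "all") {
  a <- traj$atoms[traj$atoms$polymer, , drop = FALSE]
  if (!identical(chain, "all")) a <- a[a$chain == chain, , drop = FALSE]
  unique(a[, c("chain", "resno", "resname")])
}

# index of one named atom of a residue; NA when absent
.atom_index <- function(traj, chain, resno, atom) {
  a <- traj$atoms
  i <- which(a$chain == chain & a$resno == resno & a$atom == atom & a$polymer)
  if (length(i) == 0L) NA_integer_ else i[1L]
}
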