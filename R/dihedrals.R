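#' Dihedral angle defined by four points
#'
#' IUPAC sign convention: looking from `p2` to `p3`, the angle is the
#' clockwise rotation of the `p3->p4` bond relative to the `p1->p2` bond.
#' The value is reported in degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi series over a trajectory
#'
#' For every polymer residue `i` of the chain and every frame,
#' `phi(i)` is the C(i-1)-N(i)-CA(i)-C(i) dihedral and `psi(i)` the
#' N(i)-CA(i)-C(i)-N(i+1) dihedral, in degrees, IUPAC convention.
#' `phi` is undefined (`NA`) for the first residue and `psi` for the
#' last; a residue missing one of its backbone atoms has its affected
#' angles marked `NA` with a warning.
#'
#' @param traj a [trajectory()].
#' @param chain chain identifier.
#' @return An object of class `dihedral_series`: list with `phi` and
#'   `psi` (`n_frames x n_res` matrices, columns named by author residue
#'   number), `resno`, `chain`, `time_ps`.
#' @export
compute_phi_psi <- function(traj, chain) {
  res <- polymer_residues(traj, chain)
  if (nrow(res) == 0L) stop("no polymer residues in chain ", chain)
  nres <- nrow(res)
  idx <- function(atom) vapply(seq_len(nres), function(i)
    .atom_index(traj, chain, res$resno[i], atom), integer(1))
  iN <- idx("N"); iCA <- idx("CA"); iC <- idx("C")
  if (anyNA(c(iN, iCA, iC)))
    warning("missing backbone atoms in chain ", chain,
            "; affected angles set to NA")

  nf <- n_frames(traj)
  phi <- matrix(NA_real_, nf, nres)
  psi <- matrix(NA_real_, nf, nres)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    for (i in seq_len(nres)) {
      if (i > 1L && !anyNA(c(iC[i - 1L], iN[i], iCA[i], iC[i])))
        phi[f, i] <- dihedral_angle(co[iC[i - 1L], ], co[iN[i], ],
                                    co[iCA[i], ], co[iC[i], ])
      if (i < nres && !anyNA(c(iN[i], iCA[i], iC[i], iN[i + 1L])))
        psi[f, i] <- dihedral_angle(co[iN[i], ], co[iCA[i], ],
                                    co[iC[i], ], co[iN[i + 1L], ])
    }
  }
  colnames(phi) <- colnames(psi) <- res$resno
  structure(list(phi = phi, psi = psi, resno = res$resno,
                 chain = chain, time_ps = traj$time_ps),
            class = "dihedral_series")
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat("dihedral_series: chain ", x$chain, ", ", length(x$resno),
      " residues x ", nrow(x$phi), " frames\n", sep = "")
  invisible(x)
}
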