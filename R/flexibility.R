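# Calpha RMSD/RMSF with least-squares (Kabsch) rigid-body superposition.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` (det = +1) and translation `t`
#' minimizing the RMSD between `R %*% mobile + t` and `reference`.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (residual after the fit, Angstrom).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("point counts differ between mobile and reference")
  if (nrow(mobile) < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2L, cm); B <- sweep(reference, 2L, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cr - as.numeric(R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2L, tvec, "+")
  list(rotation = R, translation = tvec,
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

# apply a superpose() transform to an n x 3 matrix
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2L, fit$translation, "+")
}

#' Calpha RMSD time series
#'
#' Per frame: superpose the frame onto the reference frame (least-squares
#' fit on `fit_selection`), then report the root-mean-square displacement
#' of the atoms in `selection`.  With the default `fit_selection =
#' selection` this is the classical Calpha RMSD against the starting
#' structure; a separate fit set allows measuring a sub-region while
#' fitting on a rigid core.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices to measure (e.g. from
#'   `select_atoms(traj, atom = "CA")`).
#' @param reference reference frame index (default 1, the first retained
#'   frame).
#' @param fit_selection atom indices used for the superposition fit.
#' @return data.frame of class `rmsd_series` with columns `time_ps`,
#'   `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, selection, reference = 1L,
                        fit_selection = selection) {
  if (length(selection) == 0L) stop("empty selection")
  ref <- frame_coords(traj, reference)
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    co <- frame_coords(traj, f)
    fit <- superpose(co[fit_selection, , drop = FALSE],
                     ref[fit_selection, , drop = FALSE])
    moved <- apply_transform(co[selection, , drop = FALSE], fit)
    sqrt(mean(rowSums((moved - ref[selection, , drop = FALSE])^2)))
  }, numeric(1))
  structure(data.frame(time_ps = traj$time_ps, rmsd = out),
            class = c("rmsd_series", "data.frame"),
            reference = reference)
}

#' Per-residue Calpha RMSF
#'
#' All frames are first superposed onto the reference frame (fit on
#' `fit_selection`); the fluctuation of each selected atom is then the
#' root-mean-square deviation from its time-average position:
#' `RMSF(i) = sqrt(mean_t ||x_i(t) - mean_t x_i||^2)`.
#'
#' @inheritParams rmsd_series
#' @return data.frame of class `rmsf_profile` with columns `chain`,
#'   `resno`, `rmsf` (Angstrom), one row per selected atom.
#' @export
rmsf <- function(traj, selection, reference = 1L, fit_selection = selection) {
  if (length(selection) == 0L) stop("empty selection")
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  ref <- frame_coords(traj, reference)
  nf <- n_frames(traj)
  nsel <- length(selection)
  stack <- array(NA_real_, c(nf, nsel, 3L))
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    fit <- superpose(co[fit_selection, , drop = FALSE],
                     ref[fit_selection, , drop = FALSE])
    stack[f, , ] <- apply_transform(co[selection, , drop = FALSE], fit)
  }
  mean_pos <- apply(stack, c(2L, 3L), mean)
  dev2 <- vapply(seq_len(nsel), function(i) {
    mean(rowSums(sweep(stack[, i, , drop = TRUE], 2L, mean_pos[i, ])^2))
  }, numeric(1))
  a <- traj$atoms[selection, ]
  structure(data.frame(chain = a$chain, resno = a$resno,
                       rmsf = sqrt(dev2)),
            class = c("rmsf_profile", "data.frame"),
            reference = reference)
}
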