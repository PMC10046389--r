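# Ion-binding analysis: per-residue occupancy within a distance cutoff,
# per-ion binding onset, and the bound-ion count time series.
#
# "Distance from a residue" is the minimum over the residue's heavy
# atoms (hydrogens excluded).  Coordinates are taken as unwrapped; no
# periodic-boundary minimum-image correction is applied.

# indices of heavy protein atoms, grouped by (chain, resno)
.heavy_by_residue <- function(traj) {
  a <- traj$atoms
  heavy <- which(a$polymer & a$element != "H")
  split(heavy, paste(a$chain[heavy], a$resno[heavy], sep = ":"))[
    unique(paste(a$chain[heavy], a$resno[heavy], sep = ":"))]
}

.ion_indices <- function(traj, ion_element) {
  ions <- which(!traj$atoms$polymer & traj$atoms$element == ion_element)
  if (length(ions) == 0L)
    stop("no ions with element '", ion_element, "' in the trajectory")
  ions
}

# n x m matrix of squared distances between two coordinate sets
.cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
}

#' Per-residue ion occupancy
#'
#' For every polymer residue, the fraction of frames in which at least
#' one ion of `ion_element` lies within `cutoff_A` of any heavy atom of
#' the residue (binary presence per frame, not an ion count).
#'
#' @param traj a [trajectory()].
#' @param ion_element element symbol of the ion, e.g. `"Ca"`, `"Na"`.
#' @param cutoff_A distance cutoff in Angstrom (default 3.0, the
#'   conventional contact radius for ion fixation).
#' @return data.frame of class `occupancy_profile` with columns `chain`,
#'   `resno`, `occupancy` (in `[0, 1]`); attributes record the cutoff,
#'   element and frame count.
#' @export
ion_occupancy <- function(traj, ion_element, cutoff_A = 3.0) {
  ions <- .ion_indices(traj, ion_element)
  byres <- .heavy_by_residue(traj)
  nf <- n_frames(traj)
  cut2 <- cutoff_A^2
  hits <- matrix(0L, nf, length(byres))
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    ico <- co[ions, , drop = FALSE]
    for (r in seq_along(byres)) {
      d2 <- .cross_dist2(co[byres[[r]], , drop = FALSE], ico)
      hits[f, r] <- as.integer(min(d2) <= cut2)
    }
  }
  key <- do.call(rbind, strsplit(names(byres), ":", fixed = TRUE))
  structure(data.frame(chain = key[, 1L], resno = as.integer(key[, 2L]),
                       occupancy = colMeans(hits)),
            class = c("occupancy_profile", "data.frame"),
            cutoff_A = cutoff_A, ion_element = ion_element, n_frames = nf)
}

# logical n_frames x n_ions matrix: ion within cutoff of any protein heavy atom
.bound_matrix <- function(traj, ion_element, cutoff_A) {
  ions <- .ion_indices(traj, ion_element)
  heavy <- which(traj$atoms$polymer & traj$atoms$element != "H")
  nf <- n_frames(traj)
  cut2 <- cutoff_A^2
  bound <- matrix(FALSE, nf, length(ions))
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    d2 <- .cross_dist2(co[ions, , drop = FALSE], co[heavy, , drop = FALSE])
    bound[f, ] <- apply(d2, 1L, min) <= cut2
  }
  bound
}

#' Per-ion binding onset
#'
#' For each ion of the element, the earliest frame from which the ion
#' stays within `cutoff_A` of some protein heavy atom for at least
#' `persistence_frames` consecutive frames.  Ions that never satisfy the
#' rule are reported with status `"never"`.  The default persistence of
#' 10 frames corresponds to 1 ns at a 100 ps save stride and guards
#' against single-frame grazing contacts.
#'
#' @inheritParams ion_occupancy
#' @param persistence_frames minimum consecutive bound frames (>= 1).
#' @return data.frame of class `binding_onset` with columns `ion`
#'   (index among ions of the element), `onset_time_ps` (`NA` when
#'   never bound), `status` (`"bound"`/`"never"`).
#' @export
binding_onset <- function(traj, ion_element, cutoff_A = 3.0,
                          persistence_frames = 10L) {
  stopifnot(persistence_frames >= 1L)
  bound <- .bound_matrix(traj, ion_element, cutoff_A)
  onset <- vapply(seq_len(ncol(bound)), function(i) {
    r <- rle(bound[, i])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= persistence_frames)
    if (length(ok) == 0L) NA_integer_ else starts[ok[1L]]
  }, integer(1))
  data.frame(ion = seq_len(ncol(bound)),
             onset_time_ps = ifelse(is.na(onset), NA_real_,
                                    traj$time_ps[onset]),
             status = ifelse(is.na(onset), "never", "bound"))
}

#' Bound-ion count time series
#'
#' Number of ions of the element within `cutoff_A` of the protein in
#' each frame -- the binding-kinetics curve whose plateau shows when
#' (almost) all counter-ions have condensed onto the chain.
#'
#' @inheritParams ion_occupancy
#' @return data.frame with columns `time_ps`, `n_bound`.
#' @export
bound_count_series <- function(traj, ion_element, cutoff_A = 3.0) {
  bound <- .bound_matrix(traj, ion_element, cutoff_A)
  data.frame(time_ps = traj$time_ps, n_bound = rowSums(bound))
}
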