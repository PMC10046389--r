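# Dimer geometry: inter-chain anchor distances and separation verdicts.

#' Inter-chain anchor-distance time series
#'
#' For each anchor residue number, the per-frame Euclidean distance
#' between the Calpha of that residue on `chain1` and on `chain2`.
#' Anchors are author residue numbers (the figure convention: typically
#' three positions spread along the chain).
#'
#' @param traj a [trajectory()] holding a two-chain system.
#' @param chain1,chain2 chain identifiers.
#' @param anchors integer vector of author residue numbers present on
#'   both chains.
#' @return object of class `anchor_distances`: data.frame with
#'   `time_ps` and one column `d_<anchor>` per anchor (Angstrom).
#' @export
anchor_distances <- function(traj, chain1, chain2, anchors) {
  i1 <- vapply(anchors, function(r) .atom_index(traj, chain1, r, "CA"), integer(1))
  i2 <- vapply(anchors, function(r) .atom_index(traj, chain2, r, "CA"), integer(1))
  if (anyNA(i1))
    stop("anchor residue ", anchors[which(is.na(i1))[1L]],
         " has no CA on chain ", chain1)
  if (anyNA(i2))
    stop("anchor residue ", anchors[which(is.na(i2))[1L]],
         " has no CA on chain ", chain2)
  D <- t(vapply(seq_len(n_frames(traj)), function(f) {
    co <- frame_coords(traj, f)
    sqrt(rowSums((co[i1, , drop = FALSE] - co[i2, , drop = FALSE])^2))
  }, numeric(length(anchors))))
  if (length(anchors) == 1L) D <- matrix(D, ncol = 1L)
  colnames(D) <- paste0("d_", anchors)
  structure(cbind(data.frame(time_ps = traj$time_ps), as.data.frame(D)),
            class = c("anchor_distances", "data.frame"),
            anchors = anchors, chains = c(chain1, chain2))
}

#' Classify dimer separation from anchor distances
#'
#' The dimer is called `"separated"` when the minimum-over-anchors
#' distance exceeds `threshold_A` throughout the final
#' `persistence_fraction` of frames (a persistence rule that ignores
#' single-frame excursions); otherwise `"stable"`.  The onset is the
#' first frame of the terminal excursion above the threshold.
#'
#' Defaults (50 Angstrom over the final 20 % of frames) are reporting
#' conventions, not physics: separated chains drift to hundreds of
#' Angstrom, bound dimers oscillate near their contact distance.
#'
#' @param series an `anchor_distances` object.
#' @param threshold_A separation threshold in Angstrom (> 0).
#' @param persistence_fraction final fraction of frames that must stay
#'   beyond the threshold, in `(0, 1]`.
#' @return list of class `separation_verdict`: `label`
#'   (`"stable"`/`"separated"`), `onset_time_ps` (`NA` unless
#'   separated), `max_distance_A`, plus the parameters used.
#' @export
classify_separation <- function(series, threshold_A = 50,
                                persistence_fraction = 0.2) {
  stopifnot(threshold_A > 0,
            persistence_fraction > 0, persistence_fraction <= 1)
  dcols <- grep("^d_", names(series))
  dmin <- do.call(pmin, series[dcols])
  n <- length(dmin)
  tail_n <- max(1L, ceiling(persistence_fraction * n))
  tail_idx <- (n - tail_n + 1L):n
  separated <- all(dmin[tail_idx] > threshold_A)
  onset <- NA_real_
  if (separated) {
    below <- which(dmin <= threshold_A)
    first_above <- if (length(below) == 0L) 1L else max(below) + 1L
    onset <- series$time_ps[first_above]
  }
  structure(list(label = if (separated) "separated" else "stable",
                 onset_time_ps = onset,
                 max_distance_A = max(unlist(series[dcols])),
                 threshold_A = threshold_A,
                 persistence_fraction = persistence_fraction),
            class = "separation_verdict")
}

#' @export
print.separation_verdict <- function(x, ...) {
  cat("separation verdict: ", x$label,
      if (x$label == "separated")
        paste0(" (onset ", x$onset_time_ps, " ps)") else "",
      "; max inter-chain distance ",
      sprintf("%.1f", x$max_distance_A), " A\n", sep = "")
  invisible(x)
}

#' Inter-chain disulfide-position distance
#'
#' Per-frame distance between the Sgamma atoms of `res1` (on `chain1`)
#' and `res2` (on `chain2`); a bonded cystine sits near 2.05 Angstrom,
#' while values of several Angstrom mean the bridge is open.  When a
#' Sgamma atom is absent (e.g. backbone-only models) the Calpha-Calpha
#' distance is returned instead, flagged in the `atom` attribute and
#' column.
#'
#' @param traj a [trajectory()].
#' @param chain1,chain2 chain identifiers.
#' @param res1,res2 author residue numbers of the two cysteines.
#' @return data.frame with columns `time_ps`, `distance_A`, `atom`
#'   (`"SG"` or `"CA"` fallback).
#' @export
disulfide_distance <- function(traj, chain1, chain2, res1, res2) {
  i1 <- .atom_index(traj, chain1, res1, "SG")
  i2 <- .atom_index(traj, chain2, res2, "SG")
  atom <- "SG"
  if (is.na(i1) || is.na(i2)) {
    atom <- "CA"
    i1 <- .atom_index(traj, chain1, res1, "CA")
    i2 <- .atom_index(traj, chain2, res2, "CA")
    if (is.na(i1) || is.na(i2))
      stop("residue ", res1, "/", res2, " missing on chain ",
           chain1, "/", chain2)
    warning("SG atoms absent; falling back to CA-CA distance")
  }
  d <- vapply(seq_len(n_frames(traj)), function(f) {
    co <- frame_coords(traj, f)
    sqrt(sum((co[i1, ] - co[i2, ])^2))
  }, numeric(1))
  data.frame(time_ps = traj$time_ps, distance_A = d, atom = atom)
}
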