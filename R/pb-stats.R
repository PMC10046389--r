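# Per-position PB frequency profiles and the derived statistics:
# Neq (equivalent number of blocks), Delta-Neq and Delta-PB.

#' Per-position Protein Block frequency profile
#'
#' Accumulates PB assignments over frames into per-position frequencies:
#' `f_x(i)` is the count of block `x` at position `i` divided by the
#' number of frames where position `i` is assignable.  Unassignable
#' (`Z`) observations are excluded rather than counted as a 17th state,
#' so the 16 frequencies of every assignable position sum to 1 -- the
#' normalization the Neq and Delta-PB formulas assume.  Positions that
#' are never assignable are flagged and excluded downstream.
#'
#' @param pbs a `pb_strings` matrix from [assign_pbs()], or a plain
#'   character matrix (frames x positions) over `a`..`p`/`Z` with column
#'   names giving author residue numbers.
#' @return An object of class `pb_profile`: list with `freq` and
#'   `counts` (16 x n_pos matrices, rows `a`..`p`), `resno`,
#'   `n_frames`, `n_assignable` (per position), `assignable` (logical).
#' @export
pb_profile <- function(pbs) {
  pbs <- unclass(pbs)
  resno <- as.integer(colnames(pbs))
  npos <- ncol(pbs)
  counts <- matrix(0L, 16L, npos, dimnames = list(PB_LABELS, resno))
  for (x in seq_along(PB_LABELS))
    counts[x, ] <- colSums(pbs == PB_LABELS[x])
  n_assign <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(n_assign, 1L), "/")
  freq[, n_assign == 0L] <- NA_real_
  structure(list(freq = freq, counts = counts, resno = resno,
                 n_frames = nrow(pbs), n_assignable = n_assign,
                 assignable = n_assign > 0L),
            class = "pb_profile")
}

#' Build a profile directly from frequency vectors
#'
#' Convenience constructor for closed-form work: wraps a 16 x n matrix of
#' per-position PB frequencies (columns summing to 1) as a `pb_profile`.
#'
#' @param freq numeric 16 x n matrix (or 16-vector for one position);
#'   rows in `a`..`p` order.
#' @param resno author residue numbers for the columns.
#' @return a `pb_profile`.
#' @export
pb_profile_from_freq <- function(freq, resno = NULL) {
  if (is.null(dim(freq))) freq <- matrix(freq, ncol = 1L)
  stopifnot(nrow(freq) == 16L)
  if (any(abs(colSums(freq) - 1) > 1e-9))
    stop("frequency columns must sum to 1")
  if (any(freq < 0)) stop("negative frequency")
  if (is.null(resno)) resno <- seq_len(ncol(freq))
  dimnames(freq) <- list(PB_LABELS, resno)
  structure(list(freq = freq, counts = freq * NA, resno = as.integer(resno),
                 n_frames = NA_integer_, n_assignable = rep(NA_integer_, ncol(freq)),
                 assignable = rep(TRUE, ncol(freq))),
            class = "pb_profile")
}

#' @export
print.pb_profile <- function(x, ...) {
  cat("pb_profile: ", length(x$resno), " positions (",
    sum(x$assignable), " assignable), ", x$n_frames, " frames\n", sep = "")
  invisible(x)
}

#' Equivalent number of Protein Blocks (Neq)
#'
#' `Neq(i) = exp(-sum_x f_x(i) * ln f_x(i))`, the exponential of the
#' Shannon entropy (nats) of the position's PB distribution, with the
#' convention `0 * ln 0 = 0`.  Neq is 1 when a single block is observed,
#' 16 for the uniform (random) distribution, and in between measures the
#' effective number of local conformations sampled at that position.
#'
#' @param profile a `pb_profile`.
#' @return named numeric vector (names = author residue numbers), class
#'   `neq_profile`; `NA` at never-assignable positions.
#' @export
neq <- function(profile) {
  stopifnot(inherits(profile, "pb_profile"))
  f <- profile$freq
  plogp <- f * log(f)
  plogp[!is.finite(plogp)] <- 0      # 0*ln 0 := 0 (and NA columns handled below)
  v <- exp(-colSums(plogp))
  v[!profile$assignable] <- NA_real_
  names(v) <- profile$resno
  class(v) <- "neq_profile"
  v
}

#' @export
print.neq_profile <- function(x, ...) { print(unclass(x)); invisible(x) }

# align two position sets by author number (or explicit pairing map)
.align_positions <- function(r1, r2, pairing = NULL) {
  if (is.null(pairing)) {
    common <- intersect(r1, r2)
    dropped <- length(setdiff(r1, r2)) + length(setdiff(r2, r1))
    if (dropped > 0)
      warning(dropped, " unaligned positions excluded from the comparison")
    if (length(common) == 0L) stop("no aligned positions between the two systems")
    data.frame(pos1 = common, pos2 = common)
  } else {
    stopifnot(all(c("pos1", "pos2") %in% names(pairing)))
    keep <- pairing$pos1 %in% r1 & pairing$pos2 %in% r2
    if (any(!keep))
      warning(sum(!keep), " pairing rows refer to absent positions; excluded")
    if (!any(keep)) stop("no aligned positions between the two systems")
    pairing[keep, c("pos1", "pos2")]
  }
}

#' Per-position absolute Neq difference between two systems
#'
#' Positions are aligned by author-number identity unless an explicit
#' `pairing` table (columns `pos1`, `pos2`) is given -- the latter is the
#' route for comparing frameshifted systems of unequal length.
#'
#' @param n1,n2 `neq_profile` vectors from [neq()].
#' @param pairing optional data.frame with columns `pos1`, `pos2`.
#' @return data.frame with columns `pos1`, `pos2`, `delta_neq`
#'   (`|Neq1 - Neq2|`, in `[0, 15]`).
#' @export
delta_neq <- function(n1, n2, pairing = NULL) {
  r1 <- as.integer(names(n1)); r2 <- as.integer(names(n2))
  al <- .align_positions(r1, r2, pairing)
  d <- abs(unclass(n1)[match(al$pos1, r1)] - unclass(n2)[match(al$pos2, r2)])
  out <- data.frame(pos1 = al$pos1, pos2 = al$pos2, delta_neq = unname(d))
  # positions never assignable in either system are excluded
  out[!is.na(out$delta_neq), , drop = FALSE]
}

#' Per-position PB profile divergence (Delta-PB)
#'
#' `DeltaPB(i) = sum_x |f_x^S1(i) - f_x^S2(i)|`, the L1 distance between
#' the two systems' PB frequency vectors at aligned position `i`.  It is
#' 0 for identical distributions and 2 for distributions with disjoint
#' support (a total difference), and complements Delta-Neq, which is
#' blind to *which* blocks are populated.
#'
#' @param p1,p2 `pb_profile` objects.
#' @param pairing optional data.frame with columns `pos1`, `pos2`.
#' @return data.frame with columns `pos1`, `pos2`, `delta_pb` in `[0, 2]`.
#' @export
delta_pb <- function(p1, p2, pairing = NULL) {
  stopifnot(inherits(p1, "pb_profile"), inherits(p2, "pb_profile"))
  al <- .align_positions(p1$resno[p1$assignable], p2$resno[p2$assignable],
                         pairing)
  i1 <- match(al$pos1, p1$resno)
  i2 <- match(al$pos2, p2$resno)
  d <- colSums(abs(p1$freq[, i1, drop = FALSE] - p2$freq[, i2, drop = FALSE]))
  data.frame(pos1 = al$pos1, pos2 = al$pos2, delta_pb = unname(d))
}

#' Export a PB frequency map
#'
#' Positions x blocks frequency table in the layout used for PB heat
#' maps: one row per block `a`..`p`, one column per position (author
#' numbers as column names), cells are frequencies (columns of
#' assignable positions sum to 1).
#'
#' @param profile a `pb_profile`.
#' @param path optional TSV output path (written with a provenance
#'   header via [write_tsv_provenance()]).
#' @param params named list recorded in the provenance header.
#' @return the 16 x n data.frame, invisibly when written.
#' @export
export_pb_map <- function(profile, path = NULL, params = list()) {
  df <- as.data.frame(profile$freq)
  names(df) <- profile$resno
  df <- cbind(pb = PB_LABELS, df)
  if (is.null(path)) return(df)
  write_tsv_provenance(df, path, params)
  invisible(df)
}
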