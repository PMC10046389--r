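# Protein Block assignment: each residue/frame with a complete 8-angle
# dihedral window is labelled with the prototype minimizing the RMSDA
# (root-mean-square deviation on angular values, shortest-arc wrapping).

# wrap a difference in degrees into (-180, 180]
.wrap180 <- function(d) {
  w <- d - 360 * round(d / 360)
  w[w == -180] <- 180
  w
}

#' Angular dissimilarity between a dihedral window and a prototype
#'
#' Root-mean-square deviation over the 8 angles of a Protein Block
#' window, with each difference wrapped to the shortest arc:
#' `sqrt(mean(wrap(window - prototype)^2))`, in degrees.  This is the
#' standard dissimilarity of the Protein Blocks literature.
#'
#' @param window numeric 8-vector of dihedrals (degrees); any `NA` makes
#'   the window unassignable and the result `NA`.
#' @param prototype numeric 8-vector (a row of [pb_reference()]).
#' @return dissimilarity in degrees, or `NA` if the window is incomplete.
#' @examples
#' ref <- pb_reference()
#' rmsda(ref["m", ], ref["m", ])          # 0
#' rmsda(ref["m", ] + 360, ref["m", ])    # 0 (periodicity)
#' @export
rmsda <- function(window, prototype) {
  if (anyNA(window)) return(NA_real_)
  sqrt(mean(.wrap180(window - prototype)^2))
}

# n x 8 matrix of windows for all residues of one frame (NA-padded)
.pb_windows <- function(phi_row, psi_row) {
  n <- length(phi_row)
  pad <- function(v, k) {
    if (k >= 0) c(v[-seq_len(k)], rep(NA_real_, k))
    else c(rep(NA_real_, -k), v[seq_len(n + k)])
  }
  cbind(pad(psi_row, -2), pad(phi_row, -1), pad(psi_row, -1),
        phi_row, psi_row,
        pad(phi_row, 1), pad(psi_row, 1), pad(phi_row, 2))
}

#' Assign Protein Blocks along a dihedral series
#'
#' For every frame and every residue whose 8-angle window
#' `(psi[i-2], phi[i-1], psi[i-1], phi[i], psi[i], phi[i+1], psi[i+1],
#' phi[i+2])` is fully defined (which requires residues `i-2..i+2`
#' in-chain), the residue is labelled with the Protein Block whose
#' prototype minimizes [rmsda()]; ties go to the alphabetically lowest
#' label.  All other positions -- in particular the first two and last
#' two residues of the chain -- are marked `"Z"` (unassignable).
#'
#' @param dihedrals a `dihedral_series` from [compute_phi_psi()].
#' @param table prototype table, by default [pb_reference()].
#' @return character matrix of class `pb_strings`
#'   (`n_frames x n_res`, entries in `a`..`p` or `Z`), columns named by
#'   author residue number.
#' @export
assign_pbs <- function(dihedrals, table = pb_reference()) {
  stopifnot(nrow(table) == 16L, ncol(table) == 8L)
  nf <- nrow(dihedrals$phi)
  nres <- ncol(dihedrals$phi)
  out <- matrix("Z", nf, nres, dimnames = list(NULL, dihedrals$resno))
  for (f in seq_len(nf)) {
    W <- .pb_windows(dihedrals$phi[f, ], dihedrals$psi[f, ])
    ok <- !apply(W, 1L, anyNA)
    if (!any(ok)) next
    Wok <- W[ok, , drop = FALSE]
    d2 <- vapply(seq_len(16L), function(p) {
      rowSums(.wrap180(Wok - matrix(table[p, ], nrow(Wok), 8, byrow = TRUE))^2)
    }, numeric(nrow(Wok)))
    if (!is.matrix(d2)) d2 <- matrix(d2, nrow = 1L)
    best <- max.col(-d2, ties.method = "first")
    out[f, ok] <- rownames(table)[best]
  }
  structure(out, class = c("pb_strings", "matrix"), resno = dihedrals$resno,
            chain = dihedrals$chain)
}

#' Export per-frame PB strings as text
#'
#' One fasta-like block per frame (`> frame <i> time_ps <t>` followed by
#' the PB string), the interchange format of existing PB tooling.
#'
#' @param pbs a `pb_strings` matrix from [assign_pbs()].
#' @param path output file; when `NULL` the lines are returned.
#' @param time_ps optional per-frame times for the headers.
#' @return the lines, invisibly when written to `path`.
#' @export
export_pb_strings <- function(pbs, path = NULL, time_ps = NULL) {
  nf <- nrow(pbs)
  if (is.null(time_ps)) time_ps <- 100 * (seq_len(nf) - 1)
  lines <- character(2L * nf)
  lines[c(TRUE, FALSE)] <- sprintf("> frame %d time_ps %.1f", seq_len(nf), time_ps)
  lines[c(FALSE, TRUE)] <- apply(pbs, 1L, paste, collapse = "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
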