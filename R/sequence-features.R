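# Sequence-level characterization of calreticulin C-domain variants:
# variant application, formal charge, counter-ion requirement, ER
# retention (KDEL) and CREAC/cysteine detection, helix content, and the
# summary feature table.

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Apply a simple protein variant to a fragment sequence
#'
#' Handles single-residue substitutions (`p.L367I`) and nonsense/stop
#' variants (`p.E389*`, truncating so the last retained residue is
#' author number `n - 1`).  Frameshift products (`fs` notations) must be
#' supplied as explicit sequences -- nucleotide-level frameshift
#' arithmetic is out of scope -- and raise an error pointing that out.
#'
#' @param wt_seq wild-type fragment as a single amino-acid string.
#' @param notation HGVS-like protein notation, e.g. `"p.E389*"`.
#' @param start author number of the first residue of `wt_seq`
#'   (352 for the calreticulin C-domain).
#' @return the edited sequence string.
#' @export
apply_simple_variant <- function(wt_seq, notation, start = 352L) {
  m <- regmatches(notation,
                  regexec("^p\\.([A-Z])([0-9]+)([A-Z*])$", notation))[[1]]
  if (length(m) == 0L) {
    if (grepl("fs", notation))
      stop("frameshift notation '", notation,
           "': supply the product as an explicit sequence")
    stop("cannot parse variant notation '", notation, "'")
  }
  ref <- m[2]; pos <- as.integer(m[3]); alt <- m[4]
  off <- pos - start + 1L
  if (off < 1L || off > nchar(wt_seq))
    stop("position ", pos, " outside the fragment (",
         start, "-", start + nchar(wt_seq) - 1L, ")")
  found <- substr(wt_seq, off, off)
  if (found != ref)
    stop("reference mismatch at ", pos, ": notation says ", ref,
         ", sequence has ", found)
  if (alt == "*") {
    if (off == 1L) stop("stop at the first fragment residue leaves an empty fragment")
    substr(wt_seq, 1L, off - 1L)
  } else {
    paste0(substr(wt_seq, 1L, off - 1L), alt,
           substr(wt_seq, off + 1L, nchar(wt_seq)))
  }
}

#' Net formal side-chain charge of a sequence
#'
#' `(#K + #R) - (#D + #E)` in elementary charges; histidine counts 0 and
#' termini are ignored.  This is the convention under which the
#' wild-type calreticulin C-domain fragment scores -26.
#'
#' @param seq amino-acid string.
#' @return signed integer.
#' @export
net_formal_charge <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  as.integer(sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E")))
}

#' Counter-ions needed to neutralize a net charge
#'
#' `ceiling(|charge| / |valence|)` ions of the requested species, or 0
#' when the species cannot neutralize the charge (same sign, or zero
#' charge).  Divalent calcium neutralizes a -26 system with 13 ions;
#' monovalent sodium needs 26; positively charged systems take chloride.
#'
#' @param charge signed integer net charge.
#' @param ion one of `"Ca2+"`, `"Na+"`, `"Cl-"`.
#' @return integer ion count.
#' @export
counterion_requirement <- function(charge, ion = c("Ca2+", "Na+", "Cl-")) {
  ion <- match.arg(ion)
  valence <- c("Ca2+" = 2L, "Na+" = 1L, "Cl-" = -1L)[[ion]]
  if (charge == 0L || sign(charge) == sign(valence)) return(0L)
  as.integer(ceiling(abs(charge) / abs(valence)))
}

#' ER retention signal detection
#'
#' `TRUE` iff the fragment terminates with the exact tetrapeptide KDEL
#' (the motif must be C-terminal; an internal or displaced KDEL does not
#' retain the protein in the endoplasmic reticulum).
#'
#' @param seq amino-acid string.
#' @return logical flag.
#' @export
detect_kdel <- function(seq) {
  endsWith(seq, "KDEL")
}

#' Cysteine count and CREAC motif detection
#'
#' Counts cysteines and tests whether the CREAC motif -- the
#' frameshift-specific C-terminal sequence whose two cysteines form the
#' inter-chain disulfide bridges of stable mutant dimers -- occurs near
#' the end of the sequence.  The default window of 12 residues covers
#' the motif plus the 7-residue C-terminal extension that follows it in
#' the mutant alternative reading frame.
#'
#' @param seq amino-acid string.
#' @param window number of C-terminal residues searched for `CREAC`.
#' @return list with `n_cys` (integer) and `has_creac` (logical).
#' @export
detect_creac_cysteines <- function(seq, window = 12L) {
  n_cys <- lengths(regmatches(seq, gregexpr("C", seq)))
  tail_seq <- substr(seq, max(1L, nchar(seq) - window + 1L), nchar(seq))
  list(n_cys = as.integer(n_cys), has_creac = grepl("CREAC", tail_seq))
}

#' Helical content as a percentage of the fragment
#'
#' `round(100 * sum(interval sizes, inclusive) / length)` for
#' non-overlapping author-number intervals annotated as helical.
#'
#' @param helix_intervals list of `c(start, end)` author-number pairs
#'   (inclusive), or `NULL`/empty for 0.
#' @param length fragment length in residues.
#' @return integer percentage in `[0, 100]`.
#' @export
helix_fraction <- function(helix_intervals, length) {
  if (is.null(helix_intervals) || length(helix_intervals) == 0L) return(0L)
  iv <- do.call(rbind, helix_intervals)
  if (any(iv[, 2L] < iv[, 1L])) stop("interval end before start")
  o <- order(iv[, 1L])
  iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
    stop("overlapping helix intervals")
  sizes <- iv[, 2L] - iv[, 1L] + 1L
  as.integer(round(100 * sum(sizes) / length))
}

#' Variant feature table
#'
#' One row per variant with the sequence-derived features: fragment
#' length, ER retention signal, net formal charge, helical content,
#' cysteine count, CREAC motif, the counter-ion species/count needed to
#' neutralize the system, and the dimer-capable flag (CREAC present,
#' i.e. disulfide-bridged dimerization possible).
#'
#' @param variants list of variant records as returned by
#'   [calr_variants()]: each a list with `id`, `class_label`,
#'   `notation`, `sequence`, `start`.
#' @param helix_annotations named list (by variant `id`) of helix
#'   interval lists as in [helix_fraction()]; missing ids get `NA`.
#' @return data.frame, one row per variant.
#' @export
build_feature_table <- function(variants, helix_annotations = list()) {
  rows <- lapply(variants, function(v) {
    cr <- detect_creac_cysteines(v$sequence)
    q <- net_formal_charge(v$sequence)
    species <- if (q < 0L) "Ca2+" else if (q > 0L) "Cl-" else "none"
    hx <- helix_annotations[[v$id]]
    data.frame(
      system = v$id, class = v$class_label, notation = v$notation,
      length = nchar(v$sequence),
      kdel = detect_kdel(v$sequence),
      charge = q,
      helix_percent = if (is.null(hx)) NA_integer_
                      else helix_fraction(hx, nchar(v$sequence)),
      n_cys = cr$n_cys,
      has_creac = cr$has_creac,
      counterion = species,
      counterion_n = if (species == "none") 0L
                     else counterion_requirement(q, species),
      dimer_capable = cr$has_creac,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
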