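# Bundled calreticulin C-domain sequences and annotations.
#
# The wild-type 352-417 fragment and the class A/B/C frameshift products
# are shipped as a plain-text FASTA fixture (see its headers for
# provenance); classes D and E are derived from the wild type at run
# time by applying their point-variant notations.

#' Read a FASTA file of fragment sequences
#'
#' Minimal FASTA input for sequence-feature work.  A `start=<n>` token in
#' a header sets the author number of the fragment's first residue
#' (default 352, the calreticulin C-domain convention).
#'
#' @param path FASTA file path.
#' @return named list of records, each with `id`, `sequence`, `start`.
#' @export
read_fragment_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA headers in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  recs <- lapply(seq_along(hdr), function(k) {
    h <- sub("^>", "", lines[hdr[k]])
    id <- strsplit(h, "[ |]")[[1]][1]
    start <- 352L
    m <- regmatches(h, regexec("start=([0-9]+)", h))[[1]]
    if (length(m)) start <- as.integer(m[2])
    seqs <- lines[(hdr[k] + 1L):ends[k]]
    seqs <- toupper(gsub("[^A-Za-z]", "", paste(seqs, collapse = "")))
    list(id = id, sequence = seqs, start = start)
  })
  names(recs) <- vapply(recs, `[[`, "", "id")
  recs
}

#' The wild-type calreticulin C-domain fragment
#'
#' Residues 352-417 of human calreticulin (the exon-9-encoded acidic
#' C-domain, from alanine 352 to leucine 417, ending in the KDEL ER
#' retention signal).
#'
#' @return list with `id`, `sequence`, `start`.
#' @export
calr_c_domain <- function() {
  f <- system.file("extdata", "calr_c_domain_variants.fasta",
                   package = "pbtraj", mustWork = TRUE)
  read_fragment_fasta(f)[["CALRwt"]]
}

#' The six calreticulin C-domain study systems
#'
#' Wild type plus the five variant classes: A (`p.L367Tfs*46`, canonical
#' type 1), B (`p.K385Nfs*47`, canonical type 2), C (`p.E380Dfs*51`),
#' D (`p.E389*`) and E (`p.L367I`).  Frameshift products (A, B, C) come
#' from the bundled FASTA fixture (reconstructed sequences; see the
#' fixture headers for provenance and caveats); the point variants D and
#' E are derived from the wild type via [apply_simple_variant()].
#'
#' @return named list of variant records (`id`, `class_label`,
#'   `notation`, `sequence`, `start`).
#' @export
calr_variants <- function() {
  f <- system.file("extdata", "calr_c_domain_variants.fasta",
                   package = "pbtraj", mustWork = TRUE)
  fx <- read_fragment_fasta(f)
  wt <- fx[["CALRwt"]]
  rec <- function(id, class_label, notation, sequence, start = 352L)
    list(id = id, class_label = class_label, notation = notation,
         sequence = sequence, start = start)
  list(
    CALRwt = rec("CALRwt", "wt", NA_character_, wt$sequence),
    CALRm_A = rec("CALRm_A", "A", "p.L367Tfs*46", fx[["CALRm_A"]]$sequence),
    CALRm_B = rec("CALRm_B", "B", "p.K385Nfs*47", fx[["CALRm_B"]]$sequence),
    CALRm_C = rec("CALRm_C", "C", "p.E380Dfs*51", fx[["CALRm_C"]]$sequence),
    CALRm_D = rec("CALRm_D", "D", "p.E389*",
                  apply_simple_variant(wt$sequence, "p.E389*")),
    CALRm_E = rec("CALRm_E", "E", "p.L367I",
                  apply_simple_variant(wt$sequence, "p.L367I"))
  )
}

#' Helix annotations for the study systems
#'
#' Helical intervals (author numbers, inclusive) as printed in the
#' narrative description of each system's dynamics.  Only class A's
#' interval (366-388 over a 60-residue fragment, 38 %) reproduces the
#' published helix-content column exactly; for the other systems the
#' printed boundaries and the published percentages disagree, a
#' documented discrepancy of the source data that this package does not
#' attempt to resolve.
#'
#' @return named list (by variant id) of interval lists.
#' @export
calr_helix_annotations <- function() {
  list(
    CALRwt  = list(c(352, 386)),
    CALRm_A = list(c(366, 388)),
    CALRm_B = list(c(354, 374), c(379, 414), c(417, 425)),
    CALRm_C = list(c(384, 406)),
    CALRm_D = list(c(353, 386)),
    CALRm_E = list(c(352, 386))
  )
}

#' Anchor-residue triplets for dimer distance analysis
#'
#' The per-system anchor positions used for inter-chain distance plots:
#' three author numbers spread along each chain.
#'
#' @return named list (by variant id) of integer triplets.
#' @export
calr_dimer_anchors <- function() {
  list(
    CALRwt  = c(356L, 371L, 386L),
    CALRm_A = c(366L, 385L, 400L),
    CALRm_B = c(366L, 400L, 419L),
    CALRm_D = c(352L, 370L, 388L),
    CALRm_E = c(356L, 371L, 386L)
  )
}
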