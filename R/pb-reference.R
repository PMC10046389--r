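#' The 16 Protein Block dihedral prototypes
#'
#' Returns the canonical reference table of the Protein Blocks structural
#' alphabet: 16 local backbone prototypes labelled `a` to `p`, each defined
#' by 8 dihedral angles spanning five consecutive residues,
#' `(psi[i-2], phi[i-1], psi[i-1], phi[i], psi[i], phi[i+1], psi[i+1],
#' phi[i+2])`, in degrees.  Block `m` is the alpha-helix core prototype and
#' block `d` the central beta-strand prototype; `a`-`c` are strand N-caps,
#' `e`-`f` strand C-caps, `g`-`j` coil, `k`-`l` helix N-caps and `n`-`p`
#' helix C-caps.
#'
#' The angle values are embedded verbatim from the original Protein Blocks
#' definition (de Brevern, Etchebest & Hazout 2000, Proteins 41:271-287),
#' as distributed with the PBxplore assignment tool.  They are constants of
#' the alphabet, not tunable parameters.
#'
#' @return A 16 x 8 numeric matrix.  Row names are the block labels
#'   `a`..`p`; column names are `psi_m2`, `phi_m1`, `psi_m1`, `phi_0`,
#'   `psi_0`, `phi_p1`, `psi_p1`, `phi_p2`.
#' @examples
#' ref <- pb_reference()
#' ref["m", c("phi_0", "psi_0")]  # helix-core central angles
#' @export
pb_reference <- function() {
  vals <- c(
    # psi-2    phi-1     psi-1     phi0      psi0      phi+1     psi+1     phi+2
     41.14,    75.53,    13.92,   -99.80,   131.88,   -96.27,   122.08,   -99.68,  # a
    108.24,   -90.12,   119.54,   -92.21,   -18.06,  -128.93,   147.04,   -99.90,  # b
    -11.61,  -105.66,    94.81,  -106.09,   133.56,  -106.93,   135.97,  -100.63,  # c
    141.98,  -112.79,   132.20,  -114.79,   140.11,  -111.05,   139.54,  -103.16,  # d
    133.25,  -112.37,   137.64,  -108.13,   133.00,   -87.30,   120.54,    77.40,  # e
    116.40,  -105.53,   129.32,   -96.68,   140.72,   -74.19,   -26.65,   -94.51,  # f
      0.40,   -81.83,     4.91,  -100.59,    85.50,   -71.65,   130.78,    84.98,  # g
    119.14,  -102.58,   130.83,   -67.91,   121.55,    76.25,    -2.95,   -90.88,  # h
    130.68,   -56.92,   119.26,    77.85,    10.42,   -99.43,   141.40,   -98.01,  # i
    114.32,  -121.47,   118.14,    82.88,  -150.05,   -83.81,    23.35,   -85.82,  # j
    117.16,   -95.41,   140.40,   -59.35,   -29.23,   -72.39,   -25.08,   -76.16,  # k
    139.20,   -55.96,   -32.70,   -68.51,   -26.09,   -74.44,   -22.60,   -71.74,  # l
    -39.62,   -64.73,   -39.52,   -65.54,   -38.88,   -66.89,   -37.76,   -70.19,  # m
    -35.34,   -65.03,   -38.12,   -66.34,   -29.51,   -89.10,    -2.91,    77.90,  # n
    -45.29,   -67.44,   -27.72,   -87.27,     5.13,    77.49,    30.71,   -93.23,  # o
    -27.09,   -86.14,     0.30,   -82.02,    19.12,  -124.90,   156.96,   -95.95   # p
  )
  m <- matrix(vals, nrow = 16, ncol = 8, byrow = TRUE)
  rownames(m) <- letters[1:16]
  colnames(m) <- c("psi_m2", "phi_m1", "psi_m1", "phi_0",
                   "psi_0", "phi_p1", "psi_p1", "phi_p2")
  m
}

#' @rdname pb_reference
#' @format NULL
#' @details `PB_LABELS` is the ordered vector of the 16 block labels.
#' @export
PB_LABELS <- letters[1:16]
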