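# Small systems built in code for the test suite.

# static trajectory of an ideal backbone with constant phi/psi,
# replicated over n_frames identical frames
static_backbone_traj <- function(n_res = 9, phi = -57, psi = -47,
                                 n_frames = 1, chain = "A",
                                 resno_start = 352L, with_cb = TRUE) {
  bb <- build_backbone(c(NA, rep(phi, n_res - 1)),
                       c(rep(psi, n_res - 1), NA),
                       resno_start = resno_start, chain = chain,
                       with_cb = with_cb)
  row <- as.numeric(t(bb$coords))
  trajectory(bb$atoms, matrix(rep(row, n_frames), nrow = n_frames,
                              byrow = TRUE),
             time_ps = 100 * (seq_len(n_frames) - 1), label = "static")
}

# manual topology: n_res CA-only residues on a line, plus optional het ions
ca_line_atoms <- function(n_res, chain = "A", resno_start = 1L) {
  data.frame(chain = chain,
             resno = resno_start + seq_len(n_res) - 1L,
             resname = "ALA", atom = "CA", element = "C",
             polymer = TRUE, stringsAsFactors = FALSE)
}

ion_atoms <- function(n, element = "Ca") {
  data.frame(chain = "X", resno = 9000L + seq_len(n),
             resname = toupper(element), atom = toupper(element),
             element = element, polymer = FALSE, stringsAsFactors = FALSE)
}

# coordinates helper: one frame from a list of xyz rows
xyz_row <- function(coords) as.numeric(t(coords))

# random proper rotation matrix (seeded by caller)
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply a rigid transform to every frame of a trajectory
transform_traj <- function(traj, R, shift = c(0, 0, 0)) {
  xyz <- t(apply(traj$xyz, 1, function(row) {
    co <- matrix(row, ncol = 3, byrow = TRUE)
    as.numeric(t(sweep(co %*% t(R), 2, shift, "+")))
  }))
  trajectory(traj$atoms, xyz, traj$time_ps, traj$label)
}

# random PB frequency vector (16 components summing to 1)
random_freq <- function() {
  x <- stats::rexp(16)
  x / sum(x)
}

# generic non-collinear CA arrangement (Kabsch fit is non-degenerate)
noncollinear_ca <- function(n) {
  cbind(10 * seq_len(n), 3 * sin(seq_len(n)), 2 * cos(1.7 * seq_len(n)))
}
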