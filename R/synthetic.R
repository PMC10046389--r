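# Ground-truth synthetic trajectory generation.
#
# These generators stand in for molecular-dynamics runs: they produce
# statistically controlled conformational ensembles with known
# per-position PB mixtures, scripted ion-binding schedules and scripted
# dimer separation -- no force field, no solvent, no physics.  Backbone
# coordinates are built from dihedrals by sequential internal-to-
# Cartesian (NeRF-style) construction with ideal geometry, so that
# recomputing phi/psi from the output reproduces the inputs.

# run code with a temporary RNG state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Ideal backbone geometry parameters
#'
#' Bond lengths (Angstrom), bond angles and the omega dihedral (degrees)
#' used by [build_backbone()]: N-CA 1.458, CA-C 1.525, C-N 1.329;
#' N-CA-C 111.2, CA-C-N 116.6, C-N-CA 121.7; omega 180 (trans peptide).
#'
#' @return named list of geometry constants.
#' @export
geometry_params <- function() {
  list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
       ang_n_ca_c = 111.2, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
       omega = 180)
}

# place atom d given a-b-c, |c-d| = bond, angle(b,c,d), dihedral(a,b,c,d)
.place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180
  chi <- dihedral_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- c(-bond * cos(th), bond * sin(th) * cos(chi),
               bond * sin(th) * sin(chi))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Build an ideal-geometry backbone from phi/psi angles
#'
#' Sequential NeRF-style construction of N, CA, C (and a pseudo
#' C-beta) positions from per-residue phi/psi dihedrals, with the
#' geometry of [geometry_params()] and trans (omega = 180) peptide
#' bonds.  `phi[1]` and `psi[n]` are geometrically undefined and
#' ignored; an undefined angle mid-chain is an error.  Recomputing
#' phi/psi from the output reproduces the inputs.
#'
#' @param phi,psi numeric vectors of equal length `n >= 2`, degrees.
#' @param params geometry constants, see [geometry_params()].
#' @param resno_start author number of the first residue.
#' @param chain chain identifier.
#' @param with_cb add an ideally placed C-beta pseudo-atom per residue
#'   (gives residues a side-chain heavy atom for ion targeting).
#' @return list with `atoms` (topology data.frame as in [trajectory()])
#'   and `coords` (`natoms x 3` matrix).
#' @export
build_backbone <- function(phi, psi, params = geometry_params(),
                           resno_start = 352L, chain = "A",
                           with_cb = TRUE) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  if (anyNA(phi[-1L]) || anyNA(psi[-n]))
    stop("undefined phi/psi angle mid-chain")
  p <- params
  N <- CA <- C <- CB <- matrix(NA_real_, n, 3L)
  # first residue in the xy-plane
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(p$b_n_ca, 0, 0)
  th <- p$ang_n_ca_c * pi / 180
  C[1L, ] <- CA[1L, ] + p$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    N[i, ] <- .place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                          p$b_c_n, p$ang_ca_c_n, psi[i - 1L])
    CA[i, ] <- .place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                           p$b_n_ca, p$ang_c_n_ca, p$omega)
    C[i, ] <- .place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                          p$b_ca_c, p$ang_n_ca_c, phi[i])
  }
  if (with_cb) {
    for (i in seq_len(n))
      CB[i, ] <- .place_atom(N[i, ], C[i, ], CA[i, ], 1.53, 110.1, 122.6)
  }
  per_res <- if (with_cb) c("N", "CA", "C", "CB") else c("N", "CA", "C")
  natoms <- length(per_res)
  atoms <- data.frame(
    chain = chain,
    resno = rep(resno_start + seq_len(n) - 1L, each = natoms),
    resname = "ALA",
    atom = rep(per_res, n),
    element = rep(c("N", "C", "C", if (with_cb) "C"), n),
    polymer = TRUE, stringsAsFactors = FALSE
  )
  coords <- matrix(NA_real_, n * natoms, 3L)
  for (i in seq_len(n)) {
    base <- (i - 1L) * natoms
    coords[base + 1L, ] <- N[i, ]
    coords[base + 2L, ] <- CA[i, ]
    coords[base + 3L, ] <- C[i, ]
    if (with_cb) coords[base + 4L, ] <- CB[i, ]
  }
  list(atoms = atoms, coords = coords)
}

#' Sample a trajectory from per-position PB mixtures
#'
#' Per frame and per position, a Protein Block is drawn from that
#' position's mixture and the position's own (phi, psi) are set to the
#' drawn prototype's central angles plus uniform jitter in
#' `[-jitter_deg, +jitter_deg]`; the frame's backbone is then built with
#' [build_backbone()].  Deterministic for a fixed seed.
#'
#' Because a PB window spans five residues, assignment of a position
#' depends on its neighbours' angles too.  With the default independent
#' per-position draws the generator produces flexible, high-entropy
#' ensembles, but the assigned label need not equal the drawn one at
#' positions whose neighbours were drawn differently.  With
#' `frame_coherent = TRUE` one draw per frame is shared by every
#' position, so interior windows are conformationally pure; mixtures
#' over the two context-free blocks `m` (helix) and `d` (strand) are
#' then recovered exactly up to multinomial sampling noise -- the
#' regime used for ground-truth recovery validation.
#'
#' @param n_res number of residues (>= 5 for any assignable position).
#' @param mixtures 16-vector (recycled across positions) or 16 x n_res
#'   matrix of PB mixtures, rows in `a`..`p` order, columns summing to 1.
#' @param jitter_deg half-width of the uniform angular jitter (degrees).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param stride_ps frame time stride (ps).
#' @param resno_start,chain,label passed to the topology.
#' @param frame_coherent draw one block per frame shared by all
#'   positions (requires identical mixture columns).
#' @return list with `trajectory` (a [trajectory()]) and `ground_truth`
#'   (list: `mixtures`, `sampled` frames x positions label matrix,
#'   `jitter_deg`, `seed`, `stride_ps`).
#' @export
sample_system <- function(n_res, mixtures, jitter_deg = 5, n_frames = 100,
                          seed = 1L, stride_ps = 100,
                          resno_start = 352L, chain = "A",
                          label = "synthetic", frame_coherent = FALSE) {
  ref <- pb_reference()
  if (is.null(dim(mixtures))) mixtures <- matrix(mixtures, 16L, n_res)
  stopifnot(nrow(mixtures) == 16L, ncol(mixtures) == n_res,
            jitter_deg >= 0)
  if (any(abs(colSums(mixtures) - 1) > 1e-9))
    stop("mixture columns must sum to 1")
  if (frame_coherent && any(abs(mixtures - mixtures[, 1L]) > 1e-12))
    stop("frame_coherent sampling requires identical mixture columns")
  rownames(mixtures) <- PB_LABELS
  .with_seed(seed, {
    sampled <- matrix(NA_character_, n_frames, n_res)
    xyz <- matrix(NA_real_, n_frames, 0L)
    atoms <- NULL
    for (f in seq_len(n_frames)) {
      lab <- if (frame_coherent)
        rep(sample(PB_LABELS, 1L, prob = mixtures[, 1L]), n_res)
      else vapply(seq_len(n_res), function(i)
        sample(PB_LABELS, 1L, prob = mixtures[, i]), character(1))
      sampled[f, ] <- lab
      phi <- ref[lab, "phi_0"] + stats::runif(n_res, -jitter_deg, jitter_deg)
      psi <- ref[lab, "psi_0"] + stats::runif(n_res, -jitter_deg, jitter_deg)
      bb <- build_backbone(phi, psi, resno_start = resno_start, chain = chain)
      if (f == 1L) {
        atoms <- bb$atoms
        xyz <- matrix(NA_real_, n_frames, 3L * nrow(atoms))
      }
      xyz[f, ] <- as.numeric(t(bb$coords))
    }
    traj <- trajectory(atoms, xyz, time_ps = stride_ps * (seq_len(n_frames) - 1),
                       label = label)
    list(trajectory = traj,
         ground_truth = list(mixtures = mixtures, sampled = sampled,
                             jitter_deg = jitter_deg, seed = seed,
                             stride_ps = stride_ps,
                             frame_coherent = frame_coherent))
  })
}

#' Rigid helix with flexible tails
#'
#' Canonical test system emulating a stable helix flanked by mobile
#' termini: positions inside `core_range` are pure helix block `m`,
#' tail positions draw from a broad coil mixture, so downstream RMSF
#' must rank the tails above the core.
#'
#' @param n_res total residues.
#' @param core_range `c(first, last)` 1-based positions of the rigid core.
#' @param tail_mixture 16-vector mixture for tail positions; default is
#'   uniform over the ten coil-associated blocks `a`..`j`.
#' @inheritParams sample_system
#' @return as [sample_system()]; `ground_truth` additionally carries
#'   `core_positions` and `tail_positions` (1-based).
#' @export
make_helix_with_tails <- function(n_res = 32L, core_range = c(9L, 24L),
                                  tail_mixture = NULL, jitter_deg = 5,
                                  n_frames = 100, seed = 1L,
                                  stride_ps = 100, resno_start = 352L,
                                  chain = "A", label = "helix_with_tails") {
  if (is.null(tail_mixture)) {
    tail_mixture <- rep(0, 16L)
    tail_mixture[1:10] <- 1 / 10      # blocks a..j
  }
  core <- seq(core_range[1L], core_range[2L])
  mix <- matrix(tail_mixture, 16L, n_res)
  mix[, core] <- 0
  mix[13L, core] <- 1                 # block m
  out <- sample_system(n_res, mix, jitter_deg, n_frames, seed,
                       stride_ps, resno_start, chain, label)
  out$ground_truth$core_positions <- core
  out$ground_truth$tail_positions <- setdiff(seq_len(n_res), core)
  out
}

#' Add scripted ions to a trajectory
#'
#' Appends one het atom per schedule row.  While "bound" (frames
#' `bind_frame..unbind_frame`, the latter `NA` for never-unbind) the ion
#' sits 2.0 Angstrom from a heavy atom of its target residue; while
#' unbound it is parked at least 15 Angstrom away from every protein
#' atom.  `bind_frame = NA` scripts an ion that never binds.
#'
#' @param traj a [trajectory()].
#' @param schedule data.frame with columns `target_resno`, `bind_frame`,
#'   `unbind_frame` (frame indices, 1-based).
#' @param element ion element symbol (default `"Ca"`).
#' @param seed RNG seed (ion approach directions).
#' @return a [trajectory()] with the ions appended; the schedule is
#'   attached as attribute `ground_truth`.
#' @export
add_ions <- function(traj, schedule, element = "Ca", seed = 1L) {
  stopifnot(all(c("target_resno", "bind_frame", "unbind_frame") %in%
                  names(schedule)))
  n_ion <- nrow(schedule)
  nf <- n_frames(traj)
  a <- traj$atoms
  .with_seed(seed, {
    dirs <- matrix(stats::rnorm(3L * n_ion), n_ion, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    ion_xyz <- matrix(NA_real_, nf, 3L * n_ion)
    for (f in seq_len(nf)) {
      co <- frame_coords(traj, f)
      centroid <- colMeans(co)
      r_max <- sqrt(max(rowSums(sweep(co, 2L, centroid)^2)))
      for (k in seq_len(n_ion)) {
        b <- schedule$bind_frame[k]; u <- schedule$unbind_frame[k]
        bound <- !is.na(b) && f >= b && (is.na(u) || f <= u)
        if (bound) {
          tr <- schedule$target_resno[k]
          ti <- which(a$polymer & a$resno == tr & a$element != "H")
          if (length(ti) == 0L) stop("target residue ", tr, " not found")
          anchor <- co[ti[length(ti)], ]      # last heavy atom (CB if present)
          pos <- anchor + 2.0 * dirs[k, ]
        } else {
          pos <- centroid + (r_max + 20 + 5 * k) * dirs[k, ]
        }
        ion_xyz[f, (3L * k - 2L):(3L * k)] <- pos
      }
    }
    ion_atoms <- data.frame(
      chain = "X", resno = 9000L + seq_len(n_ion),
      resname = toupper(element), atom = toupper(element),
      element = element, polymer = FALSE, stringsAsFactors = FALSE
    )
    out <- trajectory(rbind(a, ion_atoms), cbind(traj$xyz, ion_xyz),
                      traj$time_ps, traj$label)
    attr(out, "ground_truth") <- list(schedule = schedule,
                                      element = element, seed = seed)
    out
  })
}

#' Duplicate a monomer into a scripted dimer
#'
#' Chain 2 is a copy of the monomer placed at `initial_offset` Angstrom
#' along `axis`.  In `"stable"` mode it only receives small Gaussian
#' jitter; in `"separating"` mode it is additionally translated by
#' `rate` Angstrom per frame after `start_frame`, emulating chains that
#' drift apart to hundreds of Angstrom.
#'
#' @param traj a single-chain [trajectory()].
#' @param mode `"stable"` or `"separating"`.
#' @param rate separation speed in Angstrom/frame.
#' @param start_frame frame at which separation starts.
#' @param initial_offset initial inter-chain offset in Angstrom.
#' @param axis direction of the offset/separation (normalized internally).
#' @param jitter_sd per-coordinate Gaussian jitter on chain 2 (Angstrom).
#' @param seed RNG seed (jitter).
#' @return a two-chain [trajectory()]; the scripted scenario is attached
#'   as attribute `ground_truth`.
#' @export
make_dimer <- function(traj, mode = c("stable", "separating"), rate = 1,
                       start_frame = 1L, initial_offset = 30,
                       axis = c(1, 0, 0), jitter_sd = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  axis <- axis / sqrt(sum(axis^2))
  a <- traj$atoms
  ch1 <- a$chain[a$polymer][1L]
  ch2 <- if (ch1 == "A") "B" else "A"
  nf <- n_frames(traj)
  nat <- nrow(a)
  .with_seed(seed, {
    xyz2 <- matrix(NA_real_, nf, 3L * nat)
    for (f in seq_len(nf)) {
      co <- frame_coords(traj, f)
      disp <- initial_offset
      if (mode == "separating" && f > start_frame)
        disp <- disp + rate * (f - start_frame)
      co2 <- sweep(co, 2L, disp * axis, "+")
      if (jitter_sd > 0)
        co2 <- co2 + matrix(stats::rnorm(length(co2), 0, jitter_sd),
                            nrow(co2), 3L)
      xyz2[f, ] <- as.numeric(t(co2))
    }
    atoms2 <- a
    atoms2$chain <- ch2
    out <- trajectory(rbind(a, atoms2), cbind(traj$xyz, xyz2),
                      traj$time_ps, paste0(traj$label, "_dimer"))
    attr(out, "ground_truth") <- list(mode = mode, rate = rate,
                                      start_frame = start_frame,
                                      initial_offset = initial_offset,
                                      axis = axis, jitter_sd = jitter_sd,
                                      seed = seed)
    out
  })
}
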