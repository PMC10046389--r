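# Multi-model PDB reading/writing.  Fixed-width v3 columns; MODEL/ENDMDL
# blocks become frames.  Per-model times are carried in a
# "REMARK   6 TIME_PS <ps>" line (written by write_multimodel_pdb); files
# without it get the conventional 100 ps stride.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.normalize_element <- function(e) {
  e <- trimws(e)
  ifelse(nzchar(e),
         paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e)))),
         e)
}

.element_fallback <- function(name, record) {
  nm <- gsub("[^A-Za-z]", "", name)
  ifelse(record == "HETATM",
         .normalize_element(nm),                      # "CA" -> "Ca", "CL" -> "Cl"
         toupper(substr(nm, 1, 1)))                   # backbone/sidechain: C, N, O, S
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records yields a single-frame trajectory.  All models must list the
#' same atoms in the same order (a model with a deviating atom count is a
#' hard error naming the model index).  `HETATM` records (ions, water) are
#' kept as single-atom non-polymer residues; the element is parsed from
#' PDB columns 77-78, falling back to the atom name (so a bare calcium
#' `CA` HETATM still gets element `"Ca"`).
#'
#' @param path path to a PDB text file.
#' @param label system label stored on the trajectory (default: file name).
#' @return a [trajectory()].
#' @seealso [write_multimodel_pdb()]
#' @export
read_multimodel_pdb <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- rec == "MODEL "
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  model_of <- cumsum(is_model)
  if (!any(is_model)) model_of[] <- 1L
  model_of[model_of == 0L] <- 1L
  atom_lines <- lines[is_atom]
  atom_model <- model_of[is_atom]
  models <- sort(unique(atom_model))

  parse_block <- function(ln) {
    data.frame(
      record  = trimws(substr(ln, 1, 6)),
      atom    = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      chain   = trimws(substr(ln, 22, 22)),
      resno   = suppressWarnings(as.integer(substr(ln, 23, 26))),
      x = suppressWarnings(as.numeric(substr(ln, 31, 38))),
      y = suppressWarnings(as.numeric(substr(ln, 39, 46))),
      z = suppressWarnings(as.numeric(substr(ln, 47, 54))),
      element = trimws(substr(ln, 77, 78)),
      stringsAsFactors = FALSE
    )
  }

  first <- parse_block(atom_lines[atom_model == models[1L]])
  natoms <- nrow(first)
  elem <- .normalize_element(first$element)
  no_el <- !nzchar(elem)
  elem[no_el] <- .element_fallback(first$atom[no_el], first$record[no_el])
  atoms <- data.frame(
    chain = ifelse(nzchar(first$chain), first$chain, "A"),
    resno = first$resno,
    resname = first$resname,
    atom = first$atom,
    element = elem,
    polymer = first$record == "ATOM" & first$resname %in% .AA3,
    stringsAsFactors = FALSE
  )

  xyz <- matrix(NA_real_, nrow = length(models), ncol = 3L * natoms)
  for (k in seq_along(models)) {
    blk <- parse_block(atom_lines[atom_model == models[k]])
    if (nrow(blk) != natoms)
      stop("inconsistent atom count in MODEL ", k, ": ", nrow(blk),
           " atoms, expected ", natoms)
    co <- cbind(blk$x, blk$y, blk$z)
    if (any(is.na(co)))
      stop("missing coordinates in MODEL ", k)
    xyz[k, ] <- as.numeric(t(co))
  }

  # per-model times from REMARK ... TIME_PS lines, if present
  tp <- NULL
  trem <- grepl("TIME_PS", lines) & rec == "REMARK"
  if (sum(trem) == length(models)) {
    tp <- as.numeric(sub(".*TIME_PS\\s+", "", lines[trem]))
    if (any(is.na(tp))) tp <- NULL
  }
  trajectory(atoms, xyz, time_ps = tp, label = label)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL` block per frame, preceded by a `REMARK   6 TIME_PS` line so
#' the frame times survive a round trip.  Coordinates are written at PDB
#' precision (3 decimals).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  a <- traj$atoms
  record <- ifelse(a$polymer, "ATOM", "HETATM")
  # atom names shorter than 4 characters start in column 14
  name_field <- ifelse(nchar(a$atom) >= 4L, substr(a$atom, 1, 4),
                       sprintf(" %-3s", a$atom))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   6 %s TRAJECTORY %s",
                     "PBTRAJ", traj$label), con)
  for (k in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, k)
    writeLines(sprintf("REMARK   6 TIME_PS %.3f", traj$time_ps[k]), con)
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       record, seq_len(nrow(a)), name_field, "",
                       a$resname, a$chain, a$resno, "",
                       co[, 1], co[, 2], co[, 3], 1, 0,
                       toupper(a$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a whitespace-separated frame table as a trajectory
#'
#' Second trajectory dialect used for synthetic data: a plain text table
#' whose first column is the frame time in ps and whose remaining
#' `3 * natoms` columns are the flattened coordinates (x1 y1 z1 x2 ...)
#' in the topology order of `atoms`.  Lines starting with `#` are skipped.
#'
#' @param path path to the table.
#' @param atoms topology data.frame as in [trajectory()].
#' @param label system label.
#' @return a [trajectory()].
#' @export
read_frame_table <- function(path, atoms, label = basename(path)) {
  m <- unname(as.matrix(utils::read.table(path, comment.char = "#")))
  if (ncol(m) != 1L + 3L * nrow(atoms))
    stop("frame table has ", ncol(m) - 1L,
         " coordinate columns, expected ", 3L * nrow(atoms))
  trajectory(atoms, m[, -1L, drop = FALSE], time_ps = m[, 1L], label = label)
}

#' @rdname read_frame_table
#' @param traj a [trajectory()] to write.
#' @export
write_frame_table <- function(traj, path) {
  m <- cbind(traj$time_ps, traj$xyz)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_ps x1 y1 z1 ...", con)
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
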