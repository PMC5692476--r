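#' Built-in MARTINI phosphatidylcholine topology map
#'
#' Maps residue names to bead kinds for [read_gro()]. Lipid bead roles are
#' taken from the bead names themselves (`NC3`, `PO4`, `GL1`, `GL2`,
#' `C1A`...`C4B`); any residue name not listed as a lipid is treated as
#' protein.
#'
#' @param extra_lipids Additional residue names to treat as lipids.
#' @return Named character vector: residue name -> `"lipid"`.
#' @export
martini_pc_topology <- function(extra_lipids = character()) {
  lipids <- c("DUPC", "DLPC", "DTPC", "DMPC", "DPPC", "POPC", "DOPC",
              "PC2", "PC3", "PC4", extra_lipids)
  setNames(rep("lipid", length(lipids)), lipids)
}

#' Read GRO-format coordinate frames
#'
#' Parses fixed-column GRO records (positions in nm, converted to Angstrom
#' on read). Multiple concatenated frames are supported; every frame must
#' end with a box line. Residues are classed as lipid or protein via
#' `topology_map`; unknown residue names default to protein.
#'
#' @param path Path to a `.gro` file (single- or multi-frame).
#' @param topology_map Named character vector, residue name -> `"lipid"`;
#'   default [martini_pc_topology()].
#' @return A list of [cg_frame()] objects, one per frame.
#' @export
read_gro <- function(path, topology_map = martini_pc_topology()) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (i + 1L > length(lines)) {
      abort_input(sprintf("truncated GRO frame starting at line %d", i))
    }
    n_atoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n_atoms) || n_atoms <= 0) {
      abort_input(sprintf("invalid atom count at line %d", i + 1L))
    }
    last_atom <- i + 1L + n_atoms
    if (last_atom + 1L > length(lines)) {
      abort_input(sprintf(
        "missing box line: frame at line %d declares %d atoms", i, n_atoms))
    }
    atom_lines <- lines[(i + 2L):last_atom]
    bad <- which(nchar(atom_lines) < 44)
    if (length(bad) > 0) {
      abort_input(sprintf("malformed GRO atom record at line %d",
                          i + 1L + bad[1]))
    }
    resid <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
    resname <- trimws(substr(atom_lines, 6, 10))
    bead <- trimws(substr(atom_lines, 11, 15))
    x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad) > 0) {
      abort_input(sprintf("malformed GRO atom record at line %d",
                          i + 1L + bad[1]))
    }
    box <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[last_atom + 1L]), "\\s+")[[1]]))
    if (length(box) < 3 || any(is.na(box[1:3])) || any(box[1:3] <= 0)) {
      abort_input(sprintf("invalid box line at line %d", last_atom + 1L))
    }
    kind <- ifelse(resname %in% names(topology_map)[
      topology_map == "lipid"], "lipid", "protein")
    beads <- tibble(
      kind = kind, resid = resid, resname = resname, bead = bead,
      x = x * 10, y = y * 10, z = z * 10   # nm -> Angstrom
    )
    frames[[length(frames) + 1L]] <- cg_frame(beads, box[1:3] * 10)
    i <- last_atom + 2L
  }
  if (length(frames) == 0) abort_input("no frames found in GRO file")
  frames
}

#' Write a coarse-grained frame (or frames) in GRO format
#'
#' Positions are written in nm at the format's 3-decimal precision.
#'
#' @param frames A [cg_frame()] or list of them.
#' @param path Output path.
#' @param title Title line written per frame.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frames, path, title = "foldkit frame") {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  out <- character()
  for (fr in frames) {
    b <- fr$beads
    out <- c(out, title, sprintf("%5d", nrow(b)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     b$resid %% 100000L, b$resname, b$bead,
                     seq_len(nrow(b)) %% 100000L,
                     b$x / 10, b$y / 10, b$z / 10),
             sprintf("%10.5f%10.5f%10.5f",
                     fr$box[1] / 10, fr$box[2] / 10, fr$box[3] / 10))
  }
  writeLines(out, path)
  invisible(path)
}

#' Assemble frames into a trajectory table
#'
#' @param frames List of [cg_frame()] objects in time order.
#' @param times_us Frame times in microseconds (nondecreasing); defaults to
#'   a unit grid.
#' @param replica Replica identifier.
#' @return A tibble with columns `replica`, `time_us`, `frame`, suitable
#'   for [profile_trajectories()].
#' @export
as_trajectory <- function(frames, times_us = NULL, replica = "rep1") {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  if (length(frames) < 1) abort_input("need at least one frame")
  if (is.null(times_us)) times_us <- seq_along(frames)
  if (length(times_us) != length(frames) || any(diff(times_us) < 0)) {
    abort_input("`times_us` must be nondecreasing, one per frame")
  }
  tibble(replica = replica, time_us = times_us, frame = frames)
}
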