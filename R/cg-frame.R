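#' Construct a coarse-grained bilayer snapshot
#'
#' A `cg_frame` holds one coordinate snapshot of a planar bilayer system:
#' a bead table and an orthorhombic periodic box. The bilayer normal is the
#' z axis; the box is periodic in x and y only (solvent slabs cap z).
#' Lengths are in Angstroms throughout.
#'
#' Lipid beads follow MARTINI-style role names: one `PO4` phosphate bead per
#' lipid, glycerol beads `GL1`/`GL2`, and acyl-chain beads `C1A..C4A` /
#' `C1B..C4B` with 2, 3, or 4 beads per chain. Both chains of a lipid must
#' have the same bead count. Protein beads carry their author-numbered
#' residue indices so annular selections can be anchored on named residues.
#'
#' @param beads A data frame with columns `kind` (`"lipid"` or `"protein"`),
#'   `resid` (integer residue index), `resname`, `bead` (role name), and
#'   coordinates `x`, `y`, `z` in Angstroms.
#' @param box Numeric length-3 vector of box edge lengths (Angstroms).
#' @return An object of class `cg_frame` (list with `beads` and `box`).
#' @export
cg_frame <- function(beads, box) {
  if (!is.data.frame(beads)) abort_input("`beads` must be a data frame")
  beads <- as_tibble(beads)
  need <- c("kind", "resid", "resname", "bead", "x", "y", "z")
  if (!all(need %in% names(beads))) {
    abort_input(paste("`beads` must have columns",
                      paste(need, collapse = ", ")))
  }
  if (!is.numeric(box) || length(box) != 3 || any(box <= 0)) {
    abort_input("`box` must be three positive edge lengths (Angstrom)")
  }
  lip <- beads[beads$kind == "lipid", ]
  if (nrow(lip) > 0) {
    po4_per_lipid <- tapply(lip$bead == "PO4", lip$resid, sum)
    if (any(po4_per_lipid != 1)) {
      abort_input("every lipid must have exactly one PO4 bead")
    }
    nA <- tapply(grepl("^C[0-9]A$", lip$bead), lip$resid, sum)
    nB <- tapply(grepl("^C[0-9]B$", lip$bead), lip$resid, sum)
    if (any(nA != nB)) {
      abort_input("both acyl chains of a lipid must have the same bead count")
    }
  }
  structure(list(beads = beads, box = as.numeric(box)), class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  n_lip <- length(unique(x$beads$resid[x$beads$kind == "lipid"]))
  n_prot <- sum(x$beads$kind == "protein")
  cat(sprintf(
    "<cg_frame> %d lipids, %d protein beads, box %.1f x %.1f x %.1f A\n",
    n_lip, n_prot, x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Assign lipids to bilayer leaflets
#'
#' Partitions lipids into upper and lower leaflets by the position of the
#' PO4 bead relative to the midplane (the mean PO4 z over all lipids).
#'
#' @param frame A [cg_frame()].
#' @return The frame with a `leaflet` column (`"upper"`/`"lower"` for lipid
#'   beads, `NA` for protein) added to `beads`.
#' @export
assign_leaflets <- function(frame) {
  stopifnot(inherits(frame, "cg_frame"))
  beads <- frame$beads
  po4 <- beads[beads$kind == "lipid" & beads$bead == "PO4", ]
  if (nrow(po4) < 2) abort_input("need at least 2 lipids to assign leaflets")
  midplane <- mean(po4$z)
  lf <- ifelse(po4$z >= midplane, "upper", "lower")
  if (length(unique(lf)) < 2) {
    abort_input("not a bilayer: all phosphates on one side of the midplane")
  }
  map <- setNames(lf, po4$resid)
  beads$leaflet <- ifelse(beads$kind == "lipid",
                          unname(map[as.character(beads$resid)]),
                          NA_character_)
  frame$beads <- beads
  frame
}

# xy-periodic minimum-image distances between two coordinate matrices
# (n x 3 and m x 3); z is non-periodic. Returns an n x m matrix.
pbc_dist <- function(a, b, box) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  sqrt(dx^2 + dy^2 + dz^2)
}

# Minimum-image displacement components for paired coordinates.
pbc_disp <- function(from, to, box) {
  d <- to - from
  d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
  d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
  d
}
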