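#' Generate synthetic coarse-grained bilayer trajectories with known truth
#'
#' Builds planar two-leaflet MARTINI-style bilayers around an embedded
#' cylindrical "barrel" of protein beads, with an imposed radial
#' thinning/disorder perturbation centered on a designated seam residue,
#' and emits replicate multi-frame trajectories together with the exact
#' ground truth the analysis should recover.
#'
#' Each leaflet is a jittered square lattice of lipids. The local leaflet
#' separation at lateral position `p` is
#' \deqn{T(p) = T_{bulk} - \Delta \cdot g(r)}
#' where `r` is the xy distance from `p` to the seam anchor point and
#' `g(r)` is a plateau profile: `g = 1` for `r <= thinning_plateau`,
#' decaying as a Gaussian with width `thinning_width` beyond. The plateau
#' covers the annular selection shell, so the mean thickness of lipids
#' within the default 12-Angstrom shell of the seam residue is
#' `bulk_thickness - thinning_depth` by construction, while the opposite
#' side of the barrel and the bulk are essentially unperturbed.
#'
#' Acyl chains are built bead by bead with a deterministic polar (cone)
#' angle from the bilayer normal and a uniform random azimuth per bond, so
#' every bond's order parameter is exactly
#' \eqn{S = 0.5 (3\cos^2\theta_c - 1)} for the local cone angle
#' \eqn{\theta_c(r)}, which follows the same plateau profile between
#' `cone_angle_bulk` and `cone_angle_seam`. Frames are i.i.d. redraws of
#' jitter and azimuths, not time-correlated dynamics.
#'
#' @param chain_beads Acyl beads per chain: 2, 3 or 4 (thin to thick
#'   lipids).
#' @param n_lipids_per_leaflet Lattice sites per leaflet before carving out
#'   the protein (default 196; about 390 lipids total remain, matching
#'   typical CG system sizes).
#' @param lattice_spacing Lattice constant in Angstrom (default 7.5,
#'   about 56 A^2 per lipid).
#' @param bulk_thickness Unperturbed phosphate-phosphate separation in
#'   Angstrom; default depends on `chain_beads` (28/36/44 for 2/3/4 beads).
#' @param thinning_depth Seam thinning Delta in Angstrom (default 12).
#' @param thinning_plateau Radius of full-depth thinning around the seam
#'   anchor, Angstrom (default 13, covering the 12-Angstrom annular shell).
#' @param thinning_width Gaussian decay width beyond the plateau, Angstrom.
#' @param cone_angle_bulk,cone_angle_seam Chain cone angles in degrees away
#'   from the seam and at the seam (defaults 20 and 40: the seam is more
#'   disordered).
#' @param positional_jitter Gaussian jitter SD applied to lattice xy and
#'   phosphate z, Angstrom.
#' @param bond_length Distance between consecutive chain beads, Angstrom.
#' @param protein_radius Barrel cylinder radius, Angstrom.
#' @param n_frames Frames per replica (spread over `duration_us`).
#' @param n_replicas Independent replicas (different derived seeds).
#' @param duration_us Nominal trajectory duration in microseconds.
#' @param seed Integer master seed.
#' @return A tibble with columns `replica`, `time_us`, `frame` (list of
#'   [cg_frame()]), carrying a `ground_truth` attribute: a list with
#'   `seam_residue`, `opposite_residue`, `bulk_thickness`,
#'   `seam_thickness`, `s_bulk`, `s_seam`, and the generator settings.
#' @examples
#' traj <- generate_bilayer_trajectory(n_frames = 2, n_replicas = 1,
#'                                     seed = 1)
#' attr(traj, "ground_truth")$seam_residue
#' @export
generate_bilayer_trajectory <- function(chain_beads = 4,
                                        n_lipids_per_leaflet = 196,
                                        lattice_spacing = 7.5,
                                        bulk_thickness = NULL,
                                        thinning_depth = 12,
                                        thinning_plateau = 13,
                                        thinning_width = 4,
                                        cone_angle_bulk = 20,
                                        cone_angle_seam = 40,
                                        positional_jitter = 0.5,
                                        bond_length = 4.7,
                                        protein_radius = 20,
                                        n_frames = 30,
                                        n_replicas = 5,
                                        duration_us = 3,
                                        seed = 1) {
  if (!chain_beads %in% 2:4) abort_input("`chain_beads` must be 2, 3 or 4")
  if (is.null(bulk_thickness)) {
    bulk_thickness <- c(`2` = 28, `3` = 36, `4` = 44)[[as.character(chain_beads)]]
  }
  if (thinning_depth >= bulk_thickness) {
    abort_input("`thinning_depth` must be smaller than `bulk_thickness`")
  }
  if (cone_angle_bulk < 0 || cone_angle_bulk > 90 ||
      cone_angle_seam < 0 || cone_angle_seam > 90) {
    abort_input("cone angles must lie in [0, 90] degrees")
  }
  n_side <- round(sqrt(n_lipids_per_leaflet))
  box_xy <- n_side * lattice_spacing
  if (protein_radius >= box_xy / 2) {
    abort_input("`protein_radius` must be smaller than half the box")
  }
  box_z <- bulk_thickness + 2 * (chain_beads + 2) * bond_length + 20
  z_mid <- box_z / 2
  cx <- box_xy / 2
  cy <- box_xy / 2

  # Lipid sites per leaflet: two concentric rings packed against the
  # barrel wall (annular shells) plus a square lattice covering the rest
  # of the box. Annular lipids sit closer together than bulk lattice
  # lipids, as they do around a real membrane protein.
  ring_r <- protein_radius + 4 + c(0, 6.5)
  ring_sites <- do.call(rbind, lapply(ring_r, function(rr) {
    n <- max(8L, floor(2 * pi * rr / 6.5))
    ph <- 2 * pi * (seq_len(n) - 1) / n
    cbind(x = cx + rr * cos(ph), y = cy + rr * sin(ph))
  }))
  g <- (seq_len(n_side) - 0.5) * lattice_spacing
  sites <- expand.grid(x = g, y = g)
  r_center <- sqrt((sites$x - cx)^2 + (sites$y - cy)^2)
  sites <- sites[r_center > max(ring_r) + 4.5, ]
  sites <- rbind(as.data.frame(ring_sites), sites)
  n_lip_leaf <- nrow(sites)

  # protein: one residue per azimuthal column of beads spanning the membrane
  n_cols <- max(16L, ceiling(2 * pi * protein_radius / 5))
  phi <- 2 * pi * (seq_len(n_cols) - 1) / n_cols
  z_levels <- seq(-bulk_thickness / 2 - 3, bulk_thickness / 2 + 3, by = 5)
  prot_resid0 <- 2L * n_lip_leaf           # lipid resids come first
  seam_col <- 1L                           # azimuth 0
  opposite_col <- which.min(abs(phi - pi))
  seam_xy <- c(cx + protein_radius, cy)

  prot <- tibble(
    kind = "protein",
    resid = rep(prot_resid0 + seq_len(n_cols), each = length(z_levels)),
    resname = "BARL",
    bead = rep(paste0("BB", seq_along(z_levels)), times = n_cols),
    x = rep(cx + protein_radius * cos(phi), each = length(z_levels)),
    y = rep(cy + protein_radius * sin(phi), each = length(z_levels)),
    z = rep(z_mid + z_levels, times = n_cols)
  )

  plateau_profile <- function(r) {
    ifelse(r <= thinning_plateau, 1,
           exp(-(r - thinning_plateau)^2 / (2 * thinning_width^2)))
  }
  theta_of <- function(r) {
    (cone_angle_bulk +
       (cone_angle_seam - cone_angle_bulk) * plateau_profile(r)) * pi / 180
  }
  resname <- paste0("PC", chain_beads)

  build_frame <- function() {
    frames_leaf <- purrr::map_dfr(c(upper = 1, lower = -1), function(sgn) {
      x <- sites$x + rnorm(n_lip_leaf, 0, positional_jitter)
      y <- sites$y + rnorm(n_lip_leaf, 0, positional_jitter)
      x <- x %% box_xy
      y <- y %% box_xy
      r_seam <- sqrt((x - seam_xy[1])^2 + (y - seam_xy[2])^2)
      thick <- bulk_thickness - thinning_depth * plateau_profile(r_seam)
      z_po4 <- z_mid + sgn * thick / 2 +
        rnorm(n_lip_leaf, 0, positional_jitter)
      theta <- theta_of(r_seam)

      # glycerol beads sit below (toward midplane from) the phosphate
      gl1 <- cbind(x, y, z_po4 - sgn * 3)
      gl2 <- cbind(x + 2, y, z_po4 - sgn * 3)
      lip_id <- seq_len(n_lip_leaf) + if (sgn == 1) 0L else n_lip_leaf

      chain_tbl <- function(gl, chain) {
        pos <- gl
        out <- vector("list", chain_beads)
        for (b in seq_len(chain_beads)) {
          az <- runif(n_lip_leaf, 0, 2 * pi)
          step <- cbind(bond_length * sin(theta) * cos(az),
                        bond_length * sin(theta) * sin(az),
                        -sgn * bond_length * cos(theta))
          pos <- pos + step
          out[[b]] <- tibble(
            kind = "lipid", resid = lip_id, resname = resname,
            bead = paste0("C", b, chain),
            x = pos[, 1], y = pos[, 2], z = pos[, 3])
        }
        bind_rows(out)
      }

      bind_rows(
        tibble(kind = "lipid", resid = lip_id, resname = resname,
               bead = "PO4", x = x, y = y, z = z_po4),
        tibble(kind = "lipid", resid = lip_id, resname = resname,
               bead = "GL1", x = gl1[, 1], y = gl1[, 2], z = gl1[, 3]),
        tibble(kind = "lipid", resid = lip_id, resname = resname,
               bead = "GL2", x = gl2[, 1], y = gl2[, 2], z = gl2[, 3]),
        chain_tbl(gl1, "A"),
        chain_tbl(gl2, "B")
      )
    })
    cg_frame(bind_rows(frames_leaf, prot), c(box_xy, box_xy, box_z))
  }

  times <- seq_len(n_frames) / n_frames * duration_us
  traj <- purrr::map_dfr(seq_len(n_replicas), function(rep_i) {
    set.seed(derive_seed(seed, rep_i))
    tibble(
      replica = paste0("rep", rep_i),
      time_us = times,
      frame = purrr::map(seq_len(n_frames), function(i) build_frame())
    )
  })

  p2 <- function(theta_deg) {
    0.5 * (3 * cos(theta_deg * pi / 180)^2 - 1)
  }
  attr(traj, "ground_truth") <- list(
    seam_residue = prot_resid0 + seam_col,
    opposite_residue = prot_resid0 + opposite_col,
    bulk_thickness = bulk_thickness,
    seam_thickness = bulk_thickness - thinning_depth,
    thinning_depth = thinning_depth,
    s_bulk = p2(cone_angle_bulk),
    s_seam = p2(cone_angle_seam),
    cone_angle_bulk = cone_angle_bulk,
    cone_angle_seam = cone_angle_seam,
    chain_beads = chain_beads,
    positional_jitter = positional_jitter,
    n_lipids = 2L * n_lip_leaf,
    seam_xy = seam_xy
  )
  traj
}
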