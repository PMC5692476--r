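# Fixture builders used across the suite. Everything is constructed in
# code; no binary fixtures.

# A single transient tibble from a function of time.
make_transient <- function(f, times = 0:600, replicate = "r1",
                           condition = "test", batch = "b1") {
  tibble::tibble(
    time_s = times, signal = f(times),
    condition = condition, replicate = replicate, batch = batch
  )
}

# Deterministic flat bilayer: lipids on a small grid, phosphates at
# +/- separation/2 about z_mid, chains straight down (theta = 0).
flat_bilayer_frame <- function(n_side = 4, separation = 23,
                               chain_beads = 2, spacing = 8,
                               z_mid = 40, box_z = 80,
                               protein = FALSE, protein_resid = 9001L) {
  g <- (seq_len(n_side) - 0.5) * spacing
  sites <- expand.grid(x = g, y = g)
  box <- c(n_side * spacing, n_side * spacing, box_z)
  rows <- list()
  lip <- 0L
  for (sgn in c(1, -1)) {
    for (i in seq_len(nrow(sites))) {
      lip <- lip + 1L
      x <- sites$x[i]; y <- sites$y[i]
      z_po4 <- z_mid + sgn * separation / 2
      add <- function(bead, bx, by, bz) {
        tibble::tibble(kind = "lipid", resid = lip, resname = "PC2",
                       bead = bead, x = bx, y = by, z = bz)
      }
      part <- list(add("PO4", x, y, z_po4),
                   add("GL1", x, y, z_po4 - sgn * 3),
                   add("GL2", x + 2, y, z_po4 - sgn * 3))
      for (b in seq_len(chain_beads)) {
        part <- c(part,
                  list(add(paste0("C", b, "A"), x, y,
                           z_po4 - sgn * (3 + 4.7 * b)),
                       add(paste0("C", b, "B"), x + 2, y,
                           z_po4 - sgn * (3 + 4.7 * b))))
      }
      rows <- c(rows, part)
    }
  }
  if (protein) {
    cx <- box[1] / 2
    rows <- c(rows, list(tibble::tibble(
      kind = "protein", resid = protein_resid, resname = "BARL",
      bead = paste0("BB", 1:3), x = cx, y = cx,
      z = z_mid + c(-5, 0, 5))))
  }
  foldkit::cg_frame(dplyr::bind_rows(rows), box)
}

# Minimal frame holding lipids with explicitly placed G-1 bonds; used for
# order-parameter limit checks. `directions` is an n x 3 matrix of bond
# vectors from GL1 to C1A (and GL2 to C1B).
bond_direction_frame <- function(directions, box = c(100, 100, 100)) {
  n <- nrow(directions)
  base_z <- 50
  rows <- lapply(seq_len(n), function(i) {
    x <- (i %% 10) * 9 + 1
    y <- (i %/% 10) * 9 + 1
    gl <- c(x, y, base_z + ifelse(i %% 2 == 0, 6, -6))
    d <- directions[i, ]
    dplyr::bind_rows(
      tibble::tibble(kind = "lipid", resid = i, resname = "PC2",
                     bead = "PO4", x = gl[1], y = gl[2], z = gl[3] + 2),
      tibble::tibble(kind = "lipid", resid = i, resname = "PC2",
                     bead = "GL1", x = gl[1], y = gl[2], z = gl[3]),
      tibble::tibble(kind = "lipid", resid = i, resname = "PC2",
                     bead = "GL2", x = gl[1] + 2, y = gl[2], z = gl[3]),
      tibble::tibble(kind = "lipid", resid = i, resname = "PC2",
                     bead = "C1A", x = gl[1] + d[1], y = gl[2] + d[2],
                     z = gl[3] + d[3]),
      tibble::tibble(kind = "lipid", resid = i, resname = "PC2",
                     bead = "C1B", x = gl[1] + 2 + d[1], y = gl[2] + d[2],
                     z = gl[3] + d[3])
    )
  })
  foldkit::cg_frame(dplyr::bind_rows(rows), box)
}

# Random lipid + protein frame for selection property tests.
random_frame <- function(n_lipids = 30, n_protein_beads = 6,
                         box = c(60, 60, 80), seed = 1) {
  set.seed(seed)
  lip <- dplyr::bind_rows(lapply(seq_len(n_lipids), function(i) {
    x <- runif(1, 0, box[1]); y <- runif(1, 0, box[2])
    z <- sample(c(30, 50), 1) + runif(1, -2, 2)
    dplyr::bind_rows(
      tibble::tibble(kind = "lipid", resid = as.integer(i), resname = "PC2",
                     bead = c("PO4", "GL1", "GL2", "C1A", "C1B"),
                     x = x + c(0, 0, 2, 0, 2),
                     y = y,
                     z = z + c(0, -3, -3, -7, -7))
    )
  }))
  prot <- tibble::tibble(
    kind = "protein",
    resid = n_lipids + rep(1:2, each = ceiling(n_protein_beads / 2))[
      seq_len(n_protein_beads)],
    resname = "BARL", bead = paste0("BB", seq_len(n_protein_beads)),
    x = runif(n_protein_beads, 0, box[1]),
    y = runif(n_protein_beads, 0, box[2]),
    z = runif(n_protein_beads, 30, 50)
  )
  foldkit::cg_frame(dplyr::bind_rows(lip, prot), box)
}

# Independent brute-force annular/bulk selection oracle: explicit double
# loop over beads with scalar minimum-image arithmetic.
brute_force_select <- function(frame, mode, anchor = NULL, cutoff) {
  beads <- frame$beads
  po4 <- beads[beads$kind == "lipid" & beads$bead == "PO4", ]
  ref <- if (mode == "near_residue") {
    beads[beads$kind == "protein" & beads$resid == anchor, ]
  } else {
    beads[beads$kind == "protein", ]
  }
  if (nrow(ref) == 0 && mode == "bulk") return(as.integer(sort(po4$resid)))
  keep <- logical(nrow(po4))
  for (i in seq_len(nrow(po4))) {
    dmin <- Inf
    for (j in seq_len(nrow(ref))) {
      dx <- po4$x[i] - ref$x[j]
      dx <- dx - frame$box[1] * round(dx / frame$box[1])
      dy <- po4$y[i] - ref$y[j]
      dy <- dy - frame$box[2] * round(dy / frame$box[2])
      dz <- po4$z[i] - ref$z[j]
      dmin <- min(dmin, sqrt(dx^2 + dy^2 + dz^2))
    }
    keep[i] <- if (mode == "near_residue") dmin <= cutoff else dmin > cutoff
  }
  as.integer(sort(po4$resid[keep]))
}
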