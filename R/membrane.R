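#' Select annular or bulk lipids around a membrane protein
#'
#' Reproduces the two selection rules used to contrast the lipid environment
#' at a protein residue with bulk membrane:
#' \itemize{
#'   \item `near_residue`: lipids whose PO4 bead lies within `cutoff`
#'     (default 12 Angstrom, inclusive) of any bead of `anchor_residue` —
#'     the annular shell around that residue;
#'   \item `bulk`: lipids whose PO4 bead is strictly further than `cutoff`
#'     (default 30 Angstrom) from every protein bead.
#' }
#' Distances use the xy-periodic minimum image; z is non-periodic.
#' Selections are per frame: recompute on every snapshot.
#'
#' @param frame A [cg_frame()].
#' @param mode `"near_residue"` or `"bulk"`.
#' @param anchor_residue Protein residue index (required for
#'   `near_residue`).
#' @param cutoff Distance cutoff in Angstrom; defaults to 12 for
#'   `near_residue` and 30 for `bulk`.
#' @param lipid_reference Which lipid beads the `near_residue` distance is
#'   measured from: `"PO4"` (default, consistent with the phosphate-based
#'   bulk criterion) or `"any_bead"` (whole lipid).
#' @return Sorted integer vector of selected lipid residue indices, with
#'   attributes `mode`, `anchor_residue`, `cutoff`.
#' @export
select_lipids <- function(frame, mode = c("near_residue", "bulk"),
                          anchor_residue = NULL, cutoff = NULL,
                          lipid_reference = c("PO4", "any_bead")) {
  stopifnot(inherits(frame, "cg_frame"))
  mode <- match.arg(mode)
  lipid_reference <- match.arg(lipid_reference)
  if (is.null(cutoff)) cutoff <- if (mode == "near_residue") 12 else 30
  check_number(cutoff, "cutoff", positive = TRUE)
  beads <- frame$beads
  po4 <- beads[beads$kind == "lipid" & beads$bead == "PO4", ]
  po4_xyz <- as.matrix(po4[, c("x", "y", "z")])

  if (mode == "near_residue") {
    if (is.null(anchor_residue)) {
      abort_input("`anchor_residue` is required for near_residue selection")
    }
    anchor <- beads[beads$kind == "protein" & beads$resid == anchor_residue, ]
    if (nrow(anchor) == 0) {
      abort_input(sprintf("protein residue %s not found in frame",
                          anchor_residue))
    }
    ref <- if (lipid_reference == "PO4") po4 else
      beads[beads$kind == "lipid", ]
    d <- pbc_dist(as.matrix(ref[, c("x", "y", "z")]),
                  as.matrix(anchor[, c("x", "y", "z")]), frame$box)
    near <- unique(ref$resid[apply(d, 1, min) <= cutoff])
    keep <- po4$resid %in% near
  } else {
    prot <- beads[beads$kind == "protein", ]
    if (nrow(prot) == 0) {
      keep <- rep(TRUE, nrow(po4))
    } else {
      d <- pbc_dist(po4_xyz, as.matrix(prot[, c("x", "y", "z")]), frame$box)
      keep <- apply(d, 1, min) > cutoff
    }
  }
  structure(sort(po4$resid[keep]),
            mode = mode, anchor_residue = anchor_residue, cutoff = cutoff)
}

#' Phosphate-based membrane thickness for a lipid selection
#'
#' Thickness is the difference between the mean PO4 z of the selected
#' upper-leaflet lipids and the mean PO4 z of the selected lower-leaflet
#' lipids. Each leaflet must contribute at least `min_per_leaflet` lipids;
#' otherwise the frame yields `NA` (excluded from any aggregation).
#'
#' @param frame A [cg_frame()] (leaflets assigned on the fly if absent).
#' @param lipids Integer vector of lipid residue indices (e.g. from
#'   [select_lipids()]); `NULL` uses all lipids.
#' @param min_per_leaflet Minimum lipids per leaflet (default 3).
#' @return Thickness in Angstrom, or `NA_real_` if a leaflet is
#'   underpopulated.
#' @export
membrane_thickness <- function(frame, lipids = NULL, min_per_leaflet = 3) {
  stopifnot(inherits(frame, "cg_frame"))
  if (!"leaflet" %in% names(frame$beads)) frame <- assign_leaflets(frame)
  po4 <- frame$beads[frame$beads$kind == "lipid" &
                       frame$beads$bead == "PO4", ]
  if (!is.null(lipids)) po4 <- po4[po4$resid %in% lipids, ]
  z_up <- po4$z[po4$leaflet == "upper"]
  z_lo <- po4$z[po4$leaflet == "lower"]
  if (length(z_up) < min_per_leaflet || length(z_lo) < min_per_leaflet) {
    return(NA_real_)
  }
  mean(z_up) - mean(z_lo)
}

# Bond table for one frame: one row per (lipid, chain, bond) with its
# second-Legendre order parameter S = 0.5 (3 cos^2 theta - 1), theta the
# angle between the bond vector and the z axis. Bonds per chain: G-1
# (glycerol bead to first chain bead), then 1-2, 2-3, 3-4 as the chain
# length allows. Zero-length bonds are dropped.
frame_bond_table <- function(frame) {
  beads <- frame$beads[frame$beads$kind == "lipid", ]
  key <- paste(beads$resid, beads$bead)
  pos <- as.matrix(beads[, c("x", "y", "z")])
  rownames(pos) <- key
  resids <- unique(beads$resid)

  out <- list()
  for (chain in c("A", "B")) {
    gl <- if (chain == "A") "GL1" else "GL2"
    chain_beads <- paste0("C", 1:4, chain)
    present <- vapply(chain_beads,
                      function(b) any(beads$bead == b), logical(1))
    n_chain <- sum(present)
    if (n_chain == 0) next
    seq_beads <- c(gl, chain_beads[seq_len(n_chain)])
    labels <- c("G-1", "1-2", "2-3", "3-4")[seq_len(n_chain)]
    for (i in seq_len(n_chain)) {
      from_key <- paste(resids, seq_beads[i])
      to_key <- paste(resids, seq_beads[i + 1])
      ok <- from_key %in% rownames(pos) & to_key %in% rownames(pos)
      if (!any(ok)) next
      d <- pbc_disp(pos[from_key[ok], , drop = FALSE],
                    pos[to_key[ok], , drop = FALSE], frame$box)
      len2 <- rowSums(d^2)
      nz <- len2 > 0
      s <- 0.5 * (3 * d[nz, 3]^2 / len2[nz] - 1)
      out[[length(out) + 1L]] <- tibble(
        resid = resids[ok][nz], chain = chain,
        bond = labels[i], s = s)
    }
  }
  if (length(out) == 0) {
    return(tibble(resid = integer(), chain = character(),
                  bond = character(), s = numeric()))
  }
  bind_rows(out)
}

#' Acyl-chain order parameters for a lipid selection
#'
#' For every selected lipid, computes the second-Legendre order parameter
#' \deqn{S = 0.5\,(3 \cos^2\theta - 1)}
#' for each bond along both acyl chains, where \eqn{\theta} is the angle
#' between the bond vector and the bilayer normal (z). Bonds are labeled
#' `G-1` (glycerol bead to first chain bead) and `1-2`, `2-3`, `3-4` between
#' consecutive chain beads, up to the chain length present in the system.
#' The two chains are pooled, so one value is reported per bond label.
#'
#' @inheritParams membrane_thickness
#' @return A tibble with columns `bond`, `order_parameter` (mean S over
#'   selected lipids and both chains; always in `[-0.5, 1]`), and `n_bonds`.
#' @export
order_parameters <- function(frame, lipids = NULL) {
  stopifnot(inherits(frame, "cg_frame"))
  bonds <- frame_bond_table(frame)
  if (!is.null(lipids)) bonds <- bonds[bonds$resid %in% lipids, ]
  if (nrow(bonds) == 0) {
    return(tibble(bond = character(), order_parameter = numeric(),
                  n_bonds = integer()))
  }
  bonds %>%
    group_by(bond) %>%
    summarise(order_parameter = mean(s), n_bonds = dplyr::n(),
              .groups = "drop") %>%
    arrange(match(bond, c("G-1", "1-2", "2-3", "3-4")))
}

#' Local vs bulk membrane profile over replicate trajectories
#'
#' Runs the full annular-lipid analysis over a set of replicate
#' trajectories: for each post-burn-in frame, lipids are selected around
#' each anchor residue (within `cutoff`) and as bulk (further than
#' `bulk_cutoff` from any protein bead); phosphate-based thickness and
#' per-bond order parameters are computed per selection, time-averaged per
#' replica, then summarized as mean and sample SD across replicas. With
#' the defaults, a trajectory covering 3 microseconds with burn-in 1/6 is
#' analysed over its final 2.5 microseconds.
#'
#' @param trajectories A tibble with columns `replica`, `time_us`, and
#'   `frame` (a list column of [cg_frame()] objects), e.g. from
#'   [generate_bilayer_trajectory()].
#' @param anchors Named integer vector of anchor residue indices, e.g.
#'   `c(seam = 808, opposite = 613)`; names label the selections.
#' @param cutoff Annular cutoff in Angstrom (default 12).
#' @param bulk_cutoff Bulk distance threshold in Angstrom (default 30).
#' @param burn_in_fraction Fraction of initial frames discarded per replica
#'   (default 1/6).
#' @param min_per_leaflet Minimum lipids per leaflet for a thickness value.
#' @return An object of class `foldkit_membrane_profile`: a list with
#'   `summary` (tibble: `selection`, `metric`, `bond`, `mean`, `sd`,
#'   `n_replicas`), `per_replica` (tibble of replica time-averages), and
#'   `settings`. Supports [tidy()] and [autoplot()].
#' @export
profile_trajectories <- function(trajectories, anchors,
                                 cutoff = 12, bulk_cutoff = 30,
                                 burn_in_fraction = 1 / 6,
                                 min_per_leaflet = 3) {
  if (!is.data.frame(trajectories) ||
      !all(c("replica", "time_us", "frame") %in% names(trajectories))) {
    abort_input(
      "`trajectories` must have columns `replica`, `time_us`, `frame`")
  }
  if (length(anchors) > 0 && is.null(names(anchors))) {
    names(anchors) <- paste0("near_", anchors)
  }
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    abort_input("`burn_in_fraction` must be in [0, 1)")
  }
  sel_names <- c(names(anchors), "bulk")

  per_rep <- list()
  bond_sets <- list()
  for (rep_id in unique(trajectories$replica)) {
    tr <- trajectories[trajectories$replica == rep_id, ]
    tr <- tr[order(tr$time_us), ]
    n_f <- nrow(tr)
    n_drop <- floor(burn_in_fraction * n_f + 1e-9)
    frames <- tr$frame[(n_drop + 1L):n_f]

    acc <- list()
    for (fr in frames) {
      fr <- assign_leaflets(fr)
      bonds <- frame_bond_table(fr)
      sels <- c(
        lapply(anchors, function(a) {
          select_lipids(fr, "near_residue", anchor_residue = a,
                        cutoff = cutoff)
        }),
        list(bulk = select_lipids(fr, "bulk", cutoff = bulk_cutoff))
      )
      for (sn in sel_names) {
        lipids <- sels[[sn]]
        th <- membrane_thickness(fr, lipids,
                                 min_per_leaflet = min_per_leaflet)
        bsub <- bonds[bonds$resid %in% lipids, ]
        op <- if (nrow(bsub) > 0) {
          stats::aggregate(s ~ bond, data = bsub, FUN = mean)
        } else {
          data.frame(bond = character(), s = numeric())
        }
        acc[[length(acc) + 1L]] <- bind_rows(
          tibble(selection = sn, metric = "thickness",
                 bond = NA_character_, value = th),
          tibble(selection = sn, metric = "order_parameter",
                 bond = op$bond, value = op$s)
        )
      }
    }
    rep_tbl <- bind_rows(acc) %>%
      group_by(selection, metric, bond) %>%
      summarise(value = mean(value, na.rm = TRUE), .groups = "drop") %>%
      mutate(replica = rep_id, .before = 1)
    per_rep[[length(per_rep) + 1L]] <- rep_tbl
    bond_sets[[length(bond_sets) + 1L]] <-
      sort(unique(rep_tbl$bond[!is.na(rep_tbl$bond)]))
  }
  if (length(unique(bond_sets)) > 1) {
    abort_input("replicas expose different bond sets; topologies must match")
  }
  per_rep <- bind_rows(per_rep)
  summary <- per_rep %>%
    group_by(selection, metric, bond) %>%
    summarise(
      mean = mean(value),
      sd = if (dplyr::n() > 1) stats::sd(value) else 0,
      n_replicas = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(match(selection, sel_names), metric,
            match(bond, c("G-1", "1-2", "2-3", "3-4")))

  structure(
    list(summary = summary, per_replica = per_rep,
         settings = list(anchors = anchors, cutoff = cutoff,
                         bulk_cutoff = bulk_cutoff,
                         burn_in_fraction = burn_in_fraction,
                         min_per_leaflet = min_per_leaflet)),
    class = "foldkit_membrane_profile"
  )
}

#' @export
print.foldkit_membrane_profile <- function(x, ...) {
  cat(sprintf("Membrane profile over %d replica(s)\n",
              max(x$summary$n_replicas)))
  print(x$summary, n = Inf)
  invisible(x)
}
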