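#' Selection of an aromatic-ring atom group
#'
#' @param chain_id chain of the residue.
#' @param residue_number residue number (author numbering).
#' @param ring_atoms atom names forming the ring; default is the Trp indole
#'   (9 atoms).
#' @return an object of class `"ring_selection"`.
#' @export
ring_selection <- function(chain_id, residue_number,
                           ring_atoms = c("CG", "CD1", "CD2", "NE1", "CE2",
                                          "CE3", "CZ2", "CZ3", "CH2")) {
  if (length(ring_atoms) < 3L) stop("a ring needs at least 3 atoms")
  structure(list(chain_id = chain_id,
                 residue_number = as.integer(residue_number),
                 ring_atoms = as.character(ring_atoms)),
            class = "ring_selection")
}

.ring_indices <- function(traj, ring) {
  sel <- data.frame(chain_id = ring$chain_id,
                    residue_number = ring$residue_number,
                    atom_name = ring$ring_atoms, stringsAsFactors = FALSE)
  resolve_selection(traj, sel, what = "ring")
}

#' Per-frame distance between two ring centroids
#'
#' The centroid of each ring is the unweighted mean of its atom coordinates;
#' the series is the per-frame Euclidean distance between the two centroids
#' (e.g. the W25 ligand indole vs the receptor's W214 indole).
#'
#' @param traj a [trajectory()].
#' @param a,b [ring_selection()]s resolvable in the topology.
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
centroid_distance_series <- function(traj, a, b) {
  ia <- .ring_indices(traj, a)
  ib <- .ring_indices(traj, b)
  cen <- function(ix) {
    cbind(rowMeans(traj$xyz[, 3L * ix - 2L, drop = FALSE]),
          rowMeans(traj$xyz[, 3L * ix - 1L, drop = FALSE]),
          rowMeans(traj$xyz[, 3L * ix, drop = FALSE]))
  }
  d <- cen(ia) - cen(ib)
  sqrt(rowSums(d^2))
}

#' Summarize a per-frame distance (or angle) distribution
#'
#' Median uses the midpoint rule for even n; the mode is the center of the
#' most populated histogram bin (left-closed bins centered on multiples of
#' `bin_width`; ties resolve to the lowest bin).
#'
#' @param series non-empty numeric vector (NAs dropped with a message).
#' @param bin_width histogram bin width; default 0.1 resolves typical
#'   distance-reporting granularity.
#' @return an object of class `"distribution_summary"`: list with `n`,
#'   `median`, `mode`, `min`, `max`, `bin_width`.
#' @export
summarize_distribution <- function(series, bin_width = 0.1) {
  if (anyNA(series)) {
    message("dropping ", sum(is.na(series)), " missing values")
    series <- series[!is.na(series)]
  }
  if (!length(series)) stop("empty series")
  stopifnot(bin_width > 0)
  ctr <- floor(series / bin_width + 0.5)      # index of bin centered on k*bw
  ctr <- ctr - min(ctr) + 1L
  counts <- tabulate(ctr)
  mode <- (which.max(counts) + min(floor(series / bin_width + 0.5)) - 1L) *
    bin_width
  structure(list(n = length(series), median = stats::median(series),
                 mode = mode, min = min(series), max = max(series),
                 bin_width = bin_width),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d  median = %.3g  mode = %.3g  range = [%.3g, %.3g]  (bin %.3g)\n",
    x$n, x$median, x$mode, x$min, x$max, x$bin_width))
  invisible(x)
}

#' Four-atom torsion specification
#'
#' @param atoms data.frame of exactly 4 rows with `chain_id`,
#'   `residue_number`, `atom_name`, in bonded order (e.g. N, CA, CB, CG for
#'   chi1).
#' @return an object of class `"dihedral_spec"`.
#' @export
dihedral_spec <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) == 4L)
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key)) stop("dihedral atoms must be distinct")
  structure(list(atoms = atoms), class = "dihedral_spec")
}

#' Convenience chi1 spec (N-CA-CB-CG) for a residue
#' @param chain_id,residue_number the residue.
#' @param cg_name name of the fourth atom (default `"CG"`).
#' @return a [dihedral_spec()].
#' @export
chi1_spec <- function(chain_id, residue_number, cg_name = "CG") {
  dihedral_spec(data.frame(
    chain_id = chain_id, residue_number = as.integer(residue_number),
    atom_name = c("N", "CA", "CB", cg_name), stringsAsFactors = FALSE))
}

.row_cross <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' Per-frame signed torsion angle
#'
#' Standard IUPAC signed torsion of four points, in degrees in
#' `(-180, 180]`.  Frames where the first or last three atoms are collinear
#' have no defined torsion; those frames are returned as `NA` with a warning.
#'
#' @param traj a [trajectory()].
#' @param spec a [dihedral_spec()].
#' @return numeric vector of angles (degrees), one per frame.
#' @export
dihedral_series <- function(traj, spec) {
  stopifnot(inherits(spec, "dihedral_spec"))
  idx <- resolve_selection(traj, spec$atoms, what = "dihedral")
  P <- lapply(idx, function(i)
    traj$xyz[, c(3L * i - 2L, 3L * i - 1L, 3L * i), drop = FALSE])
  b1 <- P[[2L]] - P[[1L]]
  b2 <- P[[3L]] - P[[2L]]
  b3 <- P[[4L]] - P[[3L]]
  n1 <- .row_cross(b1, b2)
  n2 <- .row_cross(b2, b3)
  bad <- sqrt(rowSums(n1^2)) < 1e-9 | sqrt(rowSums(n2^2)) < 1e-9
  b2n <- b2 / sqrt(rowSums(b2^2))
  ang <- atan2(rowSums(.row_cross(n1, n2) * b2n),
               rowSums(n1 * n2)) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  if (any(bad)) {
    warning(sum(bad), " frame(s) with collinear atoms; torsion undefined")
    ang[bad] <- NA_real_
  }
  ang
}

#' Classify a chi1 torsion into rotamer classes
#'
#' Fixed 120-degree sectors centered on the canonical rotamers:
#' gauche(-) at -60 (sector `[-120, 0)`), gauche(+) at +60 (`[0, 120)`),
#' antiperiplanar at 180 (the rest of the circle).  Angles are first
#' normalized to `(-180, 180]`, so the classes partition the circle and are
#' 360-degree periodic.
#'
#' @param angle numeric vector of torsions in degrees.
#' @return character vector with values `"gauche_minus"`, `"gauche_plus"`,
#'   `"antiperiplanar"` (`NA` propagates).
#' @export
classify_rotamer <- function(angle) {
  a <- ((angle + 180) %% 360) - 180
  a[!is.na(a) & a == -180] <- 180
  out <- rep(NA_character_, length(a))
  out[!is.na(a) & a >= -120 & a < 0] <- "gauche_minus"
  out[!is.na(a) & a >= 0 & a < 120] <- "gauche_plus"
  out[!is.na(a) & (a >= 120 | a < -120)] <- "antiperiplanar"
  out
}

#' Geometric contact specification
#'
#' Hydrogen bonds use a heavy-atom donor-acceptor distance cutoff plus a
#' D-H...A angle cutoff (the angle at the hydrogen); if a donor has no
#' hydrogen listed the criterion downgrades to distance-only with a message.
#' Salt bridges use any cation-group nitrogen to anion-group oxygen distance.
#'
#' Defaults (3.5 Angstrom / 120 degrees for H-bonds, 4.0 Angstrom for salt
#' bridges) follow common MD-analysis conventions.
#'
#' @param kind `"hbond"` or `"saltbridge"`.
#' @param donors data.frame with `chain_id`, `residue_number`, `atom_name`
#'   and (for hbond, optional) `hydrogen_name`; for salt bridges these are
#'   the cation-group nitrogens.
#' @param acceptors data.frame with `chain_id`, `residue_number`,
#'   `atom_name`; for salt bridges the anion-group oxygens.
#' @param distance_cutoff Angstrom; default 3.5 (hbond) or 4.0 (saltbridge).
#' @param angle_cutoff degrees (hbond only).
#' @return an object of class `"contact_spec"`.
#' @export
contact_spec <- function(kind = c("hbond", "saltbridge"), donors, acceptors,
                         distance_cutoff = NULL, angle_cutoff = 120) {
  kind <- match.arg(kind)
  distance_cutoff <- distance_cutoff %||% if (kind == "hbond") 3.5 else 4.0
  stopifnot(distance_cutoff > 0, angle_cutoff > 0,
            is.data.frame(donors), is.data.frame(acceptors))
  if (!"hydrogen_name" %in% names(donors)) donors$hydrogen_name <- NA_character_
  structure(list(kind = kind, donors = donors, acceptors = acceptors,
                 distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "contact_spec")
}

# logical frames x (donor, acceptor) pair matrix of satisfied contacts
.contact_pair_matrix <- function(traj, spec, frames) {
  di <- resolve_selection(traj, spec$donors, what = "donor")
  ai <- resolve_selection(traj, spec$acceptors, what = "acceptor")
  hi <- rep(NA_integer_, length(di))
  if (spec$kind == "hbond") {
    has_h <- !is.na(spec$donors$hydrogen_name)
    if (any(has_h)) {
      hsel <- spec$donors[has_h, c("chain_id", "residue_number")]
      hsel$atom_name <- spec$donors$hydrogen_name[has_h]
      hi[has_h] <- resolve_selection(traj, hsel, what = "donor hydrogen")
    }
    if (any(!has_h))
      message("donor(s) without hydrogen: distance-only criterion used")
  }
  coords <- function(i) traj$xyz[frames, c(3L * i - 2L, 3L * i - 1L, 3L * i),
                                 drop = FALSE]
  ok <- matrix(FALSE, length(frames), 0L)
  for (p in seq_along(di)) {
    for (q in seq_along(ai)) {
      if (di[p] == ai[q]) next
      D <- coords(di[p]); A <- coords(ai[q])
      hit <- sqrt(rowSums((D - A)^2)) <= spec$distance_cutoff
      if (spec$kind == "hbond" && !is.na(hi[p])) {
        H <- coords(hi[p])
        u <- D - H; v <- A - H
        cosang <- rowSums(u * v) /
          (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
        hit <- hit & acos(pmin(pmax(cosang, -1), 1)) * 180 / pi >=
          spec$angle_cutoff
      }
      ok <- cbind(ok, hit)
    }
  }
  ok
}

.retained_frames <- function(traj, equilibration_discard) {
  stopifnot(equilibration_discard >= 0, equilibration_discard < 1)
  nf <- n_frames(traj)
  drop <- floor(equilibration_discard * nf)
  frames <- seq.int(drop + 1L, nf)
  if (!length(frames)) stop("no frames retained after equilibration discard")
  frames
}

#' Fraction of frames in which a contact is present
#'
#' A frame counts when ANY donor-acceptor pair of the spec meets the
#' geometric criterion (see [contact_spec()]).  Optionally discards an
#' initial fraction of frames as equilibration.
#'
#' @param traj a [trajectory()].
#' @param spec a [contact_spec()].
#' @param equilibration_discard fraction of initial frames dropped
#'   (`0 <= x < 1`, default 0).
#' @return an object of class `"occupancy_result"`: list with `fraction` in
#'   `[0, 1]`, `n_frames` (retained), `equilibration_discard`, and the
#'   per-frame count of satisfied pairs (`pair_counts`).
#' @export
contact_occupancy <- function(traj, spec, equilibration_discard = 0) {
  frames <- .retained_frames(traj, equilibration_discard)
  ok <- .contact_pair_matrix(traj, spec, frames)
  counts <- if (ncol(ok)) rowSums(ok) else rep(0L, length(frames))
  structure(list(fraction = mean(counts >= 1L), n_frames = length(frames),
                 equilibration_discard = equilibration_discard,
                 pair_counts = counts),
            class = "occupancy_result")
}

#' Fraction of frames with at least k simultaneous hydrogen bonds
#'
#' As [contact_occupancy()] but a frame counts only when at least `k`
#' donor-acceptor pairs qualify simultaneously; `k = 1` reduces to
#' [contact_occupancy()].
#'
#' @inheritParams contact_occupancy
#' @param k minimum simultaneous pair count.
#' @return an `"occupancy_result"`.
#' @export
count_multiple_hbonds <- function(traj, spec, k = 2,
                                  equilibration_discard = 0) {
  stopifnot(k >= 1)
  frames <- .retained_frames(traj, equilibration_discard)
  ok <- .contact_pair_matrix(traj, spec, frames)
  counts <- if (ncol(ok)) rowSums(ok) else rep(0L, length(frames))
  structure(list(fraction = mean(counts >= k), n_frames = length(frames),
                 equilibration_discard = equilibration_discard,
                 pair_counts = counts, k = k),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("occupancy: %.1f%% of %d frames%s\n", 100 * x$fraction,
              x$n_frames,
              if (!is.null(x$k)) sprintf(" (>= %d simultaneous pairs)", x$k)
              else ""))
  invisible(x)
}

.default_fit_selection <- function(traj, ref) {
  a <- traj$atoms[traj$atoms$atom_name == "CA", ]
  b <- ref$atoms[ref$atoms$atom_name == "CA", ]
  ka <- paste(a$chain_id, a$residue_number)
  kb <- paste(b$chain_id, b$residue_number)
  common <- a[ka %in% kb, c("chain_id", "residue_number")]
  common$atom_name <- "CA"
  common
}

#' Mean backbone RMSD of a selection against a reference ensemble
#'
#' Each frame is least-squares superposed onto the reference ensemble's
#' average structure using `fit_selection` (the reference frames are first
#' mutually superposed on the same selection, then averaged); the RMSD is
#' then computed over `measure_selection` and averaged over frames.  Used to
#' quantify how far, e.g., the receptor-immersed N-terminal ligand segment
#' drifts from its reference-complex position.
#'
#' @param traj,ref [trajectory()]s sharing the selected atoms.
#' @param fit_selection data.frame (`chain_id`, `residue_number`,
#'   `atom_name`) of atoms used for superposition; default: all C-alpha
#'   atoms common to both topologies.
#' @param measure_selection atoms over which the RMSD is computed; default:
#'   the fit selection.
#' @return mean RMSD in Angstrom (numeric scalar) with attribute
#'   `"per_frame"`.
#' @export
segment_rmsd_vs_reference <- function(traj, ref, fit_selection = NULL,
                                      measure_selection = NULL) {
  fit_selection <- fit_selection %||% .default_fit_selection(traj, ref)
  measure_selection <- measure_selection %||% fit_selection
  if (!nrow(fit_selection)) stop("empty fit selection")
  ft <- resolve_selection(traj, fit_selection, what = "fit")
  fr <- resolve_selection(ref, fit_selection, what = "fit (reference)")
  mt <- resolve_selection(traj, measure_selection, what = "measure")
  mr <- resolve_selection(ref, measure_selection, what = "measure (reference)")

  ref_xyz <- ref$xyz
  if (nrow(ref_xyz) > 1L) {
    ref_xyz <- bio3d::fit.xyz(fixed = ref$xyz[1L, ], mobile = ref$xyz,
                              fixed.inds = xyz_inds(fr),
                              mobile.inds = xyz_inds(fr))
  }
  ref_avg <- colMeans(ref_xyz)

  fitted <- bio3d::fit.xyz(fixed = ref_avg, mobile = traj$xyz,
                           fixed.inds = xyz_inds(fr),
                           mobile.inds = xyz_inds(ft))
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1L)
  dif <- fitted[, xyz_inds(mt), drop = FALSE] -
    matrix(ref_avg[xyz_inds(mr)], nrow(fitted), 3L * length(mt),
           byrow = TRUE)
  per_frame <- sqrt(rowSums(dif^2) / length(mt))
  structure(mean(per_frame), per_frame = per_frame)
}

#' Number of conformational clusters covering most of an ensemble
#'
#' Leader-style (gromos) clustering on pairwise fitted C-alpha RMSD:
#' repeatedly take the frame with the most neighbors within `rmsd_cutoff` as
#' a cluster center (ties to the earliest frame), remove the cluster, and
#' repeat.  Returns the minimal number of clusters, in decreasing population
#' order, whose cumulative population reaches `coverage` of all frames.
#'
#' @param traj a [trajectory()].
#' @param rmsd_cutoff neighbor cutoff in Angstrom (> 0).
#' @param coverage population fraction to cover (default 0.95).
#' @param selection optional atom selection data.frame; default all C-alpha.
#' @return integer count, with attribute `"cluster_sizes"` (all cluster
#'   populations in formation order).
#' @export
cluster_coverage_count <- function(traj, rmsd_cutoff, coverage = 0.95,
                                   selection = NULL) {
  stopifnot(rmsd_cutoff > 0, coverage > 0, coverage <= 1)
  idx <- if (is.null(selection)) atom_select(traj, elety = "CA")
         else resolve_selection(traj, selection, what = "cluster")
  if (!length(idx)) stop("no atoms selected for clustering")
  nf <- n_frames(traj)
  xi <- xyz_inds(idx)
  R <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    R[i, ] <- bio3d::rmsd(traj$xyz[i, ], traj$xyz, a.inds = xi, b.inds = xi,
                          fit = TRUE)
  }
  R <- (R + t(R)) / 2  # fitting is symmetric up to round-off

  remaining <- seq_len(nf)
  sizes <- integer()
  while (length(remaining)) {
    nb <- rowSums(R[remaining, remaining, drop = FALSE] <= rmsd_cutoff)
    center <- remaining[which.max(nb)]
    members <- remaining[R[center, remaining] <= rmsd_cutoff]
    sizes <- c(sizes, length(members))
    remaining <- setdiff(remaining, members)
  }
  cum <- cumsum(sort(sizes, decreasing = TRUE))
  count <- which(cum >= coverage * nf)[1L]
  structure(as.integer(count), cluster_sizes = sizes)
}
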