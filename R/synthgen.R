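#' Specification of a quasi-rigid-body system
#'
#' Describes a chain built from rigid bodies connected by flexible linkers,
#' used by [generate_hinge_trajectory()] to emulate trajectories composed of
#' quasi-rigid parts with internal jitter and large inter-body hinge motion.
#'
#' The hinge pivot of each joint is displaced laterally off the chain axis
#' (by `hinge_offset`, direction random per joint per seed) and the rotation
#' axis is perpendicular to both the chain axis and that offset.  A pivot on
#' the chain axis would leave near-hinge inter-body distances invariant to
#' second order in the hinge angle (rotation preserves distances to the
#' pivot), which no amplitude can overcome; a lever-arm pivot at the body
#' interface periphery — as in real domain hinges — makes every cross-body
#' distance fluctuate in proportion to the hinge amplitude.
#'
#' Linker residues are flexible in two ways: isotropic per-atom jitter with
#' their own (typically large) sigma, and — when a linker sits between two
#' bodies — a per-frame, per-residue random position along the chord between
#' its two anchor atoms (the flanking body termini).  A floppy tether between
#' two rigid domains sweeps the whole inter-domain gap rather than staying
#' put; were it pinned to a template, the linker residues adjacent to the
#' stationary body would fluctuate only by their jitter, whose folded
#' distance distribution at short separations has a standard deviation well
#' below the per-axis sigma, making border attachment a coin flip instead of
#' a property of the motion.
#'
#' @param bodies list of integer vectors of residue numbers (author
#'   numbering), one per rigid body; each body needs >= 3 residues (>=
#'   `cln + 2` recommended so segmentation is well-posed).
#' @param internal_jitter per-body isotropic per-atom Gaussian sigma in
#'   Angstrom (recycled).
#' @param hinge_amplitude per-joint hinge angle standard deviation in degrees
#'   (recycled over the `length(bodies) - 1` joints).
#' @param linkers list of integer vectors of residue numbers forming flexible
#'   linkers (may be empty).
#' @param linker_jitter per-linker Gaussian sigma in Angstrom (recycled).
#' @param hinge_offset lateral pivot displacement in Angstrom.
#' @return an object of class `"rigid_body_spec"`.
#' @export
rigid_body_spec <- function(bodies, internal_jitter = 0.2,
                            hinge_amplitude = 30, linkers = list(),
                            linker_jitter = 3, hinge_offset = 12) {
  stopifnot(is.list(bodies), length(bodies) >= 1L)
  bodies <- lapply(bodies, function(b) as.integer(sort(b)))
  linkers <- lapply(linkers, function(l) as.integer(sort(l)))
  if (any(vapply(bodies, length, 1L) < 3L))
    stop("every body needs at least 3 residues")
  all_res <- unlist(c(bodies, linkers))
  if (anyDuplicated(all_res))
    stop("overlapping residue ranges: residue ",
         all_res[duplicated(all_res)][1L], " appears twice")
  # order bodies along the chain
  bodies <- bodies[order(vapply(bodies, min, 1L))]
  nb <- length(bodies)
  internal_jitter <- rep_len(as.numeric(internal_jitter), nb)
  if (any(internal_jitter < 0)) stop("internal_jitter must be >= 0")
  hinge_amplitude <- rep_len(as.numeric(hinge_amplitude), max(nb - 1L, 1L))
  if (any(hinge_amplitude < 0)) stop("hinge_amplitude must be >= 0")
  linker_jitter <- rep_len(as.numeric(linker_jitter),
                           max(length(linkers), 1L))
  structure(list(bodies = bodies, internal_jitter = internal_jitter,
                 hinge_amplitude = hinge_amplitude, linkers = linkers,
                 linker_jitter = linker_jitter,
                 hinge_offset = as.numeric(hinge_offset)),
            class = "rigid_body_spec")
}

#' Simulation settings for synthetic trajectories
#'
#' @param n_frames number of frames (>= 2).
#' @param frame_interval frame spacing in ps.
#' @param seed RNG seed; outputs are bit-identical for identical spec + seed.
#' @return an object of class `"sim_spec"`.
#' @export
sim_spec <- function(n_frames = 200, frame_interval = 100, seed = 1) {
  stopifnot(n_frames >= 2, frame_interval > 0)
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = as.numeric(frame_interval),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# Rodrigues rotation of points P (m x 3) about unit axis a through pivot c
.rotate_about <- function(P, pivot, axis, theta) {
  Q <- sweep(P, 2L, pivot)
  ct <- cos(theta); st <- sin(theta)
  ax <- Q %*% c(axis)                       # (P-c).a, m x 1
  cr <- cbind(axis[2L] * Q[, 3L] - axis[3L] * Q[, 2L],
              axis[3L] * Q[, 1L] - axis[1L] * Q[, 3L],
              axis[1L] * Q[, 2L] - axis[2L] * Q[, 1L])
  R <- Q * ct + cr * st + outer(as.vector(ax), axis) * (1 - ct)
  sweep(R, 2L, pivot, "+")
}

#' Generate a hinged multi-body C-alpha trajectory
#'
#' Places one C-alpha per residue on an ideal alpha-helical template (rise
#' 1.5 Angstrom, 100 degrees per residue, radius 2.3 Angstrom); each frame is
#' a rigid placement of the body templates, with every body after the first
#' rotated about its joint's hinge by an angle drawn from
#' `N(0, hinge_amplitude)`, plus per-atom Gaussian jitter.  Flexible linkers
#' get their own (typically large) jitter.  The ground-truth body assignment
#' is attached as attribute `"ground_truth"` so downstream recovery is
#' assertable.
#'
#' Jitter is drawn as standard normals in a fixed order and scaled by each
#' sigma, so sweeping jitter at a fixed seed yields coupled trajectories.
#'
#' @param spec a [rigid_body_spec()].
#' @param sim a [sim_spec()].
#' @return a [trajectory()] with attribute `ground_truth` (list with
#'   `assignment`: per-residue body id, linkers = 0; `bodies`; `linkers`).
#' @export
generate_hinge_trajectory <- function(spec, sim = sim_spec()) {
  stopifnot(inherits(spec, "rigid_body_spec"), inherits(sim, "sim_spec"))
  bodies <- spec$bodies
  nb <- length(bodies)
  residues <- sort(unlist(c(bodies, spec$linkers)))
  n <- length(residues)
  ord <- match(residues, residues)  # identity; template index = rank

  # ideal helical C-alpha template
  k <- seq_len(n)
  phi <- k * 100 * pi / 180
  template <- cbind(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * k)

  assignment <- integer(n)                 # body id, 0 for linker
  sigma <- numeric(n)
  for (b in seq_len(nb)) {
    ix <- match(bodies[[b]], residues)
    assignment[ix] <- b
    sigma[ix] <- spec$internal_jitter[b]
  }
  if (length(spec$linkers)) {
    for (l in seq_along(spec$linkers)) {
      ix <- match(spec$linkers[[l]], residues)
      sigma[ix] <- spec$linker_jitter[l]
    }
  }

  nf <- sim$n_frames
  xyz <- matrix(0, nf, 3L * n)
  with_seed(sim$seed, {
    # per-joint geometry: pivot displaced off the chain axis
    pivots <- axes <- vector("list", max(nb - 1L, 0L))
    if (nb > 1L) {
      for (j in seq_len(nb - 1L)) {
        last_prev <- max(match(bodies[[j]], residues))
        first_next <- min(match(bodies[[j + 1L]], residues))
        mid <- (template[last_prev, ] + template[first_next, ]) / 2
        ang <- stats::runif(1L, 0, 2 * pi)
        offset_dir <- c(cos(ang), sin(ang), 0)
        pivots[[j]] <- mid + spec$hinge_offset * offset_dir
        ax <- c(-offset_dir[2L], offset_dir[1L], 0)  # z x offset_dir
        axes[[j]] <- ax / sqrt(sum(ax^2))
      }
    }
    thetas <- if (nb > 1L)
      matrix(stats::rnorm(nf * (nb - 1L)), nf, nb - 1L) *
        rep(spec$hinge_amplitude * pi / 180, each = nf)
    else matrix(0, nf, 0L)

    # linkers bracketed by two bodies sweep the chord between their two
    # anchor atoms with a per-frame, per-residue random fraction
    linker_joint <- integer(length(spec$linkers))
    if (length(spec$linkers) && nb > 1L) {
      for (l in seq_along(spec$linkers)) {
        lmin <- min(spec$linkers[[l]])
        lmax <- max(spec$linkers[[l]])
        j <- which(vapply(seq_len(nb - 1L), function(j)
          lmin > max(bodies[[j]]) && lmax < min(bodies[[j + 1L]]),
          logical(1L)))
        linker_joint[l] <- if (length(j) == 1L) j else 0L
      }
    }
    u_list <- lapply(seq_along(spec$linkers), function(l) {
      j <- linker_joint[l]
      if (j == 0L) return(NULL)
      m <- length(spec$linkers[[l]])
      if (spec$hinge_amplitude[j] == 0) {
        # frozen joint: tether rests at fixed fractional positions
        matrix(seq_len(m) / (m + 1), nf, m, byrow = TRUE)
      } else {
        matrix(stats::runif(nf * m), nf)
      }
    })
    noise <- array(stats::rnorm(nf * n * 3L), dim = c(nf, n, 3L))

    for (f in seq_len(nf)) {
      P <- template
      for (b in seq.int(2L, length.out = nb - 1L)) {
        ix <- match(bodies[[b]], residues)
        P[ix, ] <- .rotate_about(P[ix, , drop = FALSE], pivots[[b - 1L]],
                                 axes[[b - 1L]], thetas[f, b - 1L])
      }
      for (l in seq_along(spec$linkers)) {
        j <- linker_joint[l]
        if (j == 0L) next
        ix <- match(spec$linkers[[l]], residues)
        A <- P[max(match(bodies[[j]], residues)), ]
        B <- P[min(match(bodies[[j + 1L]], residues)), ]
        u <- u_list[[l]][f, ]
        P[ix, ] <- rep(A, each = length(ix)) +
          outer(u, B - A)
      }
      P <- P + noise[f, , ] * sigma
      xyz[f, ] <- as.vector(t(P))
    }
  })

  atoms <- data.frame(
    atom_name = "CA",
    residue_name = ifelse(assignment == 0L, "GLY", "ALA"),
    residue_number = residues,
    chain_id = "A",
    stringsAsFactors = FALSE
  )
  traj <- trajectory(atoms, xyz, frame_interval = sim$frame_interval,
                     label = sprintf("synthetic %d-body hinge system", nb))
  attr(traj, "ground_truth") <- list(assignment = assignment,
                                     residues = residues,
                                     bodies = bodies,
                                     linkers = spec$linkers)
  traj
}

# approximate canonical random-coil 1H shifts (ppm) by residue/atom
.rc_defaults <- list(
  GLY = c(HA2 = 3.96, HA3 = 3.96),
  PRO = c(HA = 4.42, HB2 = 2.05, HD1 = 3.65, HD2 = 3.65),
  TRP = c(HA = 4.66, HE1 = 10.22),
  default = c(HA = 4.35)
)

.proton_inventory <- function(residue_name) {
  tab <- .rc_defaults[[residue_name]] %||% .rc_defaults$default
  data.frame(atom_name = names(tab), rc = unname(tab),
             stringsAsFactors = FALSE)
}

#' Generate synthetic chemical-shift tables with known secondary shifts
#'
#' Builds a random-coil reference table from canonical 1H random-coil values
#' and an observed table equal to random coil + injected secondary chemical
#' shifts + Gaussian noise.  The injected per-proton ground truth is returned
#' so that [compute_scs()] recovery is assertable (exact at `noise_sd = 0`).
#'
#' @param sequence data.frame with `residue_number` and `residue_name`
#'   (3-letter codes; GLY/PRO/TRP get their characteristic protons).
#' @param helix_scs named numeric vector of helical H-alpha offsets in ppm;
#'   names are residue numbers.  Applied to every H-alpha-type proton of the
#'   residue.
#' @param ring_current_scs data.frame with `residue_number`, `atom_name`,
#'   `scs` (ppm) for ring-current-shifted protons; every listed proton must
#'   exist in the sequence's proton inventory.
#' @param noise_sd Gaussian noise sigma in ppm added to observed shifts.
#' @param seed RNG seed.
#' @param temperature,label metadata stored on the returned tables.
#' @return list with `observed` and `random_coil` ([shift_table()]s) and
#'   `truth` (data.frame `residue_number`, `atom_name`, `scs`).
#' @export
generate_shift_table <- function(sequence, helix_scs = NULL,
                                 ring_current_scs = NULL, noise_sd = 0,
                                 seed = 1, temperature = NA_real_,
                                 label = "synthetic") {
  stopifnot(is.data.frame(sequence),
            all(c("residue_number", "residue_name") %in% names(sequence)))
  inv <- do.call(rbind, lapply(seq_len(nrow(sequence)), function(i) {
    p <- .proton_inventory(sequence$residue_name[i])
    data.frame(residue_number = sequence$residue_number[i],
               residue_name = sequence$residue_name[i],
               atom_name = p$atom_name, rc = p$rc, stringsAsFactors = FALSE)
  }))
  inv$scs <- 0
  if (!is.null(helix_scs)) {
    for (rn in names(helix_scs)) {
      hit <- inv$residue_number == as.integer(rn) & grepl("^HA", inv$atom_name)
      if (!any(hit))
        stop("no H-alpha proton for residue ", rn, " in sequence")
      inv$scs[hit] <- inv$scs[hit] + helix_scs[[rn]]
    }
  }
  if (!is.null(ring_current_scs)) {
    key_inv <- paste(inv$residue_number, inv$atom_name)
    key_rc <- paste(ring_current_scs$residue_number,
                    ring_current_scs$atom_name)
    idx <- match(key_rc, key_inv)
    if (anyNA(idx))
      stop("unknown proton: ", key_rc[is.na(idx)][1L])
    inv$scs[idx] <- inv$scs[idx] + ring_current_scs$scs
  }
  obs_ppm <- with_seed(seed,
    inv$rc + inv$scs + stats::rnorm(nrow(inv), sd = noise_sd))

  mk <- function(ppm) shift_table(
    data.frame(residue_number = inv$residue_number,
               residue_name = inv$residue_name,
               atom_name = inv$atom_name, shift_ppm = ppm,
               stringsAsFactors = FALSE),
    temperature = temperature, label = label)
  list(observed = mk(obs_ppm), random_coil = mk(inv$rc),
       truth = inv[, c("residue_number", "atom_name", "scs")])
}

#' Generate a NOESY peak list from known distances
#'
#' Inverts the volume-to-distance calibration model: each peak's volume is
#' `v_ref * (d_ref / d)^6 * (1 + eps)` with `eps ~ N(0, noise_frac)`.
#'
#' @param distances data.frame with `res_i`, `atom_i`, `res_j`, `atom_j`,
#'   `distance` (Angstrom, > 0), or a bare numeric vector of distances (a
#'   synthetic intra-residue HA-HN pair is fabricated per entry).
#' @param v_ref reference volume (volume observed at `d_ref`).
#' @param d_ref reference distance in Angstrom.
#' @param seed RNG seed.
#' @param noise_frac relative volume noise sigma.
#' @param temperature,label metadata for the peak list.
#' @return a [peak_list()] with attribute `ground_truth` (the distance table
#'   plus `v_ref`, `d_ref`).
#' @export
generate_peak_list <- function(distances, v_ref = 100, d_ref = 3.2,
                               seed = 1, noise_frac = 0,
                               temperature = NA_real_, label = "synthetic") {
  if (is.numeric(distances) && is.null(dim(distances))) {
    distances <- data.frame(res_i = seq_along(distances), atom_i = "HA",
                            res_j = seq_along(distances), atom_j = "HN",
                            distance = as.numeric(distances),
                            stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(distances),
            all(c("res_i", "atom_i", "res_j", "atom_j", "distance") %in%
                  names(distances)))
  if (any(distances$distance <= 0)) stop("distances must be positive")
  eps <- with_seed(seed, stats::rnorm(nrow(distances), sd = noise_frac))
  vol <- v_ref * (d_ref / distances$distance)^6 * (1 + eps)
  if (any(vol <= 0))
    stop("volume noise produced non-positive volumes; lower noise_frac")
  pl <- peak_list(
    data.frame(res_i = distances$res_i, atom_i = distances$atom_i,
               res_j = distances$res_j, atom_j = distances$atom_j,
               volume = vol, stringsAsFactors = FALSE),
    temperature = temperature, label = label)
  attr(pl, "ground_truth") <- list(distances = distances, v_ref = v_ref,
                                   d_ref = d_ref)
  pl
}

#' Generate a sigmoidal melting series
#'
#' Values follow `end + (start - end) / (1 + exp((t - midpoint) /
#' steepness))` plus Gaussian noise: a monotone sigmoid from `start_value`
#' at low temperature to `end_value` at high temperature (monotone exactly
#' when `noise_sd = 0`).
#'
#' @param t_grid strictly increasing temperatures in degrees C (>= 3 points).
#' @param start_value,end_value asymptotic low/high-temperature values.
#' @param midpoint melting midpoint in degrees C.
#' @param steepness transition width in degrees C (> 0).
#' @param noise_sd Gaussian noise sigma.
#' @param seed RNG seed.
#' @param kind,label metadata for the series.
#' @return a [fold_series()] with attribute `ground_truth` (the sigmoid
#'   parameters).
#' @export
generate_melting_series <- function(t_grid, start_value, end_value,
                                    midpoint, steepness, noise_sd = 0,
                                    seed = 1, kind = "synthetic",
                                    label = "synthetic") {
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 3L) stop("need at least 3 temperatures")
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  stopifnot(steepness > 0)
  v <- end_value + (start_value - end_value) /
    (1 + exp((t_grid - midpoint) / steepness))
  v <- v + with_seed(seed, stats::rnorm(length(t_grid), sd = noise_sd))
  fs <- fold_series(t_grid, v, kind = kind, label = label)
  attr(fs, "ground_truth") <- list(start_value = start_value,
                                   end_value = end_value,
                                   midpoint = midpoint,
                                   steepness = steepness)
  fs
}
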