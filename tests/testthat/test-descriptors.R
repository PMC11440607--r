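# Trajectory geometry and occupancy descriptors

trp_ring <- function(resno = 1, chain = "A")
  ring_selection(chain, resno, ring_atoms = c("CG", "CD1", "NE1"))

ring_atoms_df <- function(resno, chain = "A")
  data.frame(atom_name = c("CG", "CD1", "NE1"), residue_name = "TRP",
             residue_number = resno, chain_id = chain,
             stringsAsFactors = FALSE)

test_that("ring-centroid distances follow from the coordinates", {
  atoms <- rbind(ring_atoms_df(1), ring_atoms_df(2))
  base <- matrix(rnorm(9, sd = 2), 3, 3)
  shifted <- sweep(base, 2, c(3, 4, 0), "+")
  tr <- make_traj(list(rbind(base, shifted)), atoms)
  expect_equal(centroid_distance_series(tr, trp_ring(1), trp_ring(2)), 5)
  expect_equal(centroid_distance_series(tr, trp_ring(1), trp_ring(1)), 0)

  # random geometry vs brute-force mean-then-distance recomputation
  set.seed(5)
  frames <- lapply(1:20, function(i) matrix(rnorm(18, sd = 4), 6, 3))
  tr2 <- make_traj(frames, atoms)
  d <- centroid_distance_series(tr2, trp_ring(1), trp_ring(2))
  ref <- sapply(frames, function(P) {
    ca <- colMeans(P[1:3, ]); cb <- colMeans(P[4:6, ])
    sqrt(sum((ca - cb)^2))
  })
  expect_equal(d, ref, tolerance = 1e-10)

  expect_error(centroid_distance_series(tr, trp_ring(9), trp_ring(2)),
               "not found")
})

test_that("distribution summaries use midpoint medians and modal bins", {
  s <- summarize_distribution(c(1, 2, 3), bin_width = 1)
  expect_equal(s$median, 2)
  s2 <- summarize_distribution(c(1, 1, 2, 9), bin_width = 1)
  expect_equal(s2$mode, 1)       # most populated bin centered on 1
  expect_equal(s2$median, 1.5)   # midpoint rule
  expect_equal(c(s2$min, s2$max), c(1, 9))

  set.seed(8)
  draws <- rnorm(1e5, mean = 5.4, sd = 0.5)
  s3 <- summarize_distribution(draws, bin_width = 0.2)
  expect_lt(abs(s3$mode - 5.4), 0.2 + 1e-12)
  expect_lt(abs(s3$median - 5.4), 0.01)

  expect_error(summarize_distribution(numeric(0)), "empty")
})

test_that("torsions follow the IUPAC sign convention", {
  at4 <- data.frame(atom_name = c("N", "CA", "CB", "CG"),
                    residue_name = "TRP", residue_number = 1, chain_id = "A")
  spec <- dihedral_spec(at4)
  # planar trans geometry
  P <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(dihedral_series(make_traj(list(P), at4), spec), 180)
  # mirror image negates the angle
  Q <- rbind(c(1, 0, -0.5), c(0, 0, 0), c(0, 0, 1), c(0.5, -sqrt(3) / 2, 1.5))
  a <- dihedral_series(make_traj(list(Q), at4), spec)
  Qm <- Q; Qm[, 3] <- -Qm[, 3]
  expect_equal(dihedral_series(make_traj(list(Qm), at4), spec), -a)

  # independent oracle: bio3d's torsion implementation
  set.seed(10)
  for (i in 1:50) {
    R <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral_series(make_traj(list(R), at4), spec),
                 bio3d::torsion.xyz(as.vector(t(R)), atm.inc = 4),
                 tolerance = 1e-8)
  }

  # collinear geometry flagged as missing
  C <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_warning(res <- dihedral_series(make_traj(list(C), at4), spec),
                 "collinear")
  expect_true(is.na(res))
})

test_that("rotamer classes partition the circle and respect periodicity", {
  expect_equal(classify_rotamer(-60), "gauche_minus")
  expect_equal(classify_rotamer(60), "gauche_plus")
  expect_equal(classify_rotamer(180), "antiperiplanar")
  expect_equal(classify_rotamer(300), "gauche_minus")  # wraps to -60
  grid <- seq(-179.5, 180, by = 0.5)
  cls <- classify_rotamer(grid)
  expect_false(anyNA(cls))
  expect_identical(classify_rotamer(grid + 360), cls)
  expect_identical(classify_rotamer(grid - 720), cls)
  # boundary conventions
  expect_equal(classify_rotamer(c(-120, 0, 120, -180)),
               c("gauche_minus", "gauche_plus", "antiperiplanar",
                 "antiperiplanar"))
})

hb_atoms <- function() {
  rbind(
    data.frame(atom_name = c("NE1", "HE1"), residue_name = "TRP",
               residue_number = 25L, chain_id = "A"),
    data.frame(atom_name = "O", residue_name = "ARG",
               residue_number = 35L, chain_id = "A")
  )
}

test_that("contact occupancy counts frames meeting the geometric criterion", {
  atoms <- hb_atoms()
  near <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))   # D-A 2.9, angle 180
  far <- rbind(c(0, 0, 0), c(1, 0, 0), c(7, 0, 0))
  frames <- c(rep(list(near), 5), rep(list(far), 5))
  tr <- make_traj(frames, atoms)
  spec <- contact_spec("hbond",
    donors = data.frame(chain_id = "A", residue_number = 25L,
                        atom_name = "NE1", hydrogen_name = "HE1"),
    acceptors = data.frame(chain_id = "A", residue_number = 35L,
                           atom_name = "O"))
  occ <- contact_occupancy(tr, spec)
  expect_identical(occ$fraction, 0.5)
  expect_identical(contact_occupancy(make_traj(rep(list(near), 4), atoms),
                                     spec)$fraction, 1)
  expect_identical(contact_occupancy(make_traj(rep(list(far), 4), atoms),
                                     spec)$fraction, 0)

  # within distance but bent below the angle cutoff does not count
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 3, 0))   # D-A 3.0, angle 71.6
  expect_identical(contact_occupancy(make_traj(list(bent), atoms),
                                     spec)$fraction, 0)

  # equilibration discard drops leading frames
  occ2 <- contact_occupancy(tr, spec, equilibration_discard = 0.5)
  expect_identical(occ2$fraction, 0)
  expect_equal(occ2$n_frames, 5)
})

test_that("multi-pair occupancies match a brute-force pair evaluation", {
  set.seed(17)
  donors <- data.frame(atom_name = c("NH1", "NH2"), residue_name = "ARG",
                       residue_number = 35L, chain_id = "A")
  acceptors <- data.frame(atom_name = c("OD1", "OD2"), residue_name = "ASP",
                          residue_number = 28L, chain_id = "A")
  atoms <- rbind(donors, acceptors)
  frames <- lapply(1:40, function(i) matrix(rnorm(12, sd = 2.5), 4, 3))
  tr <- make_traj(frames, atoms)
  spec <- contact_spec("saltbridge",
    donors = donors[, c("chain_id", "residue_number", "atom_name")],
    acceptors = acceptors[, c("chain_id", "residue_number", "atom_name")])

  counts <- sapply(frames, function(P) {
    cnt <- 0L
    for (p in 1:2) for (q in 3:4)
      if (sqrt(sum((P[p, ] - P[q, ])^2)) <= 4.0) cnt <- cnt + 1L
    cnt
  })
  expect_identical(contact_occupancy(tr, spec)$fraction, mean(counts >= 1))
  expect_identical(count_multiple_hbonds(tr, spec, k = 2)$fraction,
                   mean(counts >= 2))
  # k = 1 reduces to plain occupancy
  expect_identical(count_multiple_hbonds(tr, spec, k = 1)$fraction,
                   contact_occupancy(tr, spec)$fraction)
})

test_that("segment RMSD measures displacement from the reference ensemble", {
  set.seed(23)
  atoms <- ca_atoms(10)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  ref <- make_traj(list(base), atoms)
  expect_equal(as.numeric(segment_rmsd_vs_reference(ref, ref)), 0,
               tolerance = 1e-8)

  # rigid 2 Angstrom offset of the measured region, fit region untouched
  shifted <- base
  shifted[6:10, ] <- sweep(shifted[6:10, ], 2, c(2, 0, 0), "+")
  tr <- make_traj(list(shifted), atoms)
  fit_sel <- data.frame(chain_id = "A", residue_number = 1:5,
                        atom_name = "CA")
  meas_sel <- data.frame(chain_id = "A", residue_number = 6:10,
                         atom_name = "CA")
  expect_equal(as.numeric(segment_rmsd_vs_reference(tr, ref, fit_sel,
                                                    meas_sel)),
               2, tolerance = 1e-6)

  # random ensembles vs a hand-coded Kabsch oracle
  frames <- lapply(1:6, function(i) base + matrix(rnorm(30, sd = 1), 10, 3))
  tr2 <- make_traj(frames, atoms)
  got <- segment_rmsd_vs_reference(tr2, ref)
  want <- mean(sapply(frames, function(P) oracle_kabsch_rmsd(base, P)))
  expect_equal(as.numeric(got), want, tolerance = 1e-8)

  # RMSD invariant under a global rototranslation of the mobile frames
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- lapply(frames, function(P) sweep(P %*% R, 2, c(10, -4, 2), "+"))
  expect_equal(as.numeric(segment_rmsd_vs_reference(make_traj(moved, atoms),
                                                    ref)),
               want, tolerance = 1e-8)

  expect_error(segment_rmsd_vs_reference(tr, ref, data.frame(
    chain_id = "B", residue_number = 1, atom_name = "CA")), "not found")
})

test_that("cluster counts cover the stated population fractions", {
  set.seed(31)
  atoms <- ca_atoms(12)
  conf <- list(matrix(rnorm(36, sd = 4), 12, 3),
               matrix(rnorm(36, sd = 4), 12, 3))
  frames <- lapply(c(rep(1, 48), rep(2, 2)), function(k)
    conf[[k]] + matrix(rnorm(36, sd = 0.05), 12, 3))
  tr <- make_traj(frames, atoms)
  # 96/4 split: the dominant cluster alone reaches 95%
  expect_identical(as.integer(cluster_coverage_count(tr, rmsd_cutoff = 1.5)),
                   1L)
  # all frames identical -> a single cluster
  same <- make_traj(rep(list(conf[[1]]), 10), atoms)
  expect_identical(as.integer(cluster_coverage_count(same,
                                                     rmsd_cutoff = 0.5)), 1L)
})
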