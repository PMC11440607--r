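# Secondary-chemical-shift fold descriptors and melting-curve normalization

toy_shift_tables <- function(scs_values) {
  # scs_values: data.frame(residue_number, atom_name, scs)
  rc <- shift_table(data.frame(residue_number = scs_values$residue_number,
                               atom_name = scs_values$atom_name,
                               shift_ppm = 4.3), label = "rc")
  obs <- shift_table(data.frame(residue_number = scs_values$residue_number,
                                atom_name = scs_values$atom_name,
                                shift_ppm = 4.3 + scs_values$scs),
                     label = "obs")
  list(observed = obs, random_coil = rc)
}

test_that("secondary shifts are observed minus random coil", {
  t1 <- toy_shift_tables(data.frame(residue_number = 21, atom_name = "HA",
                                    scs = -0.25))
  scs <- compute_scs(t1$observed, t1$random_coil)
  expect_equal(scs$scs, -0.25)

  # identical tables -> all zero
  t0 <- toy_shift_tables(data.frame(residue_number = 16:20, atom_name = "HA",
                                    scs = 0))
  expect_true(all(compute_scs(t0$observed, t0$random_coil)$scs == 0))

  # disjoint tables rejected; partial overlap excluded with a message
  a <- shift_table(data.frame(residue_number = 1, atom_name = "HA",
                              shift_ppm = 4))
  b <- shift_table(data.frame(residue_number = 2, atom_name = "HA",
                              shift_ppm = 4))
  expect_error(compute_scs(a, b), "overlap")
  c2 <- shift_table(data.frame(residue_number = 1:2, atom_name = "HA",
                               shift_ppm = 4))
  expect_message(out <- compute_scs(c2, a), "excluded")
  expect_equal(nrow(out), 1)
})

test_that("SCS_helix sums absolute H-alpha shifts over the helical window", {
  vals <- data.frame(residue_number = 16:27, atom_name = "HA",
                     scs = rep(c(-0.1, 0.1), 6))
  t1 <- toy_shift_tables(vals)
  scs <- compute_scs(t1$observed, t1$random_coil)
  expect_equal(as.numeric(scs_helix(scs)), 1.2)      # mixed signs, |.| sum
  # permutation invariance and additivity over disjoint windows
  perm <- scs[sample(nrow(scs)), ]
  expect_equal(as.numeric(scs_helix(perm)), 1.2)
  expect_equal(as.numeric(scs_helix(scs, 16:21)) +
                 as.numeric(scs_helix(scs, 22:27)), 1.2)
  expect_error(scs_helix(scs, window = 1:5), "window")
})

test_that("SCS_Tc sums the ring-current proton set with mode control", {
  pr <- tc_ring_current_protons()
  expect_equal(nrow(pr), 9)   # duplicated indole NH collapses to one entry
  vals <- data.frame(residue_number = pr$residue_number,
                     atom_name = pr$atom_name, scs = -0.2)
  t1 <- toy_shift_tables(vals)
  scs <- compute_scs(t1$observed, t1$random_coil)
  expect_equal(as.numeric(scs_tc(scs)), 1.8)
  expect_equal(as.numeric(scs_tc(scs, mode = "signed")), -1.8)
  expect_equal(attr(scs_tc(scs), "coverage"), 1)

  # signed and absolute differ exactly when signs are mixed
  vals$scs <- rep(c(-0.2, 0.2), length.out = 9)
  t2 <- toy_shift_tables(vals)
  scs2 <- compute_scs(t2$observed, t2$random_coil)
  expect_false(isTRUE(all.equal(as.numeric(scs_tc(scs2, mode = "signed")),
                                as.numeric(scs_tc(scs2)))))
  # all-zero shifts give zero in both modes
  vals$scs <- 0
  t3 <- toy_shift_tables(vals)
  expect_equal(as.numeric(scs_tc(compute_scs(t3$observed, t3$random_coil))), 0)
})

test_that("the bundled random-coil reference covers the descriptor protons", {
  rc <- read_shift_table(system.file("extdata",
                                     "random_coil_1h_reference.tsv",
                                     package = "tcagedyn"))
  pr <- tc_ring_current_protons()
  key_rc <- paste(rc$residue_number, rc$atom_name)
  expect_true(all(paste(pr$residue_number, pr$atom_name) %in% key_rc))
})

test_that("mean residue ellipticity follows the standard conversion", {
  expect_equal(mean_residue_ellipticity(0, 2.5e-5, 0.1, 25), 0)
  expect_equal(mean_residue_ellipticity(-10, 2.5e-5, 0.1, 25), -16000)
  # doubling the concentration halves the value
  expect_equal(mean_residue_ellipticity(-10, 5e-5, 0.1, 25), -8000)
  expect_error(mean_residue_ellipticity(-10, 0, 0.1, 25), "positive")
})

test_that("normalization anchors the reference's lowest temperature at 1", {
  ref <- fold_series(c(4, 15, 26, 37, 48), c(2.0, 1.8, 1.5, 1.1, 0.9),
                     kind = "SCS_Tc", label = "QR")
  norm_self <- normalize_series(ref, ref)
  expect_identical(norm_self$value[1], 1)
  expect_equal(attr(norm_self, "reference")$temperature_C, 4)

  other <- fold_series(c(4, 15, 26), c(3.0, 2.4, 1.2), kind = "SCS_Tc",
                       label = "CC")
  norm <- normalize_series(other, ref)
  expect_equal(norm$value, c(3.0, 2.4, 1.2) / 2.0)

  # scale equivariance: scaling both series leaves the result unchanged
  sc <- function(fs, k) fold_series(fs$temperature_C, fs$value * k,
                                    attr(fs, "kind"), attr(fs, "label"))
  norm_sc <- normalize_series(sc(other, 7), sc(ref, 7))
  expect_equal(norm_sc$value, norm$value)

  zeros <- fold_series(c(4, 15), c(0, 0))
  expect_equal(normalize_series(zeros, ref)$value, c(0, 0))
  zero_ref <- fold_series(c(4, 15), c(0, 1))
  expect_error(normalize_series(other, zero_ref), "zero")
})

test_that("crossing temperatures interpolate linearly and detect misses", {
  lin <- fold_series(c(5, 85), c(1.2, 0.8))
  expect_equal(crossing_temperature(lin, level = 1.0), 45)
  below <- fold_series(c(5, 45, 85), c(0.9, 0.8, 0.7))
  expect_true(is.na(crossing_temperature(below, level = 1.0)))
  # exact grid hits returned as-is, lowest first
  grid <- fold_series(c(5, 25, 45), c(1.2, 1.0, 1.0))
  expect_identical(crossing_temperature(grid, 1.0), 25)
  # strictly monotone series: crossing bracketed by adjacent grid points
  mono <- generate_melting_series(seq(5, 85, 5), 1.3, 0.7, 40, 10,
                                  noise_sd = 0)
  tc <- crossing_temperature(mono, 1.0)
  i <- findInterval(tc, mono$temperature_C)
  expect_true(mono$value[i] >= 1.0 && mono$value[i + 1] <= 1.0)
})

test_that("series values interpolate within range and reject extrapolation", {
  fs <- fold_series(c(5, 25, 45), c(1.2, 1.0, 0.6))
  expect_identical(value_at_temperature(fs, 25), 1.0)
  expect_equal(value_at_temperature(fs, 35), 0.8)   # midpoint mean
  expect_error(value_at_temperature(fs, 90), "outside")

  set.seed(3)
  t <- sort(runif(10, 0, 80)); v <- rnorm(10)
  fs2 <- fold_series(t, v)
  q <- runif(20, min(t), max(t))
  expect_equal(sapply(q, value_at_temperature, norm = fs2),
               approx(t, v, xout = q)$y)
})
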