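#' Chemical-shift table
#'
#' @param entries data.frame with `residue_number`, `atom_name`, `shift_ppm`
#'   (and optionally `residue_name`).  `(residue, atom)` keys must be unique
#'   and shifts finite.
#' @param temperature acquisition temperature in degrees C (metadata).
#' @param label variant label (metadata).
#' @return the entries as a data.frame of class `"shift_table"` with
#'   attributes `temperature` and `label`.
#' @export
shift_table <- function(entries, temperature = NA_real_, label = "") {
  stopifnot(is.data.frame(entries),
            all(c("residue_number", "atom_name", "shift_ppm") %in%
                  names(entries)))
  entries$residue_number <- as.integer(entries$residue_number)
  entries$atom_name <- as.character(entries$atom_name)
  entries$shift_ppm <- as.numeric(entries$shift_ppm)
  if (!all(is.finite(entries$shift_ppm)))
    stop("non-finite chemical shift(s)")
  key <- paste(entries$residue_number, entries$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (residue, atom) key: ", key[duplicated(key)][1L])
  structure(entries, class = c("shift_table", "data.frame"),
            temperature = as.numeric(temperature),
            label = as.character(label)[1L])
}

#' Secondary chemical shifts (observed minus random coil)
#'
#' `SCS = delta_obs - delta_rc` per proton, over the protons present in both
#' tables; protons missing from either side are excluded (count reported via
#' a message).
#'
#' @param observed,random_coil [shift_table()]s.
#' @return data.frame of class `"scs_result"` with `residue_number`,
#'   `atom_name`, `scs` (ppm), carrying both source labels as attributes.
#' @export
compute_scs <- function(observed, random_coil) {
  ko <- paste(observed$residue_number, observed$atom_name)
  kr <- paste(random_coil$residue_number, random_coil$atom_name)
  idx <- match(ko, kr)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no (residue, atom) overlap between tables")
  n_excl <- sum(!keep) + sum(!kr %in% ko)
  if (n_excl) message(n_excl, " proton(s) present in only one table; excluded")
  out <- data.frame(
    residue_number = observed$residue_number[keep],
    atom_name = observed$atom_name[keep],
    scs = observed$shift_ppm[keep] - random_coil$shift_ppm[idx[keep]],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("scs_result", "data.frame"),
            observed_label = attr(observed, "label"),
            random_coil_label = attr(random_coil, "label"),
            temperature = attr(observed, "temperature"))
}

#' Helicity descriptor: summed absolute H-alpha secondary shifts
#'
#' Sum of `|SCS|` of the H-alpha protons over a residue window (default the
#' helical segment, residues 16-27 in author numbering — residues 2-13 of
#' the truncated 25-mer construct).  Residues of the window without an
#' H-alpha entry are counted and reported via a message.
#'
#' @param scs an [compute_scs()] result.
#' @param window residue numbers of the helical segment.
#' @return the SCS_helix value (ppm, numeric scalar) with attribute
#'   `"n_protons"`.
#' @export
scs_helix <- function(scs, window = 16:27) {
  hit <- scs$residue_number %in% window & grepl("^HA[123]?$", scs$atom_name)
  if (!any(hit)) stop("no H-alpha SCS within the window")
  missing <- setdiff(window, scs$residue_number[hit])
  if (length(missing))
    message(length(missing), " window residue(s) without H-alpha SCS")
  structure(sum(abs(scs$scs[hit])), n_protons = sum(hit))
}

#' Default ring-current-sensitive proton set for the Trp-cage descriptor
#'
#' The nine unique protons whose shifts respond most to the central Trp
#' indole ring current (author numbering): W25 Heps1 (indole NH), L21 Ha,
#' G30 Ha2, P31 Hb2, R35 Ha, P37 Ha, P37 Hb2, P38 Hd1, P38 Hd2.
#'
#' @return data.frame with `residue_number` and `atom_name`.
#' @export
tc_ring_current_protons <- function() {
  data.frame(
    residue_number = c(25L, 21L, 30L, 31L, 35L, 37L, 37L, 38L, 38L),
    atom_name = c("HE1", "HA", "HA2", "HB2", "HA", "HA", "HB2", "HD1", "HD2"),
    stringsAsFactors = FALSE
  )
}

#' Trp-cage compactness descriptor: summed ring-current secondary shifts
#'
#' Sum (absolute values by default, matching the helicity descriptor's
#' convention; signed summation available) of the SCS of the ring-current
#' proton set.  The fraction of the set found in the table is attached as
#' attribute `"coverage"`.
#'
#' @param scs an [compute_scs()] result.
#' @param protons data.frame of `residue_number`, `atom_name`; default
#'   [tc_ring_current_protons()].
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return the SCS_Tc value (ppm, numeric scalar) with attribute
#'   `"coverage"`.
#' @export
scs_tc <- function(scs, protons = tc_ring_current_protons(),
                   mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  protons <- unique(protons[, c("residue_number", "atom_name")])
  key_s <- paste(scs$residue_number, scs$atom_name)
  key_p <- paste(protons$residue_number, protons$atom_name)
  idx <- match(key_p, key_s)
  found <- !is.na(idx)
  if (!any(found)) stop("none of the listed protons present in the table")
  v <- scs$scs[idx[found]]
  structure(if (mode == "absolute") sum(abs(v)) else sum(v),
            coverage = mean(found))
}

#' Mean residue molar ellipticity
#'
#' Converts raw CD ellipticity (mdeg) to mean residue molar ellipticity:
#' `raw / (10 * concentration * path_length * n_residues)`, in
#' deg cm^2 dmol^-1.
#'
#' @param raw_mdeg raw ellipticity in millidegrees.
#' @param concentration molar concentration (mol/L, > 0).
#' @param path_length cuvette path in cm (> 0).
#' @param n_residues number of residues (> 0).
#' @return numeric, deg cm^2 dmol^-1.
#' @export
mean_residue_ellipticity <- function(raw_mdeg, concentration, path_length,
                                     n_residues) {
  if (concentration <= 0 || path_length <= 0 || n_residues <= 0)
    stop("concentration, path_length and n_residues must be positive")
  raw_mdeg / (10 * concentration * path_length * n_residues)
}

#' Fold-descriptor melting series
#'
#' Points of (temperature, value) for one fold descriptor of one variant —
#' molar ellipticity at 222 nm, CD folded fraction, SCS_helix or SCS_Tc.
#' Points are sorted by ascending temperature; duplicate temperatures are
#' rejected.
#'
#' @param temperature degrees C.
#' @param value descriptor values (same length).
#' @param kind descriptor kind, e.g. `"SCS_helix"`, `"SCS_Tc"`,
#'   `"theta222"`, `"folded_fraction"`.
#' @param label variant label.
#' @return data.frame of class `"fold_series"` with columns
#'   `temperature_C`, `value`, and attributes `kind` and `label`.
#' @export
fold_series <- function(temperature, value, kind = "", label = "") {
  stopifnot(length(temperature) == length(value), length(value) >= 1L)
  o <- order(temperature)
  temperature <- as.numeric(temperature)[o]
  value <- as.numeric(value)[o]
  if (any(diff(temperature) == 0)) stop("duplicate temperatures in series")
  structure(data.frame(temperature_C = temperature, value = value),
            class = c("fold_series", "data.frame"),
            kind = as.character(kind)[1L], label = as.character(label)[1L])
}

#' Normalize a melting series to a reference variant
#'
#' Every value is divided by the reference series' value at its lowest
#' temperature (the reference data point maps to exactly 1), putting
#' descriptors from different methods on one common scale.  The reference
#' descriptor/variant/temperature are recorded on the result.
#'
#' @param series a [fold_series()].
#' @param reference a [fold_series()] of the reference variant (typically
#'   the same descriptor kind).
#' @return the normalized series: a `fold_series` that additionally carries
#'   class `"normalized_series"` and attribute `reference` (list with
#'   `kind`, `label`, `temperature_C`, `value`).
#' @export
normalize_series <- function(series, reference) {
  stopifnot(inherits(series, "fold_series"), inherits(reference, "fold_series"))
  ref_value <- reference$value[1L]   # sorted ascending: lowest temperature
  if (!is.finite(ref_value) || ref_value == 0)
    stop("reference value at its lowest temperature is zero or non-finite")
  out <- fold_series(series$temperature_C, series$value / ref_value,
                     kind = attr(series, "kind"),
                     label = attr(series, "label"))
  class(out) <- c("normalized_series", class(out))
  attr(out, "reference") <- list(kind = attr(reference, "kind"),
                                 label = attr(reference, "label"),
                                 temperature_C = reference$temperature_C[1L],
                                 value = ref_value)
  out
}

#' Lowest temperature at which a series crosses a level
#'
#' Linear interpolation between adjacent grid points; exact grid hits are
#' returned as-is.  Used to find the temperature at which a variant reaches
#' the same structural order as the reference (level 1 on the normalized
#' scale).
#'
#' @param norm a [fold_series()] (usually normalized) with >= 2 points.
#' @param level the level to cross (default 1.0).
#' @return temperature in degrees C, or `NA_real_` if the level is never
#'   attained.
#' @export
crossing_temperature <- function(norm, level = 1.0) {
  stopifnot(nrow(norm) >= 2L)
  t <- norm$temperature_C
  v <- norm$value
  for (i in seq_len(nrow(norm))) {
    if (v[i] == level) return(t[i])
    if (i < nrow(norm) && (v[i] - level) * (v[i + 1L] - level) < 0) {
      return(t[i] + (level - v[i]) / (v[i + 1L] - v[i]) * (t[i + 1L] - t[i]))
    }
  }
  NA_real_
}

#' Interpolated series value at a temperature
#'
#' Linear interpolation within the series range; exact at grid points;
#' extrapolation is rejected.
#'
#' @param norm a [fold_series()].
#' @param t query temperature in degrees C.
#' @return interpolated value.
#' @export
value_at_temperature <- function(norm, t) {
  if (t < min(norm$temperature_C) || t > max(norm$temperature_C))
    stop("temperature ", t, " outside series range [",
         min(norm$temperature_C), ", ", max(norm$temperature_C), "]")
  stats::approx(norm$temperature_C, norm$value, xout = t)$y
}
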