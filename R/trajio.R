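#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records yields a single-frame trajectory.  All models must share one
#' topology (same atoms in the same order); a mismatch is rejected naming the
#' offending model.  Author residue numbering is retained.
#'
#' @param path path to a PDB file.
#' @param frame_interval time between models in ps (deposited ensembles carry
#'   no time axis; the default 1 ps is a placeholder).
#' @param label trajectory label; defaults to the file name.
#' @return a [trajectory()].
#' @export
read_multimodel_pdb <- function(path, frame_interval = 1,
                                label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  starts <- grep("^MODEL", lines)
  if (length(starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records in ", path)
    counts <- mapply(function(s, e) sum(is_atom[s:e]), starts, ends)
    if (any(counts != counts[1L])) {
      bad <- which(counts != counts[1L])[1L]
      stop("topology mismatch: MODEL ", bad, " has ", counts[bad],
           " atoms; expected ", counts[1L])
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), nrow = 1L)
  atoms <- data.frame(
    atom_name      = pdb$atom$elety,
    residue_name   = pdb$atom$resid,
    residue_number = pdb$atom$resno,
    chain_id       = pdb$atom$chain,
    stringsAsFactors = FALSE
  )
  trajectory(atoms, xyz, frame_interval = frame_interval, label = label)
}

#' Write a segment-colored PDB file
#'
#' Writes the first frame of a trajectory with the rigid-segment id of each
#' residue encoded in the B-factor column (a tabular twin of the usual
#' segment-colored cartoon rendering).  Unassigned residues carry the sentinel
#' B-factor documented in the file's REMARK header.
#'
#' @param traj a [trajectory()].
#' @param labels a [segmentation result][segment_trajectory] covering the
#'   trajectory's residues.
#' @param path output file.
#' @param sentinel B-factor value written for unassigned residues.
#' @return `path`, invisibly.
#' @export
write_labeled_pdb <- function(traj, labels, path, sentinel = -1) {
  if (!inherits(labels, "rbs_segmentation"))
    stop("labels must be an rbs_segmentation result")
  key_res <- paste(labels$residues$chain_id, labels$residues$residue_number)
  key_atm <- paste(traj$atoms$chain_id, traj$atoms$residue_number)
  idx <- match(key_atm, key_res)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("segmentation does not cover residue ", key_atm[bad])
  }
  lab <- labels$labels[idx]
  b <- ifelse(lab == UNASSIGNED, sentinel, lab)

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(
    pdb = NULL, file = tmp,
    xyz   = traj$xyz[1L, ],
    resno = traj$atoms$residue_number,
    resid = traj$atoms$residue_name,
    eleno = seq_len(n_atoms(traj)),
    elety = traj$atoms$atom_name,
    chain = traj$atoms$chain_id,
    o = rep(1, n_atoms(traj)), b = b, end = TRUE
  )
  hdr <- c(
    "REMARK   4 RIGID-BODY SEGMENT ID ENCODED IN B-FACTOR COLUMN",
    sprintf("REMARK   4 UNASSIGNED RESIDUES CARRY SENTINEL B-FACTOR %.2f",
            sentinel)
  )
  writeLines(c(hdr, readLines(tmp, warn = FALSE)), path)
  invisible(path)
}

#' Tabular input dialect
#'
#' Describes how a delimited table maps onto the roles a reader needs.
#'
#' @param delimiter field separator.
#' @param header does the file carry a header row?
#' @param columns optional named character vector mapping roles (e.g.
#'   `residue_number`) to file column names; `NULL` assumes the file uses the
#'   role names directly.
#' @return an object of class `"table_dialect"`.
#' @export
table_dialect <- function(delimiter = "\t", header = TRUE, columns = NULL) {
  structure(list(delimiter = delimiter, header = isTRUE(header),
                 columns = columns),
            class = "table_dialect")
}

.table_roles <- list(
  shifts  = list(required = c("residue_number", "atom_name", "shift_ppm"),
                 numeric  = c("residue_number", "shift_ppm"),
                 optional = "residue_name"),
  peaks   = list(required = c("res_i", "atom_i", "res_j", "atom_j", "volume"),
                 numeric  = c("res_i", "res_j", "volume"),
                 optional = character()),
  melting = list(required = c("temperature_C", "value"),
                 numeric  = c("temperature_C", "value"),
                 optional = character())
)

#' Read a typed analysis table
#'
#' Reads chemical-shift tables (ppm), NOESY peak lists (positive volumes) or
#' melting series (degrees C vs descriptor value) from delimited text and
#' returns the corresponding typed object.  Melting series are sorted by
#' ascending temperature on load.
#'
#' @param path file path.
#' @param kind one of `"shifts"`, `"peaks"`, `"melting"`.
#' @param dialect a [table_dialect()].
#' @param ... passed to the corresponding constructor ([shift_table()],
#'   [peak_list()], [fold_series()]), e.g. `temperature`, `label`, `kind`.
#' @return a `shift_table`, `peak_list`, or `fold_series`.
#' @export
read_table <- function(path, kind = c("shifts", "peaks", "melting"),
                       dialect = table_dialect(), ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = dialect$delimiter,
                           header = dialect$header, colClasses = "character",
                           check.names = FALSE, comment.char = "",
                           quote = "\"", stringsAsFactors = FALSE)
  roles <- .table_roles[[kind]]
  map <- dialect$columns
  col_of <- function(role) if (!is.null(map) && role %in% names(map)) map[[role]] else role
  for (role in roles$required) {
    if (!col_of(role) %in% names(raw))
      stop("missing column ", sQuote(col_of(role)), " in ", path)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (role in c(roles$required, roles$optional)) {
    cn <- col_of(role)
    if (!cn %in% names(raw)) next  # optional role absent
    col <- raw[[cn]]
    if (role %in% roles$numeric) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & nzchar(trimws(col)))
      if (length(bad))
        stop("non-numeric value ", sQuote(col[bad[1L]]), " in column ",
             sQuote(cn), " at row ", bad[1L])
      if (anyNA(num))
        stop("empty value in column ", sQuote(cn), " at row ",
             which(is.na(num))[1L])
      out[[role]] <- num
    } else {
      out[[role]] <- col
    }
  }
  switch(kind,
    shifts  = shift_table(out, ...),
    peaks   = peak_list(out, ...),
    melting = fold_series(out$temperature_C, out$value, ...)
  )
}

#' @rdname read_table
#' @export
read_shift_table <- function(path, dialect = table_dialect(), ...)
  read_table(path, "shifts", dialect, ...)

#' @rdname read_table
#' @export
read_peak_list <- function(path, dialect = table_dialect(), ...)
  read_table(path, "peaks", dialect, ...)

#' @rdname read_table
#' @export
read_melting_series <- function(path, dialect = table_dialect(), ...)
  read_table(path, "melting", dialect, ...)
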