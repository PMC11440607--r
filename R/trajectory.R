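#' Multi-frame trajectory container
#'
#' A `trajectory` bundles one topology (an atom table) with an ordered set of
#' coordinate frames sharing that topology.  Coordinates are stored in the
#' bio3d layout: one row per frame, columns `x1, y1, z1, x2, ...` in Angstrom.
#'
#' Residue numbers follow the author (Ex4) numbering scheme throughout; use
#' [renumber_residues()] to convert to 1-based sequential numbering of
#' truncated constructs.
#'
#' @param atoms data.frame with columns `atom_name` (PDB convention, e.g.
#'   `"CA"`, `"NE1"`), `residue_name` (3-letter code), `residue_number`
#'   (integer, author numbering), `chain_id` (single character).
#' @param xyz numeric matrix of dimension `n_frames x (3 * n_atoms)`, or a
#'   numeric vector of length `3 * n_atoms` for a single frame.
#' @param frame_interval time between consecutive frames in ps; must be > 0.
#' @param label free-text label carried through reports.
#'
#' @return An object of class `"trajectory"` with elements `atoms`, `xyz`,
#'   `frame_interval` and `label`.
#' @export
trajectory <- function(atoms, xyz, frame_interval = 1, label = "") {
  stopifnot(is.data.frame(atoms))
  req <- c("atom_name", "residue_name", "residue_number", "chain_id")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  atoms <- data.frame(
    atom_name      = as.character(atoms$atom_name),
    residue_name   = as.character(atoms$residue_name),
    residue_number = as.integer(atoms$residue_number),
    chain_id       = as.character(atoms$chain_id),
    stringsAsFactors = FALSE
  )
  atoms$chain_id[is.na(atoms$chain_id) | atoms$chain_id == ""] <- "A"
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) key: ", key[duplicated(key)][1L])

  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), nrow = 1L)
  xyz <- unclass(as.matrix(xyz))
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns; expected ", 3L * nrow(atoms),
         " for ", nrow(atoms), " atoms")
  if (nrow(xyz) < 1L) stop("trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a single positive number (ps)")

  structure(
    list(atoms = atoms, xyz = xyz,
         frame_interval = as.numeric(frame_interval),
         label = as.character(label)[1L]),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory", if (nzchar(x$label)) sQuote(x$label) else "", "\n")
  cat("  frames:", n_frames(x), " atoms:", n_atoms(x),
      " residues:", nrow(residue_table(x)), "\n")
  cat("  frame interval:", x$frame_interval, "ps\n")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a [trajectory()] object.
#' @return integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Coordinates of one frame
#' @param traj a [trajectory()] object.
#' @param i frame index.
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Residues present in a trajectory
#'
#' @param traj a [trajectory()] object.
#' @return data.frame of unique `(chain_id, residue_number)` pairs in order of
#'   first appearance, with the residue name of the first matching atom.
#' @export
residue_table <- function(traj) {
  key <- paste(traj$atoms$chain_id, traj$atoms$residue_number)
  first <- !duplicated(key)
  data.frame(
    chain_id       = traj$atoms$chain_id[first],
    residue_number = traj$atoms$residue_number[first],
    residue_name   = traj$atoms$residue_name[first],
    stringsAsFactors = FALSE
  )
}

#' Select atom indices by chain, residue and atom name
#'
#' @param traj a [trajectory()] object.
#' @param chain,resno,elety optional filters; `NULL` selects everything.
#' @return integer vector of atom row indices (possibly empty).
#' @export
atom_select <- function(traj, chain = NULL, resno = NULL, elety = NULL) {
  keep <- rep(TRUE, n_atoms(traj))
  if (!is.null(chain)) keep <- keep & traj$atoms$chain_id %in% chain
  if (!is.null(resno)) keep <- keep & traj$atoms$residue_number %in% resno
  if (!is.null(elety)) keep <- keep & traj$atoms$atom_name %in% elety
  which(keep)
}

# xyz column indices for atom row indices (bio3d layout)
xyz_inds <- function(atom_inds) {
  as.vector(rbind(3L * atom_inds - 2L, 3L * atom_inds - 1L, 3L * atom_inds))
}

# Resolve a selection data.frame (chain_id, residue_number, atom_name) to atom
# indices, one per row, in row order; errors name the first missing atom.
resolve_selection <- function(traj, sel, what = "selection") {
  stopifnot(is.data.frame(sel))
  key_traj <- paste(traj$atoms$chain_id, traj$atoms$residue_number,
                    traj$atoms$atom_name)
  key_sel <- paste(as.character(sel$chain_id), as.integer(sel$residue_number),
                   as.character(sel$atom_name))
  idx <- match(key_sel, key_traj)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(what, " atom not found in topology: chain ", sel$chain_id[bad],
         " residue ", sel$residue_number[bad], " atom ", sel$atom_name[bad])
  }
  idx
}

#' Convert author residue numbering to sequential numbering
#'
#' The truncated 25-mer constructs retain author (Ex4) numbering 15-39; some
#' reports use 1-based sequential numbering instead (Ex4 residue 16 is
#' sequential residue 2).  This applies a constant offset to a copy of the
#' trajectory's residue numbers.
#'
#' @param traj a [trajectory()] object.
#' @param offset integer added to every residue number (e.g. `-14` maps Ex4
#'   16 to sequential 2).
#' @return a new trajectory with shifted residue numbers.
#' @export
renumber_residues <- function(traj, offset) {
  traj$atoms$residue_number <- traj$atoms$residue_number + as.integer(offset)
  traj
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
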