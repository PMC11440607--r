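#' Sentinel label for residues not assigned to any rigid segment
#' @export
UNASSIGNED <- -1L

#' Parameters for rigid-body segmentation
#'
#' Density-based clustering of the C-alpha distance standard-deviation matrix
#' uses two parameters: the cluster radius `clr` (the distance-fluctuation
#' threshold under which two residues count as neighbors, in Angstrom) and the
#' neighbor count `cln` (how many neighbors a residue needs to be a core
#' point).
#'
#' Whether a residue counts itself among its `cln` neighbors differs between
#' DBSCAN conventions; the default here requires `cln` *other* residues within
#' `clr`, with `include_self` available as a switch.
#'
#' @param clr cluster radius in Angstrom (> 0).
#' @param cln neighbor count (>= 1).
#' @param stride frame sampling interval in ps.
#' @param neighbor_counting `"exclude_self"` (default) or `"include_self"`.
#' @return an object of class `"segmentation_params"`.
#' @export
segmentation_params <- function(clr = 2.5, cln = 5, stride = 100,
                                neighbor_counting = c("exclude_self",
                                                      "include_self")) {
  neighbor_counting <- match.arg(neighbor_counting)
  stopifnot(is.numeric(clr), length(clr) == 1L, clr > 0,
            is.numeric(cln), length(cln) == 1L, cln >= 1,
            is.numeric(stride), length(stride) == 1L, stride > 0)
  structure(list(clr = clr, cln = as.integer(cln), stride = stride,
                 neighbor_counting = neighbor_counting),
            class = "segmentation_params")
}

# frame indices sampled at times 0, stride, 2*stride, ... (nearest earlier
# frame when stride is not a multiple of the frame interval)
stride_frames <- function(n_frames, frame_interval, stride) {
  if (is.null(stride)) return(seq_len(n_frames))
  if (stride < frame_interval)
    stop("stride (", stride, " ps) below frame interval (",
         frame_interval, " ps)")
  if (abs(stride %% frame_interval) > 1e-9 &&
      abs(stride %% frame_interval - frame_interval) > 1e-9)
    warning("stride is not a multiple of the frame interval; ",
            "taking the nearest earlier frame")
  times <- (seq_len(n_frames) - 1L) * frame_interval
  targets <- seq(0, times[n_frames], by = stride)
  unique(findInterval(targets + 1e-9, times))
}

#' C-alpha distance standard-deviation matrix
#'
#' For every residue pair (i, j), the population standard deviation (divide by
#' N) of the Euclidean C-alpha(i)-C-alpha(j) distance over the sampled frames.
#' Residues whose mutual distances fluctuate little move as one quasi-rigid
#' body; this matrix is the metric that rigid-body segmentation clusters.
#'
#' @param traj a [trajectory()]; every residue must have exactly one `CA`.
#' @param stride sampling interval in ps (`NULL` uses every frame).  Frames
#'   are taken at times `0, stride, 2*stride, ...`.
#' @return an object of class `"distance_stddev_matrix"`: list with `values`
#'   (symmetric, zero-diagonal `n_res x n_res` matrix, Angstrom), `residues`
#'   (data.frame of chain/residue ids in matrix order) and `n_frames` (frames
#'   actually analyzed).
#' @export
compute_distance_stddev_matrix <- function(traj, stride = NULL) {
  res <- residue_table(traj)
  key_atm <- paste(traj$atoms$chain_id, traj$atoms$residue_number)
  key_res <- paste(res$chain_id, res$residue_number)
  ca <- integer(nrow(res))
  for (k in seq_len(nrow(res))) {
    hit <- which(key_atm == key_res[k] & traj$atoms$atom_name == "CA")
    if (length(hit) != 1L)
      stop("residue ", key_res[k], " has ", length(hit),
           " CA atoms; expected exactly 1")
    ca[k] <- hit
  }

  frames <- stride_frames(n_frames(traj), traj$frame_interval, stride)
  if (length(frames) < 2L)
    stop("need at least 2 frames after striding (got ", length(frames), ")")

  n <- length(ca)
  npair <- n * (n - 1L) / 2L
  D <- matrix(0, npair, length(frames))
  for (f in seq_along(frames)) {
    D[, f] <- as.vector(stats::dist(frame_coords(traj, frames[f])[ca, ,
                                                                  drop = FALSE]))
  }
  m <- rowMeans(D)
  s <- sqrt(rowMeans((D - m)^2))  # population (divide-by-N) sd

  M <- matrix(0, n, n)
  M[lower.tri(M)] <- s
  M <- M + t(M)
  structure(list(values = M, residues = res, n_frames = length(frames)),
            class = "distance_stddev_matrix")
}

# core-point mask under either neighbor-counting convention
.core_points <- function(M, clr, cln, neighbor_counting) {
  within <- M <= clr            # diagonal is 0 <= clr, always TRUE
  deg <- rowSums(within)        # includes self
  if (neighbor_counting == "exclude_self") deg <- deg - 1L
  list(core = deg >= cln, within = within)
}

#' Density-based segmentation of a fluctuation matrix
#'
#' DBSCAN over the precomputed distance standard-deviation matrix: residue i
#' is a core point iff it has at least `cln` neighbors within `clr`
#' (self-counting per `params$neighbor_counting`); clusters are the connected
#' components of core points under the `clr` neighborhood relation; a
#' non-core residue within `clr` of a core point joins the cluster of the
#' lowest-index such core (a deterministic border rule); everything else is
#' `UNASSIGNED` and moves freely.  Segment ids are renumbered `0..K-1` by
#' each segment's first residue position.
#'
#' @param matrix a [compute_distance_stddev_matrix()] result.
#' @param params a [segmentation_params()].
#' @return an object of class `"rbs_segmentation"`: list with integer
#'   `labels` (per residue, `UNASSIGNED` = -1), `residues`, `params`,
#'   `n_frames`.
#' @export
dbscan_segment <- function(matrix, params = segmentation_params()) {
  stopifnot(inherits(matrix, "distance_stddev_matrix"),
            inherits(params, "segmentation_params"))
  M <- matrix$values
  n <- nrow(M)
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-12)) || any(diag(M) != 0) ||
      any(M < 0) || any(!is.finite(M)))
    stop("invalid fluctuation matrix (must be symmetric, non-negative, ",
         "zero-diagonal, finite)")

  cp <- .core_points(M, params$clr, params$cln, params$neighbor_counting)
  core <- cp$core
  within <- cp$within

  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(core & within[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }

  labels <- rep(UNASSIGNED, n)
  labels[core] <- comp[core]
  for (i in which(!core)) {
    covering <- which(core & within[i, ])
    if (length(covering)) labels[i] <- comp[covering[1L]]
  }

  # contiguous ids 0..K-1 ordered by first residue position of each segment
  seg_ids <- unique(labels[labels != UNASSIGNED])
  if (length(seg_ids)) {
    firsts <- vapply(seg_ids, function(s) min(which(labels == s)), 1L)
    remap <- seg_ids[order(firsts)]
    new <- labels
    for (k in seq_along(remap)) new[labels == remap[k]] <- k - 1L
    labels <- new
  }

  structure(list(labels = as.integer(labels), residues = matrix$residues,
                 params = params, n_frames = matrix$n_frames),
            class = "rbs_segmentation")
}

#' Rigid-body segmentation of a trajectory
#'
#' Composes [compute_distance_stddev_matrix()] and [dbscan_segment()]: the
#' trajectory is reduced to its C-alpha distance fluctuation matrix, which is
#' then clustered into quasi-rigid segments.  Residues not reachable from any
#' core point are labeled `UNASSIGNED` (they move freely).
#'
#' @param traj a [trajectory()].
#' @param params a [segmentation_params()].
#' @param keep_matrix store the fluctuation matrix on the result (used by
#'   `plot`)?
#' @return an `"rbs_segmentation"` object (see [dbscan_segment()]); with
#'   `keep_matrix = TRUE` it also carries the `matrix` element.
#' @export
segment_trajectory <- function(traj, params = segmentation_params(),
                               keep_matrix = TRUE) {
  M <- compute_distance_stddev_matrix(traj, stride = params$stride)
  res <- dbscan_segment(M, params)
  if (keep_matrix) res$matrix <- M
  res
}

#' Tabular summary of a segmentation
#'
#' @param result an `"rbs_segmentation"` object.
#' @return data.frame with one row per segment plus one for the unassigned
#'   set: segment id, residue ranges, size, and fraction of all residues.
#' @export
segmentation_report <- function(result) {
  stopifnot(inherits(result, "rbs_segmentation"))
  lab <- result$labels
  res <- result$residues
  ids <- sort(unique(lab[lab != UNASSIGNED]))
  rows <- lapply(c(ids, UNASSIGNED), function(s) {
    members <- which(lab == s)
    data.frame(
      segment = if (s == UNASSIGNED) "unassigned" else as.character(s),
      residues = .range_string(res$chain_id[members],
                               res$residue_number[members]),
      n_residues = length(members),
      fraction = length(members) / length(lab),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# "A:1-30, A:36-65" style collapse of consecutive residue runs
.range_string <- function(chain, resno) {
  if (!length(resno)) return("")
  o <- order(chain, resno)
  chain <- chain[o]; resno <- resno[o]
  brk <- c(TRUE, diff(resno) != 1L | chain[-1L] != chain[-length(chain)])
  grp <- cumsum(brk)
  parts <- vapply(split(seq_along(resno), grp), function(ix) {
    r <- resno[ix]
    if (length(r) == 1L) sprintf("%s:%d", chain[ix[1L]], r)
    else sprintf("%s:%d-%d", chain[ix[1L]], r[1L], r[length(r)])
  }, "")
  paste(parts, collapse = ", ")
}

#' @export
print.rbs_segmentation <- function(x, ...) {
  k <- length(unique(x$labels[x$labels != UNASSIGNED]))
  cat("rigid-body segmentation:", k, "segment(s),",
      sum(x$labels == UNASSIGNED), "of", length(x$labels),
      "residues unassigned\n")
  cat("  clr =", x$params$clr, "A, cln =", x$params$cln,
      paste0("(", x$params$neighbor_counting, "),"),
      "frames analyzed:", x$n_frames, "\n")
  invisible(x)
}

#' @export
summary.rbs_segmentation <- function(object, ...) {
  rep <- segmentation_report(object)
  print(rep, row.names = FALSE)
  invisible(rep)
}

#' @export
plot.rbs_segmentation <- function(x, ...) {
  if (is.null(x$matrix))
    stop("segmentation carries no matrix; rerun with keep_matrix = TRUE")
  M <- x$matrix$values
  n <- nrow(M)
  graphics::image(seq_len(n), seq_len(n), M[, n:1],
                  xlab = "residue index", ylab = "residue index",
                  main = "C-alpha distance stddev (A)", useRaster = TRUE, ...)
  b <- which(diff(x$labels) != 0) + 0.5
  graphics::abline(v = b, h = n + 1 - b, col = "white", lty = 3)
  invisible(x)
}
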