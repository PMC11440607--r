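# Independent oracles and fixture builders.  Every oracle is coded as a
# straightforward loop-based reimplementation, deliberately avoiding the
# package's vectorized code paths.

make_traj <- function(frames, atoms, frame_interval = 100) {
  xyz <- do.call(rbind, lapply(frames, function(p) as.vector(t(p))))
  trajectory(atoms, xyz, frame_interval = frame_interval)
}

ca_atoms <- function(n, chain = "A", start = 1L) {
  data.frame(atom_name = "CA", residue_name = "ALA",
             residue_number = seq.int(start, length.out = n),
             chain_id = chain, stringsAsFactors = FALSE)
}

# population-sd distance fluctuation matrix, triple loop
oracle_stddev_matrix <- function(frames, ca_idx = NULL) {
  if (is.null(ca_idx)) ca_idx <- seq_len(nrow(frames[[1]]))
  n <- length(ca_idx)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- numeric(length(frames))
      for (f in seq_along(frames)) {
        v <- frames[[f]][ca_idx[i], ] - frames[[f]][ca_idx[j], ]
        d[f] <- sqrt(sum(v * v))
      }
      mu <- mean(d)
      M[i, j] <- M[j, i] <- sqrt(mean((d - mu)^2))
    }
  }
  M
}

# textbook DBSCAN on a precomputed distance matrix; flood fill over cores
# with an explicit stack, borders claimed by the lowest-index covering core,
# segment ids renumbered by first member
oracle_dbscan <- function(M, clr, cln, include_self = FALSE) {
  n <- nrow(M)
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- integer()
    for (j in seq_len(n)) if (j != i && M[i, j] <= clr) nb <- c(nb, j)
    neigh[[i]] <- nb
  }
  core <- logical(n)
  for (i in seq_len(n))
    core[i] <- (length(neigh[[i]]) + if (include_self) 1L else 0L) >= cln
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(comp[i])) next
    cid <- cid + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp[v] <- cid
      for (w in neigh[[v]])
        if (core[w] && is.na(comp[w])) stack <- c(stack, w)
    }
  }
  lab <- rep(-1L, n)
  for (i in seq_len(n)) {
    if (core[i]) { lab[i] <- comp[i]; next }
    for (j in seq_len(n)) {
      if (core[j] && M[i, j] <= clr) { lab[i] <- comp[j]; break }
    }
  }
  ids <- unique(lab[lab != -1L])
  if (length(ids)) {
    firsts <- sapply(ids, function(s) min(which(lab == s)))
    remap <- ids[order(firsts)]
    out <- lab
    for (k in seq_along(remap)) out[lab == remap[k]] <- k - 1L
    lab <- out
  }
  lab
}

# Kabsch superposition + RMSD of Q onto P (both m x 3), hand-coded svd route
oracle_kabsch_rmsd <- function(P, Q, measure_P = P, measure_Q = Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(Q0) %*% P0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Qm <- sweep(measure_Q, 2, cq) %*% t(R)
  Pm <- sweep(measure_P, 2, cp)
  sqrt(mean(rowSums((Qm - Pm)^2)))
}

# leader (gromos) clustering on a precomputed rmsd matrix, loop-coded
oracle_leader_count <- function(R, cutoff, coverage = 0.95) {
  n <- nrow(R)
  remaining <- seq_len(n)
  sizes <- integer()
  while (length(remaining)) {
    best <- -1L; center <- NA_integer_
    for (i in remaining) {
      cnt <- 0L
      for (j in remaining) if (R[i, j] <= cutoff) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; center <- i }
    }
    members <- integer()
    for (j in remaining) if (R[center, j] <= cutoff) members <- c(members, j)
    sizes <- c(sizes, length(members))
    remaining <- setdiff(remaining, members)
  }
  sizes <- sort(sizes, decreasing = TRUE)
  cum <- 0L
  for (k in seq_along(sizes)) {
    cum <- cum + sizes[k]
    if (cum >= coverage * n) return(k)
  }
  length(sizes)
}

# closed-form sigmoid and its level crossing
sigmoid_value <- function(t, start, end, midpoint, steepness)
  end + (start - end) / (1 + exp((t - midpoint) / steepness))

sigmoid_crossing <- function(start, end, midpoint, steepness, level)
  midpoint + steepness * log((start - end) / (level - end) - 1)

# random symmetric fluctuation-like matrix, optionally with planted blocks
random_fluct_matrix <- function(n, scale = 3, blocks = FALSE) {
  M <- matrix(stats::runif(n * n, 0, scale), n, n)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  if (blocks && n >= 10) {
    cut <- sample(4:(n - 5), 1)
    a <- 1:cut; b <- (cut + 1):n
    M[a, a] <- matrix(stats::runif(length(a)^2, 0, 0.4), length(a))
    M[b, b] <- matrix(stats::runif(length(b)^2, 0, 0.4), length(b))
    M[a, b] <- matrix(stats::runif(length(a) * length(b), 2, scale + 2),
                      length(a))
    M[b, a] <- t(M[a, b])
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
  }
  diag(M) <- 0
  M
}

# K-body fixture used across rbs tests: 30-residue bodies, 5-residue linkers
kbody_spec <- function(K, jitter = 0.2, hinge = 30, linker_jitter = 3) {
  bodies <- list(); linkers <- list(); r <- 1L
  for (k in seq_len(K)) {
    bodies[[k]] <- r:(r + 29L); r <- r + 30L
    if (k < K) { linkers[[length(linkers) + 1L]] <- r:(r + 4L); r <- r + 5L }
  }
  rigid_body_spec(bodies, internal_jitter = jitter, hinge_amplitude = hinge,
                  linkers = linkers, linker_jitter = linker_jitter)
}

# partition comparison ignoring segment id numbering
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  ok <- a != -1L
  length(unique(paste(a[ok], b[ok]))) ==
    length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

toy_peaks <- function(volumes, sep = 5) {
  n <- length(volumes)
  peak_list(data.frame(res_i = seq_len(n), atom_i = rep("HA", n),
                       res_j = seq_len(n) + sep, atom_j = rep("HN", n),
                       volume = volumes))
}
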