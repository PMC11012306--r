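# Anisotropic network model: residue-level elastic network on
# coarse-grained nodes (C-alpha for protein residues, backbone P node for
# DNA), uniform spring constant, single distance cutoff. The low-frequency
# eigenmodes of the Hessian approximate the collective motions the
# conformer generator follows.

# one node per residue: CA (protein) / P (dna) / first heavy atom fallback
cg_nodes <- function(s) {
  a <- s$atoms[!s$atoms$is_hydrogen, ]
  key <- paste(a$chain, a$resseq)
  ukey <- unique(key)
  pick <- vapply(ukey, function(k) {
    idx <- which(key == k)
    bb <- idx[a$name[idx] %in% c("CA", "P")]
    if (length(bb)) bb[1] else idx[1]
  }, integer(1))
  data.frame(chain = a$chain[pick], resseq = a$resseq[pick],
             x = a$x[pick], y = a$y[pick], z = a$z[pick],
             stringsAsFactors = FALSE)
}

#' Build an anisotropic network model
#'
#' Standard ANM Hessian: for each node pair within `cutoff`, the
#' off-diagonal 3x3 super-block is `-gamma * (r r^T) / |r|^2` with `r` the
#' inter-node vector; diagonal blocks are minus the sum of the row's
#' off-diagonal blocks, which enforces translation invariance exactly.
#'
#' @param s an `apt_structure` (>= 2 residues after coarse-graining)
#' @param cutoff interaction cutoff, nm
#' @param gamma uniform spring constant (arbitrary energy/nm^2; cancels in
#'   mode shapes)
#' @return object of class `enm_model` with the node table, the 3N x 3N
#'   Hessian, and a `connected` flag (a disconnected network still yields
#'   modes, but with more than six near-zero eigenvalues)
#' @export
build_enm <- function(s, cutoff = 1.5, gamma = 1) {
  nodes <- cg_nodes(s)
  n <- nrow(nodes)
  if (n < 2) stop("need at least 2 coarse-grained nodes")
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  d2 <- cross_dist2(xyz, xyz)
  adj <- d2 <= cutoff^2 & d2 > 1e-12
  H <- matrix(0, 3 * n, 3 * n)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    r <- xyz[j, ] - xyz[i, ]
    blk <- -gamma * tcrossprod(r) / sum(r^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  connected <- is_connected(adj)
  if (!connected)
    warning("elastic network is disconnected; expect > 6 near-zero modes")
  structure(list(nodes = nodes, coords = xyz, cutoff = cutoff, gamma = gamma,
                 hessian = H, connected = connected),
            class = "enm_model")
}

# breadth-first connectivity on the contact graph
is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' @export
print.enm_model <- function(x, ...) {
  cat(sprintf("<enm_model> %d nodes, cutoff %.2f nm, gamma %g, %sconnected\n",
              nrow(x$nodes), x$cutoff, x$gamma,
              if (x$connected) "" else "NOT "))
  invisible(x)
}

#' Compute the lowest normal modes of an elastic network
#'
#' Dense symmetric eigendecomposition of the Hessian; eigenvalues are
#' returned ascending with tiny negative round-off clamped at zero.
#' Rigid-body modes are identified by eigenvalue below `rigid_tol` times
#' the largest eigenvalue (six of them for a connected 3-D network).
#'
#' @param m an `enm_model`
#' @param k number of modes to keep (smallest eigenvalues first)
#' @param rigid_tol relative threshold for the rigid-mode count
#' @return object of class `mode_set`: `values` (ascending), `vectors`
#'   (3N x k orthonormal), `n_rigid`
#' @export
compute_modes <- function(m, k = 20, rigid_tol = 1e-8) {
  n3 <- nrow(m$hessian)
  if (k > n3) stop("k exceeds 3N = ", n3)
  eg <- eigen(m$hessian, symmetric = TRUE)
  ord <- rev(seq_len(n3))           # ascending
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  vmax <- max(vals)
  n_rigid <- sum(vals < rigid_tol * vmax)
  vals <- pmax(vals, 0)
  structure(list(values = vals[seq_len(k)],
                 vectors = vecs[, seq_len(k), drop = FALSE],
                 n_rigid = n_rigid, rigid_tol = rigid_tol),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d modes, %d rigid; lowest non-rigid eigenvalues: %s\n",
              length(x$values), x$n_rigid,
              paste(signif(utils::head(x$values[-seq_len(x$n_rigid)], 4), 3),
                    collapse = ", ")))
  invisible(x)
}

# indices of non-rigid modes within a mode_set
nonrigid_modes <- function(modes) {
  idx <- seq_along(modes$values)
  idx[idx > modes$n_rigid]
}

#' Overlap of each mode with an inter-group distance coordinate
#'
#' For each mode, the absolute cosine between the (unit) mode vector and
#' the gradient of the centre-of-mass distance between two node groups: 1
#' means the mode moves purely along the group-group distance, 0 means it
#' leaves it unchanged. Used to pick the "scissoring" mode that drives the
#' two heparin-binding domains apart.
#'
#' @param m an `enm_model`
#' @param modes a `mode_set` from [compute_modes()]
#' @param map a `domain_map` resolving the groups on the model's nodes
#' @param groupA,groupB group names (character vectors allowed)
#' @return numeric vector of per-mode overlaps in `[0, 1]`
#' @export
mode_distance_overlap <- function(m, modes, map, groupA, groupB) {
  ia <- node_indices(m, map_residues(map, groupA))
  ib <- node_indices(m, map_residues(map, groupB))
  if (!length(ia) || !length(ib)) stop("empty group in mode_distance_overlap")
  comA <- colMeans(m$coords[ia, , drop = FALSE])
  comB <- colMeans(m$coords[ib, , drop = FALSE])
  u <- unit_vec(comB - comA)
  n <- nrow(m$coords)
  g <- numeric(3 * n)
  for (i in ia) g[(3 * i - 2):(3 * i)] <- -u / length(ia)
  for (i in ib) g[(3 * i - 2):(3 * i)] <- u / length(ib)
  g <- g / sqrt(sum(g^2))
  as.numeric(abs(crossprod(modes$vectors, g)))
}

# node rows matching a residue selection
node_indices <- function(m, res) {
  key <- paste(m$nodes$chain, m$nodes$resseq)
  which(key %in% paste(res$chain, res$resseq))
}
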