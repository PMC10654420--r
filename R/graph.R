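#' k-nearest-neighbor residue graph
#'
#' Row `i` of the returned index lists the `min(k, N-1)` residues nearest
#' to residue `i` by C-alpha Euclidean distance, in ascending order, with
#' ties broken by lower residue index. Self is never a neighbor.
#'
#' @param structure A [backbone_structure()] with at least 2 residues.
#' @param k Neighbors per residue (default 30, the standard choice for
#'   residue proximity graphs).
#' @return A list of class `"knn_graph"` with `nbr` (N x k' integer
#'   matrix, `k' = min(k, N-1)`, `NA`-padded never in practice since k' is
#'   exact), `valid` (N x k' logical, all `TRUE` here; kept parallel for
#'   degenerate chains), `k` (requested k) and `n`.
#' @export
build_knn_graph <- function(structure, k = 30L) {
  n <- structure$n_residues
  if (n < 2L) stop("build_knn_graph: need at least 2 residues")
  kk <- min(as.integer(k), n - 1L)
  # distances are rounded to 1e-6 A before sorting so that exact geometric
  # ties (e.g. the periodic distances of an ideal helix) are broken by the
  # residue-index rule identically before and after any rigid motion
  D <- round(as.matrix(stats::dist(structure$CA)), 6L)
  nbr <- matrix(NA_integer_, n, kk)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], seq_len(n)[-i])  # tie-break by lower index
    nbr[i, ] <- (seq_len(n)[-i])[ord][seq_len(kk)]
  }
  structure(list(nbr = nbr, valid = matrix(TRUE, n, kk), k = as.integer(k),
                 k_eff = kk, n = n),
            class = "knn_graph")
}

#' Raw structural node features
#'
#' Per-residue internal-coordinate features: sin and cos of the backbone
#' dihedrals phi, psi, omega (angles undefined at the termini encode as
#' `(0, 0)`), and the unit vectors from the previous and from the next
#' residue's C-alpha to this one (zero vectors at the termini).
#' All values are invariant (vectors equivariant) under rigid motion.
#'
#' @param structure A [backbone_structure()] with `N >= 3`.
#' @return A list of class `"raw_node_features"` with `dihedral_sincos`
#'   (N x 6: sin/cos of phi, psi, omega), `fwd_unit`, `bwd_unit` (N x 3).
#' @export
compute_node_features <- function(structure) {
  st <- structure
  n <- st$n_residues
  if (n < 3L) stop("compute_node_features: need at least 3 residues")
  phi <- psi <- omg <- rep(NA_real_, n)
  idx <- 2:n
  # phi_i: C(i-1) - N(i) - CA(i) - C(i)
  phi[idx] <- dihedral_angles(st$C[idx - 1L, , drop = FALSE],
                              st$N[idx, , drop = FALSE],
                              st$CA[idx, , drop = FALSE],
                              st$C[idx, , drop = FALSE])
  # omega_i: CA(i-1) - C(i-1) - N(i) - CA(i)
  omg[idx] <- dihedral_angles(st$CA[idx - 1L, , drop = FALSE],
                              st$C[idx - 1L, , drop = FALSE],
                              st$N[idx, , drop = FALSE],
                              st$CA[idx, , drop = FALSE])
  jdx <- 1:(n - 1L)
  # psi_i: N(i) - CA(i) - C(i) - N(i+1)
  psi[jdx] <- dihedral_angles(st$N[jdx, , drop = FALSE],
                              st$CA[jdx, , drop = FALSE],
                              st$C[jdx, , drop = FALSE],
                              st$N[jdx + 1L, , drop = FALSE])
  sc <- function(a) cbind(ifelse(is.na(a), 0, sin(a)),
                          ifelse(is.na(a), 0, cos(a)))
  dihedral_sincos <- cbind(sc(phi), sc(psi), sc(omg))
  colnames(dihedral_sincos) <- c("sin_phi", "cos_phi", "sin_psi", "cos_psi",
                                 "sin_omega", "cos_omega")
  unit_rows <- function(X) {
    nr <- sqrt(rowSums(X^2))
    X / ifelse(nr > 0, nr, 1)
  }
  fwd <- matrix(0, n, 3L)  # direction from previous residue
  fwd[2:n, ] <- unit_rows(st$CA[2:n, , drop = FALSE] -
                            st$CA[1:(n - 1L), , drop = FALSE])
  bwd <- matrix(0, n, 3L)  # direction from next residue
  bwd[1:(n - 1L), ] <- unit_rows(st$CA[1:(n - 1L), , drop = FALSE] -
                                   st$CA[2:n, , drop = FALSE])
  structure(list(dihedral_sincos = dihedral_sincos,
                 fwd_unit = fwd, bwd_unit = bwd),
            class = "raw_node_features")
}

#' Raw structural edge features
#'
#' For every graph edge `j -> i`: Gaussian radial basis encodings of the
#' 25 ordered inter-atomic distances between the atom sets
#' `{N, CA, C, O, virtual CB}` of residues `j` and `i`; a one-hot encoding
#' of the sequence offset `i - j` clipped to `[-w, w]`; and the unit
#' vector from `CA(j)` to `CA(i)`. RBF centers are evenly spaced on
#' `[d_min, d_max]` with width equal to the center spacing.
#'
#' @param structure A [backbone_structure()].
#' @param graph A [build_knn_graph()] result on the same structure.
#' @param n_rbf Number of radial basis functions per distance.
#' @param d_min,d_max RBF center range (A).
#' @param w Sequence-offset window half-width.
#' @return A list of class `"raw_edge_features"` with `rbf`
#'   (`(N*k') x (25*n_rbf)`), `seq_offset_onehot` (`(N*k') x (2w+1)`),
#'   `direction` (`(N*k') x 3`); edge rows are ordered residue-major
#'   (all neighbors of residue 1, then of residue 2, ...), plus the flat
#'   index vectors `i_index` and `j_index`.
#' @export
compute_edge_features <- function(structure, graph, n_rbf = 16L,
                                  d_min = 2.0, d_max = 22.0, w = 32L) {
  st <- structure
  n <- graph$n
  kk <- ncol(graph$nbr)
  i_index <- rep(seq_len(n), each = kk)
  j_index <- as.integer(t(graph$nbr))
  CB <- virtual_cbeta_mat(st$N, st$CA, st$C)
  atoms <- list(N = st$N, CA = st$CA, C = st$C, O = st$O, CB = CB)
  centers <- seq(d_min, d_max, length.out = n_rbf)
  sigma <- (d_max - d_min) / (n_rbf - 1L)
  m <- length(i_index)
  rbf <- matrix(NA_real_, m, 25L * n_rbf)
  col <- 0L
  for (a in atoms) {       # atom of residue j
    for (b in atoms) {     # atom of residue i
      d <- sqrt(rowSums((a[j_index, , drop = FALSE] -
                           b[i_index, , drop = FALSE])^2))
      z <- outer(d, centers, function(x, mu) exp(-((x - mu) / sigma)^2))
      rbf[, col + seq_len(n_rbf)] <- z
      col <- col + n_rbf
    }
  }
  off <- pmin(pmax(i_index - j_index, -w), w)
  onehot <- matrix(0, m, 2L * w + 1L)
  onehot[cbind(seq_len(m), off + w + 1L)] <- 1
  dir <- st$CA[i_index, , drop = FALSE] - st$CA[j_index, , drop = FALSE]
  dir <- dir / sqrt(rowSums(dir^2))
  structure(list(rbf = rbf, seq_offset_onehot = onehot, direction = dir,
                 i_index = i_index, j_index = j_index,
                 n_rbf = n_rbf, d_min = d_min, d_max = d_max, w = w),
            class = "raw_edge_features")
}
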