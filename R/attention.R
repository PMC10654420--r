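#' Memory-efficient global graph attention
#'
#' The core layer stack. In `global_pseudo` mode every residue attends to
#' every other; the attention logit of a pair is the scaled query-key dot
#' product plus an additive bias read from the edge feature when the pair
#' is a graph edge and from a learnable per-layer pseudo-edge feature when
#' it is not (self pairs included, since k-NN edges exclude self). The
#' pseudo-edge bias contributes one scalar per layer, so edge-feature
#' memory stays O(N*k + L) instead of O(N^2); for long chains attention
#' rows are processed in streaming chunks so no O(N^2) activation is ever
#' cached. `global_dense` is the O(N^2) ablation with real edge features
#' everywhere, and `local` restricts the softmax to graph neighbors.
#'
#' @name attention_core
NULL

LN_EPS <- 1e-5

layer_norm <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  xhat <- xc / sqrt(v + LN_EPS)
  sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`)
}

# backward: returns dX and parameter grads; recomputes the cheap stats
layer_norm_backward <- function(dY, X, g) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  sd_ <- sqrt(v + LN_EPS)
  xhat <- xc / sd_
  dxhat <- sweep(dY, 2L, g, `*`)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd_
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

#' Attention bias from edge and pseudo-edge features
#'
#' Computes the additive attention bias of one layer: `w_B' e_ij` for
#' graph edges, `w_B' beta` for every non-edge (including self pairs).
#' With `materialize = TRUE` the full N x N matrix is returned (reference
#' form, used as the oracle in tests); otherwise the bias is kept in its
#' streaming form: the per-edge scores plus the single pseudo scalar.
#'
#' @param E Edge features, `(N*k') x d` flat residue-major matrix.
#' @param graph A [build_knn_graph()] result.
#' @param w_B Bias projection vector (length d).
#' @param beta Pseudo-edge feature (length d).
#' @param materialize Return the dense N x N matrix?
#' @return Dense matrix, or a list with `edge_scores` (`N x k'`),
#'   `pseudo_score` (scalar), `graph`.
#' @export
attention_bias <- function(E, graph, w_B, beta, materialize = FALSE) {
  n <- graph$n
  kk <- ncol(graph$nbr)
  if (nrow(E) != n * kk) stop("attention_bias: edge feature shape mismatch")
  be <- as.numeric(E %*% w_B)
  b0 <- sum(w_B * beta)
  edge_scores <- matrix(be, n, kk, byrow = TRUE)
  if (!materialize)
    return(list(edge_scores = edge_scores, pseudo_score = b0, graph = graph))
  B <- matrix(b0, n, n)
  i_index <- rep(seq_len(n), each = kk)
  B[cbind(i_index, as.integer(t(graph$nbr)))] <- be
  B
}

# --- internal layer engine -------------------------------------------------

# split weight views (cheap d x d copies)
wn_split <- function(WN, d) list(W1 = WN[seq_len(d), , drop = FALSE],
                                 W2 = WN[d + seq_len(d), , drop = FALSE])
we_split <- function(WE, d) list(W1 = WE[seq_len(d), , drop = FALSE],
                                 W2 = WE[d + seq_len(d), , drop = FALSE],
                                 W3 = WE[2L * d + seq_len(d), , drop = FALSE])

# global_pseudo layer. H: N x d; E: (N*kk) x d flat residue-major;
# nbr/i_index/j_index describe the graph. chunk_rows: process attention
# rows in chunks of this size when no cache is needed (inference on long
# chains), so that no N x N intermediate is retained.
layer_pseudo_forward <- function(H, E, nbr, i_index, j_index, lp, d,
                                 want_cache = FALSE, chunk_rows = 128L) {
  n <- nrow(H)
  kk <- if (n > 1L) ncol(nbr) else 0L
  Q <- H %*% lp$WQ; K <- H %*% lp$WK; Vv <- H %*% lp$WV
  scl <- 1 / sqrt(d)
  if (kk > 0L) {
    be <- as.numeric(E %*% lp$wB)
    b0 <- sum(lp$wB * lp$beta)
  } else {
    be <- numeric(0); b0 <- sum(lp$wB * lp$beta)
  }
  A <- NULL
  if (n == 1L) {
    AV <- Vv
    w_nb <- matrix(0, 1L, 0L)
    A <- matrix(1, 1L, 1L)
  } else if (want_cache || n <= chunk_rows) {
    S <- tcrossprod(Q, K) * scl + b0
    S[cbind(i_index, j_index)] <- S[cbind(i_index, j_index)] + (be - b0)
    A <- softmax_rows(S)
    AV <- A %*% Vv
    w_nb <- matrix(A[cbind(i_index, j_index)], n, kk, byrow = TRUE)
  } else {
    AV <- matrix(0, n, d)
    w_nb <- matrix(0, n, kk)
    for (s in seq(1L, n, by = chunk_rows)) {
      rows <- s:min(s + chunk_rows - 1L, n)
      Sc <- tcrossprod(Q[rows, , drop = FALSE], K) * scl + b0
      sel <- i_index %in% rows
      ic <- i_index[sel] - s + 1L
      Sc[cbind(ic, j_index[sel])] <- Sc[cbind(ic, j_index[sel])] +
        (be[sel] - b0)
      Ac <- softmax_rows(Sc)
      AV[rows, ] <- Ac %*% Vv
      w_nb[rows, ] <- matrix(Ac[cbind(ic, j_index[sel])],
                             length(rows), kk, byrow = TRUE)
    }
  }
  if (kk > 0L) {
    gam <- rowSums(w_nb)
    u <- w_nb / ifelse(gam > 0, gam, 1)
    u_flat <- as.numeric(t(u))
    eagg <- unname(rowsum(E * u_flat, i_index, reorder = TRUE))
  } else {
    gam <- numeric(n); u <- w_nb; u_flat <- numeric(0)
    eagg <- matrix(0, n, d)
  }
  wn <- wn_split(lp$WN, d)
  Hhat <- AV %*% wn$W1 + eagg %*% wn$W2
  z1 <- Hhat + H
  H1 <- layer_norm(z1, lp$g1, lp$b1)
  if (kk > 0L) {
    we <- we_split(lp$WE, d)
    Ehat <- H1[i_index, , drop = FALSE] %*% we$W1 + E %*% we$W2 +
      H1[j_index, , drop = FALSE] %*% we$W3
    z2 <- Ehat + E
    E1 <- layer_norm(z2, lp$g2, lp$b2)
  } else {
    E1 <- E
    z2 <- E
  }
  out <- list(H = H1, E = E1)
  if (want_cache)
    out$cache <- list(H = H, E = E, Q = Q, K = K, Vv = Vv, A = A,
                      w_nb = w_nb, gam = gam, u = u, eagg = eagg, AV = AV,
                      z1 = z1, H1 = H1, z2 = z2,
                      i_index = i_index, j_index = j_index, kk = kk)
  out
}

# local attention: softmax restricted to graph neighbors
layer_local_forward <- function(H, E, nbr, i_index, j_index, lp, d) {
  n <- nrow(H)
  kk <- ncol(nbr)
  Q <- H %*% lp$WQ; K <- H %*% lp$WK; Vv <- H %*% lp$WV
  be <- as.numeric(E %*% lp$wB)
  qk <- rowSums(Q[i_index, , drop = FALSE] * K[j_index, , drop = FALSE]) /
    sqrt(d) + be
  Snb <- matrix(qk, n, kk, byrow = TRUE)
  Anb <- softmax_rows(Snb)
  a_flat <- as.numeric(t(Anb))
  AV <- unname(rowsum(Vv[j_index, , drop = FALSE] * a_flat, i_index, reorder = TRUE))
  eagg <- unname(rowsum(E * a_flat, i_index, reorder = TRUE))  # gamma = 1 here
  wn <- wn_split(lp$WN, d)
  H1 <- layer_norm(AV %*% wn$W1 + eagg %*% wn$W2 + H, lp$g1, lp$b1)
  we <- we_split(lp$WE, d)
  Ehat <- H1[i_index, , drop = FALSE] %*% we$W1 + E %*% we$W2 +
    H1[j_index, , drop = FALSE] %*% we$W3
  E1 <- layer_norm(Ehat + E, lp$g2, lp$b2)
  list(H = H1, E = E1, A_nb = Anb)
}

# dense layer: full edge features E_full, (N*N) x d flat residue-major
# (slot (i-1)*N + j). The diagonal slot carries whatever the caller put
# there (zero for the ablation model, the pseudo feature when used as the
# oracle for the sparse path); it contributes to the attention bias but is
# excluded from edge aggregation, exactly like self pairs in the sparse
# path.
layer_dense_forward <- function(H, E_full, lp, d) {
  n <- nrow(H)
  i_index <- rep(seq_len(n), each = n)
  j_index <- rep(seq_len(n), times = n)
  Q <- H %*% lp$WQ; K <- H %*% lp$WK; Vv <- H %*% lp$WV
  B <- matrix(as.numeric(E_full %*% lp$wB), n, n, byrow = TRUE)
  A <- softmax_rows(tcrossprod(Q, K) / sqrt(d) + B)
  AV <- A %*% Vv
  Anb <- A
  diag(Anb) <- 0
  gam <- rowSums(Anb)
  U <- Anb / ifelse(gam > 0, gam, 1)
  u_flat <- as.numeric(t(U))
  eagg <- unname(rowsum(E_full * u_flat, i_index, reorder = TRUE))
  wn <- wn_split(lp$WN, d)
  H1 <- layer_norm(AV %*% wn$W1 + eagg %*% wn$W2 + H, lp$g1, lp$b1)
  we <- we_split(lp$WE, d)
  Ehat <- H1[i_index, , drop = FALSE] %*% we$W1 + E_full %*% we$W2 +
    H1[j_index, , drop = FALSE] %*% we$W3
  E1 <- layer_norm(Ehat + E_full, lp$g2, lp$b2)
  list(H = H1, E = E1, A = A)
}

# --- exported layer wrappers ----------------------------------------------

#' Apply one graph attention layer
#'
#' `attention_layer()` is the memory-efficient global layer with
#' pseudo-edge bias; `attention_layer_local()` restricts attention to
#' graph neighbors (the local-view ablation); `attention_layer_dense()`
#' is the O(N^2) layer on fully connected edge features (the pseudo-edge
#' ablation, and the oracle the sparse path is tested against).
#'
#' @param H Node features, N x d.
#' @param E Edge features, `(N*k') x d` flat residue-major (for the dense
#'   variant: `(N*N) x d`, diagonal slots included).
#' @param graph A [build_knn_graph()] result (not used by the dense
#'   variant).
#' @param layer_params List with `WQ`, `WK`, `WV` (d x d), `wB`, `beta`
#'   (length d; `beta` only for the pseudo variant), `WN` (2d x d),
#'   `WE` (3d x d), `g1`, `b1`, `g2`, `b2` (length d).
#' @param chunk_rows Streaming chunk size for long chains.
#' @return List with updated `H` and `E` (and the attention matrix where
#'   it is materialized anyway).
#' @export
attention_layer <- function(H, E, graph, layer_params, chunk_rows = 128L,
                            return_attention = FALSE) {
  d <- ncol(H)
  kk <- ncol(graph$nbr)
  i_index <- rep(seq_len(graph$n), each = kk)
  j_index <- as.integer(t(graph$nbr))
  out <- layer_pseudo_forward(H, E, graph$nbr, i_index, j_index,
                              layer_params, d,
                              want_cache = return_attention,
                              chunk_rows = chunk_rows)
  if (!all(is.finite(out$H)) || !all(is.finite(out$E)))
    stop("attention_layer: non-finite activations")
  if (return_attention) {
    out$A <- out$cache$A
    out$cache <- NULL
  }
  out
}

#' @rdname attention_layer
#' @export
attention_layer_local <- function(H, E, graph, layer_params) {
  d <- ncol(H)
  kk <- ncol(graph$nbr)
  i_index <- rep(seq_len(graph$n), each = kk)
  j_index <- as.integer(t(graph$nbr))
  out <- layer_local_forward(H, E, graph$nbr, i_index, j_index,
                             layer_params, d)
  if (!all(is.finite(out$H)) || !all(is.finite(out$E)))
    stop("attention_layer_local: non-finite activations")
  out
}

#' @rdname attention_layer
#' @param E_full Fully connected edge features, `(N*N) x d` flat
#'   residue-major including diagonal slots.
#' @export
attention_layer_dense <- function(H, E_full, layer_params) {
  d <- ncol(H)
  if (nrow(E_full) != nrow(H)^2)
    stop("attention_layer_dense: E_full must have N^2 rows")
  out <- layer_dense_forward(H, E_full, layer_params, d)
  if (!all(is.finite(out$H)) || !all(is.finite(out$E)))
    stop("attention_layer_dense: non-finite activations")
  out
}

#' Build fully connected edge features for the dense variant
#'
#' Featurizes every ordered residue pair (the complete graph) and embeds
#' with the model's edge embedding; diagonal slots are filled with
#' `diag_fill` (zeros for the ablation model, a layer's pseudo-edge
#' feature when constructing the dense oracle of the sparse path).
#'
#' @param structure A [backbone_structure()].
#' @param model An [ipf_model()].
#' @param diag_fill Length-d vector for the (i, i) slots.
#' @return `(N*N) x d` matrix, flat residue-major.
#' @export
dense_edge_features <- function(structure, model, diag_fill = NULL) {
  n <- structure$n_residues
  d <- model$config$d
  # complete graph: neighbors of i are all j != i in index order
  nbr <- matrix(unlist(lapply(seq_len(n), function(i) seq_len(n)[-i])),
                n, n - 1L, byrow = TRUE)
  g <- structure(list(nbr = nbr, valid = matrix(TRUE, n, n - 1L),
                      k = n - 1L, k_eff = n - 1L, n = n),
                 class = "knn_graph")
  raw <- compute_edge_features(structure, g, n_rbf = model$config$n_rbf,
                               d_min = model$config$d_min,
                               d_max = model$config$d_max, w = model$config$w)
  eS <- cbind(raw$rbf, raw$seq_offset_onehot)
  p <- model$params
  e1 <- gvp_forward(eS, raw$direction[, 1L, drop = FALSE],
                    raw$direction[, 2L, drop = FALSE],
                    raw$direction[, 3L, drop = FALSE], p$edge_gvp1)
  e2 <- gvp_forward(e1$S, e1$Vx, e1$Vy, e1$Vz, p$edge_gvp2)
  if (is.null(diag_fill)) diag_fill <- rep(0, d)
  E_full <- matrix(0, n * n, d)
  flat <- (raw$i_index - 1L) * n + raw$j_index
  E_full[flat, ] <- e2$S
  diag_idx <- (seq_len(n) - 1L) * n + seq_len(n)
  E_full[diag_idx, ] <- matrix(diag_fill, n, d, byrow = TRUE)
  E_full
}
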