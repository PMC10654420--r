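#' Geometric feature embedding
#'
#' Raw structural features are embedded by two geometric-vector-perceptron
#' (GVP) style layers: vector channels are mixed by channel-wise linear
#' maps (rotation-equivariant), their norms join the scalar track
#' (rotation-invariant), and scalar outputs gate the vector channels.
#' Only the scalar track feeds the attention stack, so the final node and
#' edge embeddings are invariant under rigid motions while still encoding
#' relative vector geometry through norms of mixed channels (e.g. the
#' norm of a linear combination of the forward and backward chain
#' directions encodes their angle). Token features (21-symbol embedding
#' table) are concatenated with the structural node scalars and mapped
#' linearly to width `d`.
#'
#' @name embedding
NULL

relu <- function(x) (x > 0) * x
GVP_EPS <- 1e-8

# One GVP block. S: n x ns scalars; Vx,Vy,Vz: n x nv vector components.
# p: list(Wh (nh x nv), Ws (ns_out x (ns+nh)), bs, and optionally
# Wv (nvo x nh), Wg (nvo x ns_out), bg for a vector output track).
gvp_forward <- function(S, Vx, Vy, Vz, p, want_cache = FALSE) {
  Vhx <- Vx %*% t(p$Wh); Vhy <- Vy %*% t(p$Wh); Vhz <- Vz %*% t(p$Wh)
  Nrm <- sqrt(Vhx^2 + Vhy^2 + Vhz^2 + GVP_EPS)
  ns <- ncol(S)
  # Ws acts on [S | Nrm]; applying the two blocks separately avoids
  # materializing the concatenation for the (large) edge feature track
  Ws_s <- p$Ws[, seq_len(ns), drop = FALSE]
  Ws_n <- p$Ws[, -seq_len(ns), drop = FALSE]
  Z <- sweep(tcrossprod(S, Ws_s) + tcrossprod(Nrm, Ws_n), 2L, p$bs, `+`)
  SM <- relu(Z)
  out <- list(S = SM)
  if (!is.null(p$Wv)) {
    Gz <- sweep(SM %*% t(p$Wg), 2L, p$bg, `+`)
    G <- 1 / (1 + exp(-Gz))
    out$Vx <- (Vhx %*% t(p$Wv)) * G
    out$Vy <- (Vhy %*% t(p$Wv)) * G
    out$Vz <- (Vhz %*% t(p$Wv)) * G
    if (want_cache) out$cache <- list(Vhx = Vhx, Vhy = Vhy, Vhz = Vhz,
                                      Nrm = Nrm, Z = Z, G = G,
                                      VWx = Vhx %*% t(p$Wv),
                                      VWy = Vhy %*% t(p$Wv),
                                      VWz = Vhz %*% t(p$Wv))
  } else if (want_cache) {
    out$cache <- list(Vhx = Vhx, Vhy = Vhy, Vhz = Vhz, Nrm = Nrm, Z = Z)
  }
  out
}

# backward through gvp_forward. dS_out: grad wrt scalar output; dV*_out:
# grads wrt vector outputs (NULL if no vector track). Returns grads for
# params and inputs.
gvp_backward <- function(dS_out, dVx_out, dVy_out, dVz_out,
                         S, Vx, Vy, Vz, p, cache) {
  ns <- ncol(S)
  dSM <- dS_out
  g <- list()
  dVhx <- dVhy <- dVhz <- 0
  if (!is.null(p$Wv)) {
    dG <- dVx_out * cache$VWx + dVy_out * cache$VWy + dVz_out * cache$VWz
    dVWx <- dVx_out * cache$G; dVWy <- dVy_out * cache$G; dVWz <- dVz_out * cache$G
    dVhx <- dVWx %*% p$Wv; dVhy <- dVWy %*% p$Wv; dVhz <- dVWz %*% p$Wv
    g$Wv <- t(dVWx) %*% cache$Vhx + t(dVWy) %*% cache$Vhy + t(dVWz) %*% cache$Vhz
    dGz <- dG * cache$G * (1 - cache$G)
    dSM <- dSM + dGz %*% p$Wg
    g$Wg <- t(dGz) %*% relu(cache$Z)
    g$bg <- colSums(dGz)
  }
  dZ <- dSM * (cache$Z > 0)
  g$Ws <- cbind(crossprod(dZ, S), crossprod(dZ, cache$Nrm))
  g$bs <- colSums(dZ)
  Ws_s <- p$Ws[, seq_len(ns), drop = FALSE]
  Ws_n <- p$Ws[, -seq_len(ns), drop = FALSE]
  dS <- dZ %*% Ws_s
  dNrm <- dZ %*% Ws_n
  inv <- dNrm / cache$Nrm
  dVhx <- dVhx + inv * cache$Vhx
  dVhy <- dVhy + inv * cache$Vhy
  dVhz <- dVhz + inv * cache$Vhz
  g$Wh <- t(dVhx) %*% Vx + t(dVhy) %*% Vy + t(dVhz) %*% Vz
  list(grads = g, dS = dS,
       dVx = dVhx %*% p$Wh, dVy = dVhy %*% p$Wh, dVz = dVhz %*% p$Wh)
}

#' Embed raw features and a partial sequence into graph features
#'
#' Applies the two-layer GVP embedding to node and edge features, embeds
#' the 21-symbol tokens, and produces the initial node features `H0`
#' (N x d) and edge features `E0` ((N*k') x d, residue-major flat layout).
#'
#' @param raw_node A [compute_node_features()] result.
#' @param raw_edge A [compute_edge_features()] result.
#' @param partial A [partial_sequence()] of matching length.
#' @param model An [ipf_model()] (supplies parameters and width `d`).
#' @param want_cache Keep forward intermediates for backpropagation.
#' @return A list of class `"residue_graph"`: `H0`, `E0`, `i_index`,
#'   `j_index`, `n`, plus `cache` when requested.
#' @export
embed_graph <- function(raw_node, raw_edge, partial, model,
                        want_cache = FALSE) {
  p <- model$params
  n <- nrow(raw_node$dihedral_sincos)
  if (length(partial$tokens) != n)
    stop("embed_graph: partial sequence length != number of residues")
  # node track: scalars = dihedral sin/cos, vectors = chain directions
  nS <- raw_node$dihedral_sincos
  nVx <- cbind(raw_node$fwd_unit[, 1L], raw_node$bwd_unit[, 1L])
  nVy <- cbind(raw_node$fwd_unit[, 2L], raw_node$bwd_unit[, 2L])
  nVz <- cbind(raw_node$fwd_unit[, 3L], raw_node$bwd_unit[, 3L])
  n1 <- gvp_forward(nS, nVx, nVy, nVz, p$node_gvp1, want_cache)
  n2 <- gvp_forward(n1$S, n1$Vx, n1$Vy, n1$Vz, p$node_gvp2, want_cache)
  tok <- p$token_emb[partial$tokens, , drop = FALSE]
  Hcat <- cbind(n2$S, tok)
  H0 <- sweep(Hcat %*% p$W_node_in, 2L, p$b_node_in, `+`)
  # edge track: scalars = RBF + sequence offset, vector = CA direction
  eS <- cbind(raw_edge$rbf, raw_edge$seq_offset_onehot)
  eVx <- raw_edge$direction[, 1L, drop = FALSE]
  eVy <- raw_edge$direction[, 2L, drop = FALSE]
  eVz <- raw_edge$direction[, 3L, drop = FALSE]
  e1 <- gvp_forward(eS, eVx, eVy, eVz, p$edge_gvp1, want_cache)
  e2 <- gvp_forward(e1$S, e1$Vx, e1$Vy, e1$Vz, p$edge_gvp2, want_cache)
  E0 <- e2$S
  out <- structure(list(H0 = H0, E0 = E0,
                        i_index = raw_edge$i_index,
                        j_index = raw_edge$j_index, n = n),
                   class = "residue_graph")
  if (want_cache)
    out$cache <- list(n1 = n1, n2 = n2, e1 = e1, e2 = e2,
                      nS = nS, nVx = nVx, nVy = nVy, nVz = nVz,
                      eS = eS, eVx = eVx, eVy = eVy, eVz = eVz,
                      Hcat = Hcat, tokens = partial$tokens)
  out
}
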