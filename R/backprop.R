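#' Loss and analytic gradients
#'
#' Hand-derived reverse-mode differentiation of the full pipeline
#' (embedding GVPs, token embedding, attention stack, output head) for the
#' `global_pseudo` attention mode. Verified against central finite
#' differences in the test suite.
#'
#' @name backprop
NULL

# scatter-add rows of M into an n-row accumulator by group index
scatter_rows <- function(M, index, n) {
  tmp <- rowsum(M, index, reorder = TRUE)
  out <- matrix(0, n, ncol(M))
  out[as.integer(rownames(tmp)), ] <- tmp
  out
}

# backward through one global_pseudo layer; returns dH, dE and grads
layer_pseudo_backward <- function(dH1_in, dE1, lp, d, cache) {
  n <- nrow(cache$H)
  kk <- cache$kk
  i_index <- cache$i_index; j_index <- cache$j_index
  g <- list()
  dH1 <- dH1_in
  dE_acc <- NULL
  if (kk > 0L) {
    we <- we_split(lp$WE, d)
    lb2 <- layer_norm_backward(dE1, cache$z2, lp$g2)
    g$g2 <- lb2$dg; g$b2 <- lb2$db
    dEhat <- lb2$dX
    dE_acc <- dEhat  # residual branch
    Hi <- cache$H1[i_index, , drop = FALSE]
    Hj <- cache$H1[j_index, , drop = FALSE]
    g$WE <- rbind(t(Hi) %*% dEhat, t(cache$E) %*% dEhat, t(Hj) %*% dEhat)
    dH1 <- dH1 + scatter_rows(dEhat %*% t(we$W1), i_index, n) +
      scatter_rows(dEhat %*% t(we$W3), j_index, n)
    dE_acc <- dE_acc + dEhat %*% t(we$W2)
  } else {
    g$g2 <- rep(0, d); g$b2 <- rep(0, d); g$WE <- matrix(0, 3L * d, d)
  }
  lb1 <- layer_norm_backward(dH1, cache$z1, lp$g1)
  g$g1 <- lb1$dg; g$b1 <- lb1$db
  dHhat <- lb1$dX
  dH_acc <- dHhat  # residual branch
  wn <- wn_split(lp$WN, d)
  dAV <- dHhat %*% t(wn$W1)
  deagg <- dHhat %*% t(wn$W2)
  g$WN <- rbind(t(cache$AV) %*% dHhat, t(cache$eagg) %*% dHhat)
  if (kk > 0L) {
    # edge aggregation: eagg_i = sum_m u_im e_im, u = w/gamma
    u_flat <- as.numeric(t(cache$u))
    dE_acc <- dE_acc + deagg[i_index, , drop = FALSE] * u_flat
    du <- matrix(rowSums(deagg[i_index, , drop = FALSE] * cache$E),
                 n, kk, byrow = TRUE)
    gam_safe <- ifelse(cache$gam > 0, cache$gam, 1)
    dw_nb <- (du - rowSums(du * cache$u)) / gam_safe
    dw_nb[cache$gam == 0, ] <- 0
    # attention matrix
    dA <- dAV %*% t(cache$Vv)
    dVv <- t(cache$A) %*% dAV
    dA[cbind(i_index, j_index)] <- dA[cbind(i_index, j_index)] +
      as.numeric(t(dw_nb))
    dS <- cache$A * (dA - rowSums(dA * cache$A))
    scl <- 1 / sqrt(d)
    dQ <- dS %*% cache$K * scl
    dK <- t(dS) %*% cache$Q * scl
    dbe <- dS[cbind(i_index, j_index)]
    db0 <- sum(dS) - sum(dbe)
    g$wB <- as.numeric(t(cache$E) %*% dbe) + db0 * lp$beta
    g$beta <- db0 * lp$wB
    dE_acc <- dE_acc + outer(dbe, lp$wB)
  } else {
    # single node: A = [[1]] is constant, AV = Vv
    dVv <- dAV
    dQ <- dK <- matrix(0, n, d)
    g$wB <- rep(0, d); g$beta <- rep(0, d)
    dE_acc <- matrix(0, 0L, d)
  }
  g$WQ <- t(cache$H) %*% dQ
  g$WK <- t(cache$H) %*% dK
  g$WV <- t(cache$H) %*% dVv
  dH_acc <- dH_acc + dQ %*% t(lp$WQ) + dK %*% t(lp$WK) + dVv %*% t(lp$WV)
  list(dH = dH_acc, dE = dE_acc, grads = g)
}

#' Negative log-likelihood loss and gradients for one example
#'
#' Runs the forward pass with caching and backpropagates the mean
#' negative log-likelihood of the native residues over the in-scope
#' positions through every parameter.
#'
#' @param model An [ipf_model()] with `attention_mode = "global_pseudo"`.
#' @param feats A [featurize_structure()] result.
#' @param partial The (corrupted) input [partial_sequence()].
#' @param native Native tokens (integer 1..20) or sequence string.
#' @param scope Logical vector of positions entering the loss; default all.
#' @return List with `loss` (scalar) and `grads` (same structure as
#'   `model$params`).
#' @export
loss_and_gradients <- function(model, feats, partial, native, scope = NULL) {
  if (model$config$attention_mode != "global_pseudo")
    stop("loss_and_gradients: training backprop is implemented for the ",
         "global_pseudo attention mode")
  if (is.character(native)) native <- tokenize(native)
  if (any(native > 20L)) stop("native sequence contains unknown tokens")
  fw <- model_forward(model, feats, partial, want_cache = TRUE)
  probs <- fw$cache$probs
  n <- nrow(probs)
  if (is.null(scope)) scope <- rep(TRUE, n)
  if (!any(scope)) stop("loss_and_gradients: empty scope")
  ns <- sum(scope)
  p_nat <- probs[cbind(seq_len(n), native)]
  loss <- -mean(log(pmax(p_nat[scope], 1e-12)))

  d <- model$config$d
  # output head
  dlogits <- probs
  dlogits[cbind(seq_len(n), native)] <-
    dlogits[cbind(seq_len(n), native)] - 1
  dlogits <- dlogits * scope / ns
  g <- list(WP = t(fw$cache$H_L) %*% dlogits)
  dH <- dlogits %*% t(model$params$WP)
  kk <- fw$cache$layers[[1L]]$kk
  dE <- matrix(0, max(kk, 0L) * n, d)

  g$layers <- vector("list", model$config$L)
  for (l in rev(seq_len(model$config$L))) {
    lb <- layer_pseudo_backward(dH, dE, model$params$layers[[l]], d,
                                fw$cache$layers[[l]])
    g$layers[[l]] <- lb$grads
    dH <- lb$dH; dE <- lb$dE
  }

  # embedding backward
  emb <- fw$cache$emb
  ec <- emb$cache
  p <- model$params
  dW_node_in <- t(ec$Hcat) %*% dH
  db_node_in <- colSums(dH)
  dHcat <- dH %*% t(p$W_node_in)
  ns2 <- ncol(ec$n2$S)
  dnode_s2 <- dHcat[, seq_len(ns2), drop = FALSE]
  dtok <- dHcat[, ns2 + seq_len(model$config$d_seq), drop = FALSE]
  dtoken_emb <- matrix(0, 21L, model$config$d_seq)
  tmp <- rowsum(dtok, ec$tokens, reorder = TRUE)
  dtoken_emb[as.integer(rownames(tmp)), ] <- tmp

  b2n <- gvp_backward(dnode_s2, NULL, NULL, NULL,
                      ec$n1$S, ec$n1$Vx, ec$n1$Vy, ec$n1$Vz,
                      p$node_gvp2, ec$n2$cache)
  b1n <- gvp_backward(b2n$dS, b2n$dVx, b2n$dVy, b2n$dVz,
                      ec$nS, ec$nVx, ec$nVy, ec$nVz,
                      p$node_gvp1, ec$n1$cache)
  if (kk > 0L) {
    b2e <- gvp_backward(dE, NULL, NULL, NULL,
                        ec$e1$S, ec$e1$Vx, ec$e1$Vy, ec$e1$Vz,
                        p$edge_gvp2, ec$e2$cache)
    b1e <- gvp_backward(b2e$dS, b2e$dVx, b2e$dVy, b2e$dVz,
                        ec$eS, ec$eVx, ec$eVy, ec$eVz,
                        p$edge_gvp1, ec$e1$cache)
    g$edge_gvp2 <- b2e$grads
    g$edge_gvp1 <- b1e$grads
  } else {
    zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
    g$edge_gvp2 <- zero_like(p$edge_gvp2)
    g$edge_gvp1 <- zero_like(p$edge_gvp1)
  }
  g$node_gvp2 <- b2n$grads
  g$node_gvp1 <- b1n$grads
  g$token_emb <- dtoken_emb
  g$W_node_in <- dW_node_in
  g$b_node_in <- db_node_in
  # order grads to mirror params
  g <- g[names(p)[names(p) %in% names(g)]]
  list(loss = loss, grads = g, probs = probs)
}
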