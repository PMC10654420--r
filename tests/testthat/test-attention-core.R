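# global graph attention: bias streaming, layer contracts, variants,
# forward determinism, gradient flow

test_that("attention bias: streaming form equals the materialized matrix", {
  d <- 10L
  for (seed in 1:5) {
    inp <- random_layer_inputs(n = 7L, k = 3L, d = d, seed = seed)
    wB <- runif(d, -1, 1); beta <- runif(d, -1, 1)
    B <- attention_bias(inp$E, inp$graph, wB, beta, materialize = TRUE)
    s <- attention_bias(inp$E, inp$graph, wB, beta, materialize = FALSE)
    B2 <- matrix(s$pseudo_score, 7L, 7L)
    kk <- ncol(inp$graph$nbr)
    B2[cbind(rep(1:7, each = kk), as.integer(t(inp$graph$nbr)))] <-
      as.numeric(t(s$edge_scores))
    expect_equal(B, B2, tolerance = 1e-12)
    # self pairs use the pseudo value
    expect_equal(diag(B), rep(sum(wB * beta), 7L))
  }
})

test_that("zero bias projection gives zero bias; constant bias cancels in softmax", {
  d <- 8L
  inp <- random_layer_inputs(n = 6L, k = 3L, d = d, seed = 2L)
  B <- attention_bias(inp$E, inp$graph, rep(0, d), runif(d),
                      materialize = TRUE)
  expect_true(all(B == 0))
  # beta equal to every edge feature makes the bias constant, so the
  # attention equals feature-only attention (softmax shift invariance)
  lp <- random_layer_params(d, seed = 3L)
  const_e <- runif(d)
  Ec <- matrix(const_e, nrow(inp$E), d, byrow = TRUE)
  lp_c <- lp
  lp_c$beta <- const_e
  out1 <- attention_layer(inp$H, Ec, inp$graph, lp_c, return_attention = TRUE)
  lp_0 <- lp
  lp_0$wB <- rep(0, d)
  lp_0$beta <- rep(0, d)
  out0 <- attention_layer(inp$H, Ec, inp$graph, lp_0, return_attention = TRUE)
  expect_equal(out1$A, out0$A, tolerance = 1e-10)
})

test_that("attention rows are stochastic; single-node graphs degrade gracefully", {
  for (seed in 1:5) {
    n <- sample(3:20, 1L)
    d <- 8L
    inp <- random_layer_inputs(n = n, k = 4L, d = d, seed = seed)
    lp <- random_layer_params(d, seed = seed + 50L)
    out <- attention_layer(inp$H, inp$E, inp$graph, lp,
                           return_attention = TRUE)
    expect_lt(max(abs(rowSums(out$A) - 1)), 1e-6)
    expect_true(all(is.finite(out$H)) && all(is.finite(out$E)))
  }
  # N = 1: no neighbors; attention collapses to self, output finite
  d <- 8L
  lp <- random_layer_params(d, seed = 9L)
  H1 <- matrix(rnorm(d), 1L, d)
  out <- ipfrefine:::layer_pseudo_forward(H1, matrix(0, 0L, d), NULL,
                                          integer(0), integer(0), lp, d,
                                          want_cache = TRUE)
  expect_equal(out$cache$A, matrix(1, 1L, 1L))
  expect_true(all(is.finite(out$H)))
})

test_that("pseudo layer equals the dense oracle on complete graphs", {
  # the dense Eq.4-style layer with the pseudo-edge feature filled into
  # the (self) non-edge slots is the oracle for the sparse path
  worst <- 0
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(2:12, 1L)
    d <- 10L
    inp <- random_layer_inputs(n = n, k = n - 1L, d = d, seed = seed)
    lp <- random_layer_params(d, seed = seed + 500L)
    o1 <- attention_layer(inp$H, inp$E, inp$graph, lp)
    kk <- n - 1L
    ii <- rep(seq_len(n), each = kk)
    jj <- as.integer(t(inp$graph$nbr))
    E_full <- matrix(lp$beta, n * n, d, byrow = TRUE)
    E_full[(ii - 1L) * n + jj, ] <- inp$E
    o2 <- attention_layer_dense(inp$H, E_full, lp)
    worst <- max(worst, max(abs(o1$H - o2$H)),
                 max(abs(o1$E - o2$E[(ii - 1L) * n + jj, ])))
  }
  expect_lt(worst, 1e-6)
})

test_that("embedded-feature pipeline also matches the dense oracle", {
  n <- 12L
  m <- tiny_model(d = 10L, L = 1L, k = n - 1L, seed = 77L)
  st <- toy_structure(n, seed = 77L)
  feats <- featurize_structure(st, m)
  emb <- embed_graph(feats$raw_node, feats$raw_edge,
                     partial_sequence(strrep("X", n)), m)
  lp <- m$params$layers[[1L]]
  o1 <- attention_layer(emb$H0, emb$E0, feats$graph, lp)
  Ef <- dense_edge_features(st, m, diag_fill = lp$beta)
  o2 <- attention_layer_dense(emb$H0, Ef, lp)
  expect_lt(max(abs(o1$H - o2$H)), 1e-6)
})

test_that("local attention: neighbor-restricted softmax, insensitive to non-neighbors", {
  d <- 8L
  inp <- random_layer_inputs(n = 12L, k = 3L, d = d, seed = 4L)
  lp <- random_layer_params(d, seed = 5L)
  out <- attention_layer_local(inp$H, inp$E, inp$graph, lp)
  expect_lt(max(abs(rowSums(out$A_nb) - 1)), 1e-6)
  # perturbing a non-neighbor's features leaves node 1's local update
  # unchanged, but changes it under global pseudo attention
  non_nbr <- setdiff(seq_len(12L), c(1L, inp$graph$nbr[1L, ]))[1L]
  H2 <- inp$H
  H2[non_nbr, ] <- H2[non_nbr, ] + 1
  out2 <- attention_layer_local(H2, inp$E, inp$graph, lp)
  expect_equal(out$H[1L, ], out2$H[1L, ], tolerance = 1e-12)
  g1 <- attention_layer(inp$H, inp$E, inp$graph, lp)
  g2 <- attention_layer(H2, inp$E, inp$graph, lp)
  expect_gt(max(abs(g1$H[1L, ] - g2$H[1L, ])), 1e-8)
})

test_that("permuting node order permutes layer outputs consistently", {
  d <- 8L
  n <- 9L
  inp <- random_layer_inputs(n = n, k = 3L, d = d, seed = 6L)
  lp <- random_layer_params(d, seed = 7L)
  out <- attention_layer(inp$H, inp$E, inp$graph, lp)
  perm <- sample(n)
  inv <- order(perm)
  # permuted inputs: node rows reordered, neighbor indices relabeled
  kk <- ncol(inp$graph$nbr)
  g2 <- inp$graph
  g2$nbr <- matrix(inv[inp$graph$nbr[perm, ]], n, kk)
  ord <- rep((perm - 1L) * kk, each = kk) + seq_len(kk)
  E2 <- inp$E[ord, , drop = FALSE]
  out2 <- attention_layer(inp$H[perm, , drop = FALSE], E2, g2, lp)
  expect_equal(out2$H, out$H[perm, , drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(out2$E, out$E[ord, , drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("forward is deterministic, row-stochastic and SE(3)-invariant end to end", {
  m <- tiny_model(seed = 8L)
  st <- toy_structure(16L, seed = 8L)
  p1 <- predict(m, st)
  p2 <- predict(m, st)
  expect_identical(p1$probs, p2$probs)
  expect_lt(max(abs(rowSums(p1$probs) - 1)), 1e-6)
  expect_lt(max(abs(p1$entropy - ipfrefine:::row_entropy(p1$probs))), 1e-9)
  for (r in 1:5) {
    tr <- random_rigid_transform()
    p3 <- predict(m, transform_structure(st, tr$R, tr$t))
    expect_lt(max(abs(p3$probs - p1$probs)), 1e-5)
  }
})

test_that("streaming chunked attention equals the full computation", {
  m_small <- tiny_model(d = 16L, L = 2L, k = 8L, seed = 5L)
  m_small$config$chunk_rows <- 11L
  st <- toy_structure(47L, seed = 5L)
  p_chunk <- predict(m_small, st)
  m_small$config$chunk_rows <- 1000L
  p_full <- predict(m_small, st)
  expect_lt(max(abs(p_chunk$probs - p_full$probs)), 1e-12)
})

test_that("analytic gradients match finite differences on a tiny instance", {
  set.seed(10)
  m <- tiny_model(d = 8L, L = 2L, k = 4L, seed = 3L)
  st <- toy_structure(9L, seed = 11L)
  nat <- tokenize(couple_sequence(st))
  feats <- featurize_structure(st, m)
  ps <- partial_sequence(ifelse(runif(9) < 0.6, 21L, nat))
  lg <- loss_and_gradients(m, feats, ps, nat)
  expect_gt(lg$loss, 0)
  assign_in <- function(lst, path, idx, v) {
    if (length(path) == 1L) lst[[path[[1L]]]][idx] <- v
    else lst[[path[[1L]]]] <- assign_in(lst[[path[[1L]]]], path[-1L], idx, v)
    lst
  }
  get_in <- function(lst, path) { for (p in path) lst <- lst[[p]]; lst }
  fd <- function(path, idx, eps = 1e-5) {
    v0 <- get_in(m$params, path)[idx]
    mp <- m; mp$params <- assign_in(m$params, path, idx, v0 + eps)
    mm <- m; mm$params <- assign_in(m$params, path, idx, v0 - eps)
    (loss_and_gradients(mp, feats, ps, nat)$loss -
       loss_and_gradients(mm, feats, ps, nat)$loss) / (2 * eps)
  }
  # sample parameters across every group of the model
  paths <- list(list("WP"), list("W_node_in"), list("token_emb"),
                list("node_gvp1", "Wh"), list("node_gvp1", "Wg"),
                list("node_gvp2", "Ws"), list("edge_gvp1", "Wv"),
                list("edge_gvp2", "Ws"),
                list("layers", 1L, "WQ"), list("layers", 1L, "wB"),
                list("layers", 1L, "beta"), list("layers", 1L, "WN"),
                list("layers", 1L, "WE"), list("layers", 1L, "g1"),
                list("layers", 2L, "WK"), list("layers", 2L, "WV"),
                list("layers", 2L, "g2"), list("layers", 2L, "b1"))
  worst <- 0
  for (pa in paths) {
    x <- get_in(m$params, pa)
    for (t in 1:2) {
      idx <- sample(length(x), 1L)
      an <- get_in(lg$grads, pa)[idx]
      rel <- abs(fd(pa, idx) - an) / max(abs(an), abs(fd(pa, idx)), 1e-7)
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("checkpoints round-trip through JSON exactly enough to reproduce output", {
  m <- tiny_model(seed = 12L)
  st <- toy_structure(10L, seed = 12L)
  p1 <- predict(m, st)
  tf <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, tf)
  m2 <- load_checkpoint(tf)
  expect_equal(m2$config$d, m$config$d)
  p2 <- predict(m2, st)
  expect_lt(max(abs(p1$probs - p2$probs)), 1e-12)
  writeLines("{}", tf)
  expect_error(load_checkpoint(tf), "not an ipfrefine checkpoint")
})
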