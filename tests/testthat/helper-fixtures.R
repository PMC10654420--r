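# shared fixtures: tiny models, toy structures, random profiles

tiny_model <- function(d = 12L, L = 2L, k = 6L, seed = 1L,
                       mode = "global_pseudo") {
  ipf_model(d = d, L = L, k = k, attention_mode = mode, d_seq = 6L,
            gvp_vector_channels = 4L, gvp_scalar_hidden = 8L, seed = seed)
}

toy_structure <- function(n = 15L, seed = 1L, noise = 0) {
  generate_backbone(toy_spec(n, coordinate_noise_sd = noise, seed = seed))
}

random_profile <- function(n, concentration = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(stats::rgamma(n * 20L, shape = concentration), n, 20L)
  probability_profile(P / rowSums(P))
}

# random layer parameters at standard initialization scale
random_layer_params <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- function(nr, nc) matrix(runif(nr * nc, -sqrt(6 / (nr + nc)),
                                     sqrt(6 / (nr + nc))), nr, nc)
  list(WQ = u(d, d), WK = u(d, d), WV = u(d, d),
       wB = runif(d, -0.1, 0.1), beta = runif(d, -0.1, 0.1),
       WN = u(2L * d, d), WE = u(3L * d, d),
       g1 = rep(1, d), b1 = rep(0, d), g2 = rep(1, d), b2 = rep(0, d))
}

# random sparse-graph layer inputs on a complete or k-NN graph
random_layer_inputs <- function(n, k, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kk <- min(k, n - 1L)
  st <- toy_structure(max(n, 3L), seed = if (is.null(seed)) 1L else seed)
  st$N <- st$N[seq_len(n), , drop = FALSE]
  st$CA <- st$CA[seq_len(n), , drop = FALSE]
  st$C <- st$C[seq_len(n), , drop = FALSE]
  st$O <- st$O[seq_len(n), , drop = FALSE]
  st$n_residues <- n
  st$residue_numbers <- seq_len(n)
  graph <- build_knn_graph(st, k = kk)
  list(H = matrix(rnorm(n * d, sd = 0.5), n, d),
       E = matrix(rnorm(n * kk * d, sd = 0.5), n * kk, d),
       graph = graph, structure = st)
}
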