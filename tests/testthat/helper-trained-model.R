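# a toy-world refiner trained once and shared across test files (training
# is the expensive step; every consumer reuses the same fitted model)

.trained_cache <- new.env(parent = emptyenv())

toyworld_model <- function() {
  if (is.null(.trained_cache$fit)) {
    ds <- make_toy_dataset(200L, length_range = c(30L, 60L), seed = 101L)
    m <- ipf_model(d = 32L, L = 3L, k = 30L, d_seq = 16L,
                   gvp_vector_channels = 8L, gvp_scalar_hidden = 24L,
                   seed = 1L)
    .trained_cache$fit <- ipf_train(
      ds, m,
      train_config(epochs = 12L, batch_size = 8L, learning_rate = 2e-3,
                   seed = 3L),
      corruption_config(seed = 5L))
    .trained_cache$heldout <- make_toy_dataset(50L,
                                               length_range = c(30L, 60L),
                                               seed = 202L)
  }
  list(fit = .trained_cache$fit, heldout = .trained_cache$heldout)
}

# masked-position recovery of `fit` on held-out structures given a
# visible fraction of native context (0 = entire design, no context)
context_recovery <- function(fit, heldout, visible_frac, eval_seed = 9L,
                             n_structures = length(heldout$structures)) {
  set.seed(eval_seed)
  hits <- 0L; tot <- 0L
  for (i in seq_len(n_structures)) {
    nat <- tokenize(heldout$sequences[i])
    n <- length(nat)
    vis <- if (visible_frac > 0) sample(n, round(visible_frac * n))
           else integer(0)
    tk <- rep(21L, n)
    tk[vis] <- nat[vis]
    prof <- predict(fit, heldout$structures[[i]], partial_sequence(tk))
    pred <- max.col(prof$probs, ties.method = "first")
    mask <- setdiff(seq_len(n), vis)
    hits <- hits + sum(pred[mask] == nat[mask])
    tot <- tot + length(mask)
  }
  hits / tot
}
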