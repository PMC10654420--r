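#' Construct (initialize) a graph attention sequence-design model
#'
#' Creates the full parameter set of the refiner network: two GVP
#' embedding layers for nodes and for edges, a 21-symbol token embedding,
#' `L` graph attention layers (each with query/key/value maps, the edge
#' bias projection `w_B`, the pseudo-edge feature `beta`, node and edge
#' update maps `W_N`, `W_E` and two layer norms), and the output
#' projection `W_P` to the 20 residue types. Weights are scaled-uniform
#' (Glorot) initialized from a recorded seed, so a model is fully
#' reproducible from its architecture config and seed.
#'
#' @param d Feature width.
#' @param L Number of attention layers.
#' @param k Neighbors per residue in the k-NN graph.
#' @param attention_mode One of `"global_pseudo"` (default),
#'   `"global_dense"`, `"local"`.
#' @param d_seq Token embedding width.
#' @param gvp_vector_channels Hidden vector channels in the GVP layers.
#' @param gvp_scalar_hidden Hidden scalar width of the first GVP layer.
#' @param n_rbf,d_min,d_max Radial-basis bank for edge distances.
#' @param w Sequence-offset window half-width.
#' @param chunk_rows Attention rows per streaming chunk at inference.
#' @param seed Initialization seed (recorded in the model).
#' @return An object of class `"ipf_model"`: list with `config`, `params`
#'   and (after training) `history`.
#' @seealso [ipf_train()], [predict.ipf_model()], [save_checkpoint()]
#' @export
ipf_model <- function(d = 128L, L = 3L, k = 30L,
                      attention_mode = c("global_pseudo", "global_dense",
                                         "local"),
                      d_seq = 16L, gvp_vector_channels = 16L,
                      gvp_scalar_hidden = 32L,
                      n_rbf = 16L, d_min = 2.0, d_max = 22.0, w = 32L,
                      chunk_rows = 128L, seed = 1L) {
  attention_mode <- match.arg(attention_mode)
  stopifnot(d >= 4L, L >= 1L, k >= 1L)
  config <- list(d = as.integer(d), L = as.integer(L), k = as.integer(k),
                 attention_mode = attention_mode, d_seq = as.integer(d_seq),
                 gvp_vector_channels = as.integer(gvp_vector_channels),
                 gvp_scalar_hidden = as.integer(gvp_scalar_hidden),
                 n_rbf = as.integer(n_rbf), d_min = d_min, d_max = d_max,
                 w = as.integer(w), chunk_rows = as.integer(chunk_rows),
                 seed = as.integer(seed))
  model <- structure(list(config = config,
                          params = init_params(config),
                          history = NULL),
                     class = "ipf_model")
  model
}

glorot <- function(n_out, n_in) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -s, s), n_out, n_in)
}

init_params <- function(cf) {
  set.seed(cf$seed)
  d <- cf$d
  nv <- cf$gvp_vector_channels
  sh <- cf$gvp_scalar_hidden
  edge_s_in <- 25L * cf$n_rbf + (2L * cf$w + 1L)
  gvp_params <- function(ns_in, nv_in, ns_out, vector_out) {
    p <- list(Wh = glorot(nv, nv_in),
              Ws = glorot(ns_out, ns_in + nv),
              bs = rep(0, ns_out))
    if (vector_out) {
      p$Wv <- glorot(nv, nv)
      p$Wg <- glorot(nv, ns_out)
      p$bg <- rep(0, nv)
    }
    p
  }
  layer_params <- function() list(
    WQ = glorot(d, d), WK = glorot(d, d), WV = glorot(d, d),
    wB = stats::runif(d, -0.1, 0.1), beta = stats::runif(d, -0.1, 0.1),
    WN = glorot(2L * d, d), WE = glorot(3L * d, d),
    g1 = rep(1, d), b1 = rep(0, d), g2 = rep(1, d), b2 = rep(0, d))
  p <- list(
    node_gvp1 = gvp_params(6L, 2L, sh, vector_out = TRUE),
    node_gvp2 = gvp_params(sh, nv, d, vector_out = FALSE),
    edge_gvp1 = gvp_params(edge_s_in, 1L, sh, vector_out = TRUE),
    edge_gvp2 = gvp_params(sh, nv, d, vector_out = FALSE),
    token_emb = matrix(stats::runif(21L * cf$d_seq, -0.1, 0.1), 21L, cf$d_seq),
    W_node_in = glorot(d + cf$d_seq, d),
    b_node_in = rep(0, d),
    layers = replicate(cf$L, layer_params(), simplify = FALSE),
    WP = glorot(d, 20L))
  p
}

#' Featurize a structure for the model
#'
#' Computes the parameter-independent part of the pipeline: the k-NN
#' graph and the raw node and edge features. The result can be cached
#' across training epochs and across partial-sequence inputs.
#'
#' @param structure A [backbone_structure()].
#' @param model An [ipf_model()] (supplies k and the RBF/offset config).
#' @return A list with `graph`, `raw_node`, `raw_edge`.
#' @export
featurize_structure <- function(structure, model) {
  cf <- model$config
  graph <- build_knn_graph(structure, k = cf$k)
  list(graph = graph,
       raw_node = compute_node_features(structure),
       raw_edge = compute_edge_features(structure, graph, n_rbf = cf$n_rbf,
                                        d_min = cf$d_min, d_max = cf$d_max,
                                        w = cf$w))
}

#' Run the network forward
#'
#' Embeds the structure and partial sequence, applies the `L` attention
#' layers in the model's attention mode, and maps the last layer's node
#' features to per-residue distributions over the 20 amino acids in one
#' shot (no autoregression). Deterministic given model and inputs.
#'
#' @param model An [ipf_model()].
#' @param feats A [featurize_structure()] result (or a
#'   [backbone_structure()], which is featurized on the fly).
#' @param partial A [partial_sequence()]; defaults to all-unknown.
#' @param want_cache Keep all intermediates for backpropagation
#'   (training path; disables streaming).
#' @return A [probability_profile()] with `source = "refiner"`; with
#'   `want_cache = TRUE`, a list `(profile, cache)`.
#' @export
model_forward <- function(model, feats, partial = NULL, want_cache = FALSE) {
  stopifnot(inherits(model, "ipf_model"))
  if (inherits(feats, "backbone_structure"))
    feats <- featurize_structure(feats, model)
  n <- nrow(feats$raw_node$dihedral_sincos)
  if (is.null(partial))
    partial <- partial_sequence(rep(TOK_UNKNOWN, n))
  cf <- model$config
  emb <- embed_graph(feats$raw_node, feats$raw_edge, partial, model,
                     want_cache = want_cache)
  H <- emb$H0; E <- emb$E0
  i_index <- emb$i_index; j_index <- emb$j_index
  mode <- cf$attention_mode
  caches <- if (want_cache) vector("list", cf$L) else NULL
  E_full <- NULL
  if (mode == "global_dense") {
    # the ablation variant works on fully connected edge features
    E_full <- dense_edge_features_from_raw(feats, model)
  }
  for (l in seq_len(cf$L)) {
    lp <- model$params$layers[[l]]
    out <- switch(mode,
      global_pseudo = layer_pseudo_forward(H, E, feats$graph$nbr, i_index,
                                           j_index, lp, cf$d,
                                           want_cache = want_cache,
                                           chunk_rows = cf$chunk_rows),
      local = layer_local_forward(H, E, feats$graph$nbr, i_index, j_index,
                                  lp, cf$d),
      global_dense = layer_dense_forward(H, if (l == 1L) E_full else E,
                                         lp, cf$d))
    if (!all(is.finite(out$H)))
      stop("model_forward: non-finite activations in layer ", l)
    H <- out$H; E <- out$E
    if (want_cache) caches[[l]] <- out$cache
  }
  logits <- H %*% model$params$WP
  probs <- softmax_rows(logits)
  profile <- probability_profile(probs, source = "refiner")
  if (!want_cache) return(profile)
  list(profile = profile,
       cache = list(emb = emb, layers = caches, H_L = H, probs = probs,
                    feats = feats, partial = partial))
}

# dense edge features reusing an existing featurization's atom geometry
dense_edge_features_from_raw <- function(feats, model) {
  # rebuild from the structure held implicitly: featurize the complete
  # graph. feats$raw_edge does not retain the structure, so this path
  # requires the caller to have attached it.
  st <- attr(feats, "structure")
  if (is.null(st))
    stop("global_dense forward needs the structure attached to feats ",
         "(use model_forward(model, structure, ...))")
  dense_edge_features(st, model)
}

#' Predict per-residue amino-acid probabilities
#'
#' @param object An [ipf_model()].
#' @param structure A [backbone_structure()].
#' @param partial Optional [partial_sequence()] (defaults to all-unknown).
#' @param ... Unused.
#' @return A [probability_profile()].
#' @export
predict.ipf_model <- function(object, structure, partial = NULL, ...) {
  feats <- featurize_structure(structure, object)
  attr(feats, "structure") <- structure
  model_forward(object, feats, partial)
}

#' @export
print.ipf_model <- function(x, ...) {
  cf <- x$config
  cat(sprintf("<ipf_model> d=%d, L=%d, k=%d, mode=%s, %s parameters\n",
              cf$d, cf$L, cf$k, cf$attention_mode,
              format(n_params(x), big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; best val loss %.4f (epoch %d)\n",
                nrow(x$history), min(x$history$val_loss),
                which.min(x$history$val_loss)))
  invisible(x)
}

#' @export
summary.ipf_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("training history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.ipf_model <- function(object, ...) object$params

#' Plot the training loss curve
#'
#' @param x A trained [ipf_model()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ipf_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = c(1, 2), lty = 1, xlab = "epoch",
                    ylab = "negative log-likelihood", ...)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = 1:2)
  invisible(x)
}

n_params <- function(model) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  cnt(model$params)
}

# --- checkpoint I/O --------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON document (version tag, architecture
#' config including the initialization seed, training history if any, and
#' every parameter tensor with its dimensions), so checkpoints are plain
#' text and portable.
#'
#' @param model An [ipf_model()].
#' @param path Checkpoint path (`.json`).
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the restored [ipf_model()].
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ipf_model"))
  ser <- function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else if (is.numeric(x)) list(dim = length(x), data = as.numeric(x))
    else lapply(x, ser)
  }
  doc <- list(format = "ipfrefine-checkpoint", version = 1L,
              config = model$config,
              history = model$history,
              params = ser(model$params))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(doc$format) || doc$format != "ipfrefine-checkpoint")
    stop("load_checkpoint: not an ipfrefine checkpoint: ", path)
  deser <- function(x) {
    if (is.list(x) && !is.null(x$dim) && !is.null(x$data)) {
      dm <- as.integer(unlist(x$dim))
      dat <- as.numeric(unlist(x$data))
      if (length(dm) == 2L) matrix(dat, dm[1L], dm[2L]) else dat
    } else lapply(x, deser)
  }
  cf <- lapply(doc$config, unlist)
  cf$d_min <- as.numeric(cf$d_min); cf$d_max <- as.numeric(cf$d_max)
  history <- if (is.null(doc$history) || !length(doc$history)) NULL
             else do.call(rbind, lapply(doc$history, as.data.frame))
  structure(list(config = cf, params = deser(doc$params),
                 history = history),
            class = "ipf_model")
}
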