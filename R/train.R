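#' Training configuration
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Examples per Adam step (gradients are averaged).
#' @param learning_rate Adam step size.
#' @param val_frac Fraction of the dataset held out for validation (the
#'   best-validation parameters are returned).
#' @param loss_scope `"all_positions"` (default: the model learns to
#'   reconstruct the whole sequence) or `"masked_only"`.
#' @param seed Seed for shuffling, corruption streams and validation
#'   split.
#' @param verbose Print per-epoch losses.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(epochs = 10L, batch_size = 8L, learning_rate = 1e-3,
                         val_frac = 0.1, loss_scope = c("all_positions",
                                                        "masked_only"),
                         seed = 1L, verbose = FALSE) {
  loss_scope <- match.arg(loss_scope)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            val_frac >= 0, val_frac < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, val_frac = val_frac,
                 loss_scope = loss_scope, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# elementwise recursion over congruent parameter structures
param_walk <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1L]])) {
    out <- lapply(seq_along(args[[1L]]), function(i)
      do.call(param_walk, c(list(f), lapply(args, `[[`, i))))
    names(out) <- names(args[[1L]])
    out
  } else do.call(f, args)
}

# grads may order leaves differently; align to params by names recursively
align_like <- function(template, x) {
  if (!is.list(template)) return(x)
  nm <- names(template)
  if (is.null(nm)) return(lapply(seq_along(template), function(i)
    align_like(template[[i]], x[[i]])))
  lapply(stats::setNames(nm, nm), function(k) align_like(template[[k]], x[[k]]))
}

adam_init <- function(params) {
  list(m = param_walk(function(x) x * 0, params),
       v = param_walk(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_walk(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- param_walk(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- param_walk(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

#' Train the refiner by masked-sequence reconstruction
#'
#' Each epoch draws a fresh corruption of every training sequence (mask
#' 70%, replace 3% by default), runs the network on the corrupted partial
#' sequence, and minimizes the negative log-likelihood of the native
#' sequence with Adam. Structure featurization is computed once and
#' reused across epochs. The returned model carries the parameters of the
#' best validation epoch and the per-epoch loss curve. Fully reproducible
#' given the config seeds.
#'
#' @param dataset A list with `structures` (list of
#'   [backbone_structure()] with `$native_sequence` set) and optionally
#'   `sequences`; [make_toy_dataset()] output works directly.
#' @param model An [ipf_model()] to start from (its architecture config
#'   is used); default is `ipf_model()`.
#' @param train_cfg A [train_config()].
#' @param corrupt_cfg A [corruption_config()].
#' @return The trained [ipf_model()] with `history` (data.frame: epoch,
#'   train_loss, val_loss, val_recovery).
#' @export
ipf_train <- function(dataset, model = NULL, train_cfg = train_config(),
                      corrupt_cfg = corruption_config()) {
  if (is.null(model)) model <- ipf_model()
  stopifnot(inherits(model, "ipf_model"), inherits(train_cfg, "train_config"),
            inherits(corrupt_cfg, "corruption_config"))
  structures <- dataset$structures
  if (is.null(structures)) structures <- dataset
  n_ex <- length(structures)
  if (n_ex < 1L) stop("ipf_train: empty dataset")
  natives <- lapply(structures, function(st) {
    if (is.null(st$native_sequence))
      stop("ipf_train: structure without native_sequence")
    tokenize(st$native_sequence)
  })

  feats <- lapply(structures, featurize_structure, model = model)

  set.seed(train_cfg$seed)
  n_val <- max(if (train_cfg$val_frac > 0) 1L else 0L,
               round(train_cfg$val_frac * n_ex))
  n_val <- min(n_val, n_ex - 1L)
  val_idx <- if (n_val > 0L) sample.int(n_ex, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n_ex), val_idx)

  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_recovery = numeric(0))
  best <- list(loss = Inf, params = model$params)
  # independent corruption stream so validation evaluation does not
  # perturb training randomness
  corrupt_seed <- corrupt_cfg$seed

  for (epoch in seq_len(train_cfg$epochs)) {
    set.seed(corrupt_seed + epoch * 131L)
    order_ <- sample(tr_idx)
    batches <- split(order_, ceiling(seq_along(order_) / train_cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      gsum <- NULL
      bloss <- 0
      for (ix in b) {
        nat <- natives[[ix]]
        ps <- corrupt_sequence(nat, corrupt_cfg)
        scope <- if (train_cfg$loss_scope == "masked_only") !ps$visible
                 else NULL
        lg <- loss_and_gradients(model, feats[[ix]], ps, nat, scope)
        if (!is.finite(lg$loss))
          stop("ipf_train: non-finite loss at epoch ", epoch,
               ", example ", ix, " - training diverged")
        bloss <- bloss + lg$loss
        gsum <- if (is.null(gsum)) lg$grads
                else param_walk(`+`, gsum, align_like(gsum, lg$grads))
      }
      gsum <- param_walk(function(x) x / length(b), gsum)
      upd <- adam_step(model$params, align_like(model$params, gsum), state,
                       train_cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bloss
    }
    ep_loss <- ep_loss / length(order_)

    # validation: fixed per-epoch corruption, loss + recovery on masked
    val <- c(loss = NA_real_, rec = NA_real_)
    if (length(val_idx)) {
      set.seed(1e6 + corrupt_seed)
      vl <- 0; hit <- 0; tot <- 0
      for (ix in val_idx) {
        nat <- natives[[ix]]
        ps <- corrupt_sequence(nat, corrupt_cfg)
        prof <- model_forward(model, feats[[ix]], ps)
        vl <- vl + nll_loss(prof, nat)
        pred <- max.col(prof$probs, ties.method = "first")
        hit <- hit + sum(pred[!ps$visible] == nat[!ps$visible])
        tot <- tot + sum(!ps$visible)
      }
      val <- c(loss = vl / length(val_idx), rec = hit / tot)
      if (val[["loss"]] < best$loss)
        best <- list(loss = val[["loss"]], params = model$params)
    } else if (ep_loss < best$loss) {
      best <- list(loss = ep_loss, params = model$params)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss,
                                val_loss = val[["loss"]],
                                val_recovery = val[["rec"]]))
    if (train_cfg$verbose)
      message(sprintf("epoch %d  train %.4f  val %.4f  val_rec %.3f",
                      epoch, ep_loss, val[["loss"]], val[["rec"]]))
  }
  model$params <- best$params
  model$history <- history
  model
}

#' Write a training history as CSV
#'
#' @param model A trained [ipf_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_history <- function(model, path) {
  if (is.null(model$history)) stop("model has no training history")
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
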