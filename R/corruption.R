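#' Masked-sequence corruption
#'
#' The training scheme masks a fixed fraction of residues (default 70%)
#' and, among the remaining visible residues, replaces a small fraction
#' of the total length (default 3%) with a random different amino acid.
#' Counts are exact: `round(mask_frac * N)` masked, `round(replace_frac
#' * N)` replaced; the visibility mask reflects masking only, so replaced
#' positions look like trustworthy context (that is the point: the model
#' must learn to overrule noisy context).
#'
#' @param mask_frac Fraction of residues masked, in `[0, 1]`.
#' @param replace_frac Fraction of residues (of total length) replaced
#'   among the visible ones.
#' @param seed Integer seed (used by [ipf_train()] to derive per-epoch
#'   corruption streams).
#' @return An object of class `"corruption_config"`.
#' @export
corruption_config <- function(mask_frac = 0.70, replace_frac = 0.03,
                              seed = 1L) {
  stopifnot(mask_frac >= 0, mask_frac <= 1, replace_frac >= 0,
            replace_frac <= 1)
  if (mask_frac + replace_frac > 1)
    stop("corruption_config: mask_frac + replace_frac must be <= 1")
  structure(list(mask_frac = mask_frac, replace_frac = replace_frac,
                 seed = as.integer(seed)),
            class = "corruption_config")
}

#' Corrupt a native sequence for training
#'
#' Masks exactly `round(mask_frac * N)` positions chosen uniformly
#' without replacement and replaces exactly `round(replace_frac * N)` of
#' the visible positions with an amino acid drawn uniformly from the 19
#' types different from the native one. Consumes the current RNG stream.
#'
#' @param native Native tokens (integer `1..20`) or a sequence string
#'   with no unknowns.
#' @param config A [corruption_config()].
#' @return A [partial_sequence()]; replaced positions remain visible.
#' @export
corrupt_sequence <- function(native, config) {
  if (is.character(native)) native <- tokenize(native)
  if (any(native == TOK_UNKNOWN))
    stop("corrupt_sequence: native sequence contains unknown tokens")
  n <- length(native)
  n_mask <- round(config$mask_frac * n)
  n_repl <- round(config$replace_frac * n)
  if (n_repl > n - n_mask)
    stop("corrupt_sequence: replacement count ", n_repl,
         " exceeds visible count ", n - n_mask)
  tokens <- native
  masked <- if (n_mask > 0L) sample.int(n, n_mask) else integer(0)
  tokens[masked] <- TOK_UNKNOWN
  visible <- setdiff(seq_len(n), masked)
  if (n_repl > 0L) {
    repl <- if (length(visible) == 1L) visible
            else sample(visible, n_repl)
    tokens[repl] <- vapply(native[repl], function(a)
      sample(setdiff(1:20, a), 1L), integer(1L))
  }
  partial_sequence(tokens)
}

#' Negative log-likelihood of native residues under a profile
#'
#' Mean over the in-scope positions of `-log p[i, native_i]`, with the
#' log clamped at 1e-12.
#'
#' @param profile A [probability_profile()].
#' @param native Native tokens or sequence string.
#' @param scope Logical vector of in-scope positions; default all.
#' @return Nonnegative scalar.
#' @export
nll_loss <- function(profile, native, scope = NULL) {
  stopifnot(inherits(profile, "probability_profile"))
  if (is.character(native)) native <- tokenize(native)
  n <- nrow(profile$probs)
  stopifnot(length(native) == n, all(native <= 20L))
  if (is.null(scope)) scope <- rep(TRUE, n)
  if (!any(scope)) stop("nll_loss: empty scope")
  p <- profile$probs[cbind(seq_len(n), native)]
  -mean(log(pmax(p[scope], 1e-12)))
}
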