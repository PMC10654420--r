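#' Sequence-design evaluation metrics
#'
#' Recovery (identity fraction), nssr (native sequence similarity
#' recovery: fraction of designed/native pairs with BLOSUM62 score
#' strictly greater than 0), perplexity (exp of the mean negative
#' log-likelihood of the native residues) and the 20 x 20 confusion
#' matrix.
#'
#' @name metrics
NULL

.blosum_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' The standard NCBI BLOSUM62 table, reindexed to the canonical
#' alphabetical amino-acid order and shipped as a plain-text data file.
#'
#' @return 20 x 20 integer matrix with dimnames [AA_ALPHABET].
#' @export
blosum62 <- function() {
  if (is.null(.blosum_env$mat)) {
    path <- system.file("extdata", "blosum62.tsv", package = "ipfrefine")
    if (path == "") path <- file.path("inst", "extdata", "blosum62.tsv")
    tab <- utils::read.table(path, header = TRUE, row.names = 1L,
                             check.names = FALSE)
    m <- as.matrix(tab)
    storage.mode(m) <- "integer"
    m <- m[AA_ALPHABET, AA_ALPHABET]
    if (!isTRUE(all.equal(m, t(m)))) stop("blosum62: table not symmetric")
    if (any(diag(m) <= 0)) stop("blosum62: non-positive diagonal")
    .blosum_env$mat <- m
  }
  .blosum_env$mat
}

check_pair <- function(designed, native, scope) {
  if (is.character(designed)) designed <- tokenize(designed)
  if (is.character(native)) native <- tokenize(native)
  if (length(designed) != length(native))
    stop("sequence length mismatch: ", length(designed), " vs ",
         length(native))
  if (is.null(scope)) scope <- rep(TRUE, length(native))
  if (!any(scope)) stop("empty scope")
  list(d = designed, n = native, s = scope)
}

#' Sequence recovery
#'
#' Fraction of in-scope positions where designed and native residues are
#' identical.
#'
#' @param designed,native Sequences (strings or integer tokens) of equal
#'   length.
#' @param scope Logical vector of scored positions; default all.
#' @return Fraction in `[0, 1]`.
#' @export
recovery <- function(designed, native, scope = NULL) {
  x <- check_pair(designed, native, scope)
  mean(x$d[x$s] == x$n[x$s])
}

#' Native sequence similarity recovery (nssr)
#'
#' Fraction of in-scope positions whose designed/native pair has a
#' BLOSUM62 score strictly greater than zero. Identical pairs always
#' count (the diagonal is positive), so `recovery <= nssr`.
#'
#' @inheritParams recovery
#' @param matrix Substitution matrix; default [blosum62()].
#' @return Fraction in `[0, 1]`.
#' @export
nssr <- function(designed, native, scope = NULL, matrix = blosum62()) {
  x <- check_pair(designed, native, scope)
  if (any(x$d[x$s] > 20L) || any(x$n[x$s] > 20L))
    stop("nssr: unknown tokens in scored positions")
  mean(matrix[cbind(x$d[x$s], x$n[x$s])] > 0L)
}

#' Perplexity of a profile against the native sequence
#'
#' `exp(mean(-log p[i, native_i]))` over the in-scope positions (natural
#' log); 1 for a perfectly confident correct predictor, 20 for the
#' uniform predictor.
#'
#' @param profile A [probability_profile()].
#' @param native Native sequence (string or tokens).
#' @param scope Logical vector; default all.
#' @return Scalar `>= 1`.
#' @export
perplexity <- function(profile, native, scope = NULL) {
  exp(nll_loss(profile, native, scope))
}

#' Confusion matrix of designed vs native residues
#'
#' Entry `(a, b)` counts positions with native type `a` designed as type
#' `b`; row sums give the native composition.
#'
#' @inheritParams recovery
#' @return 20 x 20 integer matrix with dimnames [AA_ALPHABET].
#' @export
confusion_matrix <- function(designed, native, scope = NULL) {
  x <- check_pair(designed, native, scope)
  m <- matrix(0L, 20L, 20L, dimnames = list(native = AA_ALPHABET,
                                            designed = AA_ALPHABET))
  tb <- table(factor(x$n[x$s], levels = 1:20),
              factor(x$d[x$s], levels = 1:20))
  m[] <- as.integer(tb)
  m
}

#' Bootstrap percentile confidence interval of the median
#'
#' The reporting convention for benchmark medians: percentile CI of the
#' median from seeded bootstrap resampling (default 10,000 resamples).
#'
#' @param x Numeric sample.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Seed for the resampling.
#' @return List with `median`, `lower`, `upper`, `conf`, `n_boot`.
#' @export
bootstrap_median_ci <- function(x, n_boot = 10000L, conf = 0.95, seed = 1L) {
  stopifnot(length(x) >= 2L, n_boot >= 100L)
  set.seed(seed)
  meds <- vapply(seq_len(n_boot),
                 function(i) stats::median(sample(x, replace = TRUE)),
                 numeric(1L))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE)
  list(median = stats::median(x), lower = qs[1L], upper = qs[2L],
       conf = conf, n_boot = n_boot)
}
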