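#' Entropy-based refinement of base-model predictions
#'
#' The refinement strategy treats an existing sequence-design model (the
#' "base model") as a noisy oracle: its per-residue distributions are
#' ranked by Shannon entropy, only the most confident fraction is kept as
#' visible context, the refiner re-designs the rest in one shot, and the
#' refiner's and base's distributions are fused per residue with weights
#' `exp(-entropy)` normalized over the two sources.
#'
#' @name entropy_refine
NULL

#' Shannon entropy of a categorical distribution
#'
#' `-sum(p * log(p))` in nats with `0 * log(0) := 0`; for 20 categories
#' the range is `[0, log(20)]`.
#'
#' @param p Nonnegative vector summing to 1 (within 1e-6).
#' @return Scalar entropy in nats.
#' @export
entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("entropy: not a probability distribution")
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Keep-fraction defaults per base model
#'
#' The fraction of lowest-entropy base predictions retained as context is
#' calibrated per base model (better base models earn a larger
#' fraction): GVP-GNN 0.10, ProteinMPNN 0.10, ProteinMPNN-C 0.15,
#' ESM-IF1 0.35; unknown models default to 0.15.
#'
#' @param base_model_name One of `"gvp"`, `"mpnn"`, `"mpnn-c"`,
#'   `"esm-if1"` (case-insensitive, common aliases accepted), or any
#'   other string for the default.
#' @return Keep fraction in `[0, 1]`.
#' @export
keep_fraction_for_base <- function(base_model_name) {
  key <- tolower(base_model_name)
  tab <- c("gvp" = 0.10, "gvp-gnn" = 0.10,
           "mpnn" = 0.10, "proteinmpnn" = 0.10,
           "mpnn-c" = 0.15, "proteinmpnn-c" = 0.15,
           "esm-if1" = 0.35, "esm_if1" = 0.35, "esmif1" = 0.35)
  if (key %in% names(tab)) unname(tab[key]) else 0.15
}

#' Refinement configuration
#'
#' @param keep_fraction Fraction of lowest-entropy base predictions
#'   retained as visible context (overrides the base-model table).
#' @param base_model_name Optional base model name used to look up the
#'   default keep fraction; see [keep_fraction_for_base()].
#' @param fuse Fuse refiner and base distributions per residue
#'   (default `TRUE`); with `FALSE` the refiner's distribution alone is
#'   used.
#' @return An object of class `"refine_config"`.
#' @export
refine_config <- function(keep_fraction = NULL, base_model_name = NULL,
                          fuse = TRUE) {
  if (is.null(keep_fraction)) {
    keep_fraction <- if (is.null(base_model_name)) 0.15
                     else keep_fraction_for_base(base_model_name)
  }
  stopifnot(keep_fraction >= 0, keep_fraction <= 1)
  structure(list(keep_fraction = keep_fraction,
                 base_model_name = base_model_name, fuse = isTRUE(fuse)),
            class = "refine_config")
}

#' Select the base model's most confident predictions
#'
#' The `floor(keep_fraction * N)` positions with the smallest entropy
#' become visible with the base argmax as token; everything else is
#' masked. Entropy ties break toward the lower residue index, argmax ties
#' toward the earlier letter of the canonical alphabet.
#'
#' @param base A [probability_profile()] from the base model.
#' @param keep_fraction Fraction in `[0, 1]`.
#' @return A [partial_sequence()].
#' @export
select_low_entropy <- function(base, keep_fraction) {
  stopifnot(inherits(base, "probability_profile"),
            keep_fraction >= 0, keep_fraction <= 1)
  n <- nrow(base$probs)
  n_keep <- floor(keep_fraction * n)
  tokens <- rep(TOK_UNKNOWN, n)
  if (n_keep > 0L) {
    keep <- order(base$entropy, seq_len(n))[seq_len(n_keep)]
    tokens[keep] <- max.col(base$probs[keep, , drop = FALSE],
                            ties.method = "first")
  }
  partial_sequence(tokens)
}

#' Entropy-weighted fusion of two distributions
#'
#' Convex combination with weights proportional to `exp(-entropy)`:
#' the more confident source dominates. With equal entropies this is the
#' exact average; a zero-entropy source against a uniform one gets weight
#' `20/21`.
#'
#' @param p_refiner,p_base Probability rows (length 20).
#' @param en_refiner,en_base Their entropies (computed if `NULL`).
#' @return Fused probability row.
#' @export
fuse <- function(p_refiner, p_base, en_refiner = NULL, en_base = NULL) {
  if (is.null(en_refiner)) en_refiner <- entropy(p_refiner)
  if (is.null(en_base)) en_base <- entropy(p_base)
  w <- exp(-en_refiner) / (exp(-en_refiner) + exp(-en_base))
  w * p_refiner + (1 - w) * p_base
}

# vectorized fusion of two profiles
fuse_profiles <- function(refiner, base) {
  w <- exp(-refiner$entropy) / (exp(-refiner$entropy) + exp(-base$entropy))
  probability_profile(refiner$probs * w + base$probs * (1 - w),
                      source = "fused")
}

#' Entire sequence design with a base model
#'
#' The full refinement pipeline: select the base model's lowest-entropy
#' predictions as visible context ([select_low_entropy()]), run the
#' refiner once on the partial sequence, fuse the two distributions per
#' residue (unless `cfg$fuse` is `FALSE`), and return the argmax
#' sequence.
#'
#' @param structure A [backbone_structure()].
#' @param base A [probability_profile()] of matching length.
#' @param model A trained [ipf_model()].
#' @param cfg A [refine_config()].
#' @return List with `sequence` (string), `profile` (the fused
#'   [probability_profile()]) and `partial` (the selected context).
#' @export
design_entire <- function(structure, base, model, cfg = refine_config()) {
  stopifnot(inherits(base, "probability_profile"))
  if (nrow(base$probs) != structure$n_residues)
    stop("design_entire: base profile length != structure length")
  partial <- select_low_entropy(base, cfg$keep_fraction)
  refined <- predict(model, structure, partial)
  profile <- if (cfg$fuse) fuse_profiles(refined, base) else refined
  seq_ <- untokenize(max.col(profile$probs, ties.method = "first"))
  list(sequence = seq_, profile = profile, partial = partial)
}

#' Partial sequence design
#'
#' Fills in the unknown positions of a given partial sequence in one
#' forward pass. Positions visible in the input are authoritative and
#' copied to the output verbatim; no base model and no fusion are
#' involved.
#'
#' @param structure A [backbone_structure()].
#' @param given A [partial_sequence()] with at least one unknown.
#' @param model A trained [ipf_model()].
#' @return List with `sequence` (string) and `profile` (the refiner's
#'   [probability_profile()]).
#' @export
design_partial <- function(structure, given, model) {
  given <- validate_partial_sequence(given)
  if (length(given$tokens) != structure$n_residues)
    stop("design_partial: partial sequence length != structure length")
  if (all(given$visible))
    stop("design_partial: nothing to design (no unknown positions)")
  profile <- predict(model, structure, given)
  tokens <- max.col(profile$probs, ties.method = "first")
  tokens[given$visible] <- given$tokens[given$visible]
  list(sequence = untokenize(tokens), profile = profile)
}

#' Mutation-scan configuration
#'
#' @param target_aa Single-letter target amino acid (e.g. `"R"` when
#'   scanning for stabilizing arginines on a positively charged surface).
#' @param candidate_sites Integer residue indices (1-based) to examine,
#'   e.g. user-supplied surface residues.
#' @param binding_center 3-vector (A): center of the (externally
#'   predicted) binding site.
#' @param combine_weight Weight in `[0, 1]` mixing the probability
#'   percentile rank (descending) and the distance percentile rank
#'   (ascending) into the quality score.
#' @param top_n Number of sites flagged as recommended.
#' @return An object of class `"mutation_scan_config"`.
#' @export
mutation_scan_config <- function(target_aa = "R", candidate_sites,
                                 binding_center, combine_weight = 0.5,
                                 top_n = 20L) {
  stopifnot(length(candidate_sites) >= 1L, combine_weight >= 0,
            combine_weight <= 1, length(binding_center) == 3L)
  target_aa <- toupper(target_aa)
  if (!target_aa %in% AA_ALPHABET)
    stop("mutation_scan_config: unknown target amino acid ", target_aa)
  structure(list(target_aa = target_aa,
                 candidate_sites = as.integer(candidate_sites),
                 binding_center = as.numeric(binding_center),
                 combine_weight = combine_weight, top_n = as.integer(top_n)),
            class = "mutation_scan_config")
}

# percentile rank in [1/n, 1]; direction = "desc" gives 1 to the largest
rank_pct <- function(x, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  r <- if (direction == "desc") rank(-x, ties.method = "average")
       else rank(x, ties.method = "average")
  (length(x) + 1 - r) / length(x)
}

#' Single-point mutation scanning
#'
#' For each candidate site, the site is masked in the native sequence and
#' the refiner predicts its identity from the full remaining context; the
#' predicted probability of the target amino acid measures how compatible
#' the mutation is with the structural environment. This is combined with
#' the C-alpha distance to the binding-site center (closer is better)
#' into a quality score:
#' `combine_weight * rank_pct(prob, desc) + (1 - combine_weight) *
#' rank_pct(dist, asc)`, both ranks expressed as percentiles over the
#' candidate set. Sites whose native residue already equals the target
#' are skipped with a warning.
#'
#' @param structure A [backbone_structure()].
#' @param native Native sequence (string, no unknowns).
#' @param model A trained [ipf_model()].
#' @param cfg A [mutation_scan_config()].
#' @return A data.frame sorted by quality score (descending): rank,
#'   site (1-based index), author_resnum, native, target, prob_target,
#'   dist_A, score, recommended (top `top_n` flag).
#' @export
scan_mutations <- function(structure, native, model, cfg) {
  stopifnot(inherits(cfg, "mutation_scan_config"))
  nat <- tokenize(native)
  if (any(nat == TOK_UNKNOWN)) stop("scan_mutations: native has unknowns")
  n <- structure$n_residues
  if (length(nat) != n) stop("scan_mutations: sequence length mismatch")
  sites <- cfg$candidate_sites
  if (any(sites < 1L | sites > n))
    stop("scan_mutations: candidate site out of range")
  target_tok <- match(cfg$target_aa, AA_ALPHABET)
  already <- nat[sites] == target_tok
  if (any(already)) {
    warning("scan_mutations: skipping site(s) already ", cfg$target_aa, ": ",
            paste(sites[already], collapse = ", "))
    sites <- sites[!already]
  }
  if (!length(sites)) stop("scan_mutations: no candidate sites left")
  feats <- featurize_structure(structure, model)
  prob_target <- vapply(sites, function(s) {
    tk <- nat
    tk[s] <- TOK_UNKNOWN
    prof <- model_forward(model, feats, partial_sequence(tk))
    prof$probs[s, target_tok]
  }, numeric(1L))
  dist_A <- sqrt(colSums((t(structure$CA[sites, , drop = FALSE]) -
                            cfg$binding_center)^2))
  score <- cfg$combine_weight * rank_pct(prob_target, "desc") +
    (1 - cfg$combine_weight) * rank_pct(dist_A, "asc")
  ord <- order(-score, sites)
  out <- data.frame(rank = seq_along(sites),
                    site = sites[ord],
                    author_resnum = structure$residue_numbers[sites[ord]],
                    native = AA_ALPHABET[nat[sites[ord]]],
                    target = cfg$target_aa,
                    prob_target = prob_target[ord],
                    dist_A = dist_A[ord],
                    score = score[ord])
  out$recommended <- out$rank <= cfg$top_n
  out
}
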