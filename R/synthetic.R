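#' Synthetic toy backbones and simulated base-model profiles
#'
#' The generator builds ideal-geometry backbones from internal coordinates
#' (standard bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329 A, ideal bond
#' angles, omega fixed at 180 degrees), couples a sequence to the geometry
#' through a deterministic seeded lookup rule, and simulates base-model
#' probability profiles with a controllable confidence-correctness
#' coupling. Everything is reproducible from seeds, so the whole design
#' pipeline can be trained and tested without any external dataset.
#'
#' @name synthetic_data
NULL

# ideal backbone internal coordinates (A, degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
ANG_N_CA_C <- 111.0 * pi / 180
ANG_CA_C_N <- 116.2 * pi / 180
ANG_C_N_CA <- 121.7 * pi / 180
ANG_CA_C_O <- 120.5 * pi / 180

MOTIF_TORSIONS <- list(
  helix  = c(phi = -57,  psi = -47),
  strand = c(phi = -120, psi = 120)
)

#' Specification of a toy backbone
#'
#' @param n_residues Chain length.
#' @param motif_plan List of `(motif, length)` pairs, e.g.
#'   `list(c("helix", "12"), c("coil", "5"))`, or a data.frame with columns
#'   `motif` and `length`. Motifs are `"helix"` (phi=-57, psi=-47),
#'   `"strand"` (phi=-120, psi=+120) and `"coil"` (torsions sampled from a
#'   broad distribution). Lengths must sum to `n_residues`. By default a
#'   random plan of helix/strand/coil segments is drawn.
#' @param coordinate_noise_sd Isotropic Gaussian noise added to every atom
#'   position (A); 0 gives exact ideal geometry.
#' @param seed Integer seed controlling the plan, coil torsions and noise.
#' @return An object of class `"toy_spec"`.
#' @export
toy_spec <- function(n_residues, motif_plan = NULL, coordinate_noise_sd = 0,
                     seed = 1L) {
  stopifnot(n_residues >= 2L, coordinate_noise_sd >= 0)
  if (!is.null(motif_plan)) {
    motif_plan <- as.data.frame(do.call(rbind, lapply(motif_plan, function(m)
      data.frame(motif = as.character(m[[1L]]),
                 length = as.integer(m[[2L]])))))
    if (sum(motif_plan$length) != n_residues)
      stop("toy_spec: motif lengths must sum to n_residues")
    if (!all(motif_plan$motif %in% c("helix", "strand", "coil")))
      stop("toy_spec: unknown motif")
  }
  structure(list(n_residues = as.integer(n_residues), motif_plan = motif_plan,
                 coordinate_noise_sd = coordinate_noise_sd,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

random_motif_plan <- function(n) {
  plan <- list()
  left <- n
  while (left > 0L) {
    motif <- sample(c("helix", "strand", "coil"), 1L)
    len <- min(left, sample(4:12, 1L))
    plan[[length(plan) + 1L]] <- data.frame(motif = motif, length = len)
    left <- left - len
  }
  do.call(rbind, plan)
}

#' Generate an ideal-geometry toy backbone
#'
#' Builds the chain atom by atom with the NeRF construction from the
#' spec's target torsions; carbonyl O is placed in the C(i) plane opposite
#' N(i+1). The returned structure records the generator's ground-truth
#' phi/psi in `attr(, "target_torsions")` so featurization can be tested
#' against it exactly at zero noise.
#'
#' @param spec A [toy_spec()].
#' @return A [backbone_structure()] (without a native sequence; see
#'   [couple_sequence()]).
#' @export
generate_backbone <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_residues
  set.seed(spec$seed)
  plan <- spec$motif_plan
  if (is.null(plan)) plan <- random_motif_plan(n)
  motif <- rep(plan$motif, plan$length)

  phi <- numeric(n); psi <- numeric(n)
  for (i in seq_len(n)) {
    if (motif[i] == "coil") {
      phi[i] <- stats::runif(1L, -150, -50) * pi / 180
      psi[i] <- stats::runif(1L, -80, 160) * pi / 180
    } else {
      t <- MOTIF_TORSIONS[[motif[i]]]
      phi[i] <- t[["phi"]] * pi / 180
      psi[i] <- t[["psi"]] * pi / 180
    }
  }
  omega <- pi  # trans peptide bonds throughout

  Nm <- CAm <- Cm <- Om <- matrix(NA_real_, n, 3L)
  # seed the first residue in a fixed frame
  Nm[1L, ]  <- c(0, 0, 0)
  CAm[1L, ] <- c(BOND_N_CA, 0, 0)
  Cm[1L, ]  <- CAm[1L, ] + BOND_CA_C *
    c(-cos(ANG_N_CA_C), sin(ANG_N_CA_C), 0)
  for (i in seq_len(n - 1L)) {
    # N(i+1): torsion psi_i about N(i)-CA(i)-C(i)
    Nm[i + 1L, ] <- place_atom(Nm[i, ], CAm[i, ], Cm[i, ],
                               BOND_C_N, ANG_CA_C_N, psi[i])
    # CA(i+1): torsion omega about CA(i)-C(i)-N(i+1)
    CAm[i + 1L, ] <- place_atom(CAm[i, ], Cm[i, ], Nm[i + 1L, ],
                                BOND_N_CA, ANG_C_N_CA, omega)
    # C(i+1): torsion phi_{i+1} about C(i)-N(i+1)-CA(i+1)
    Cm[i + 1L, ] <- place_atom(Cm[i, ], Nm[i + 1L, ], CAm[i + 1L, ],
                               BOND_CA_C, ANG_N_CA_C, phi[i + 1L])
  }
  # carbonyl O: bisector of CA->C and N(i+1)->C directions, in plane
  for (i in seq_len(n)) {
    if (i < n) {
      u <- Cm[i, ] - CAm[i, ]; u <- u / vec_norm(u)
      v <- Cm[i, ] - Nm[i + 1L, ]; v <- v / vec_norm(v)
      w <- u + v; w <- w / vec_norm(w)
      Om[i, ] <- Cm[i, ] + BOND_C_O * w
    } else {
      # no next N: place at fixed torsion relative to N-CA-C
      Om[i, ] <- place_atom(Nm[i, ], CAm[i, ], Cm[i, ],
                            BOND_C_O, ANG_CA_C_O, psi[i] + pi)
    }
  }
  if (spec$coordinate_noise_sd > 0) {
    jit <- function(X) X + matrix(stats::rnorm(length(X),
                                               sd = spec$coordinate_noise_sd),
                                  nrow(X), 3L)
    Nm <- jit(Nm); CAm <- jit(CAm); Cm <- jit(Cm); Om <- jit(Om)
  }
  st <- backbone_structure(chain_id = "A", N = Nm, CA = CAm, C = Cm, O = Om,
                           residue_numbers = seq_len(n))
  attr(st, "target_torsions") <- list(phi = phi, psi = psi, omega = rep(pi, n))
  attr(st, "motif") <- motif
  st
}

# deterministic integer hash of a key string mixed with a seed
rule_hash <- function(key, seed) {
  codes <- utf8ToInt(key)
  h <- (as.numeric(seed) %% 1e6) + 1
  for (cd in codes) h <- (h * 131 + cd) %% 1048573
  as.integer(h)
}

# local descriptors driving the sequence rule: discretized phi/psi bin,
# coarse contact-count bin (CA pairs within 8 A), terminal flag
couple_descriptors <- function(structure) {
  n <- structure$n_residues
  feats <- compute_node_features(structure)
  phi <- atan2(feats$dihedral_sincos[, 1L], feats$dihedral_sincos[, 2L])
  psi <- atan2(feats$dihedral_sincos[, 3L], feats$dihedral_sincos[, 4L])
  D <- as.matrix(stats::dist(structure$CA))
  contacts <- rowSums(D < 8) - 1L
  data.frame(
    phi_bin = pmin(pmax(floor(phi / (40 * pi / 180)), -5L), 4L),
    psi_bin = pmin(pmax(floor(psi / (40 * pi / 180)), -5L), 4L),
    contact_bin = as.integer(contacts >= 8L),
    terminal = as.integer(seq_len(n) == 1L | seq_len(n) == n)
  )
}

#' Couple a sequence to a backbone's geometry
#'
#' A deterministic map from local structural descriptors (40-degree phi/psi
#' bins, a coarse contact-count bin, a terminal flag) through a seeded hash
#' lookup to one of the 20 amino acids. Because the map is a function of
#' the descriptors only (given `rule_seed` and `variant`), a classifier
#' that recovers the descriptors achieves 100% sequence recovery at zero
#' coordinate noise; this bounds and grounds what the network can learn on
#' toy data.
#'
#' A nonzero `variant` remaps the amino acids of a fixed, seeded subset of
#' descriptor keys (fraction `variable_frac`). A dataset mixing a few
#' variants emulates the many-to-many nature of real local-environment to
#' amino-acid mappings: the variant of a held-out protein cannot be read
#' off its structure, but visible residues reveal it, so partial sequence
#' input carries genuine information beyond the backbone - the property
#' the refiner is designed to exploit.
#'
#' @param structure A [backbone_structure()].
#' @param rule_seed Integer seed of the base lookup rule (the "genetic
#'   code" of the toy world; keep it fixed across a dataset).
#' @param variant Nonnegative integer; 0 (default) is the base table.
#' @param variable_frac Fraction of descriptor keys whose amino acid is
#'   variant-specific.
#' @return Character string: the native sequence (length N).
#' @export
couple_sequence <- function(structure, rule_seed = 42L, variant = 0L,
                            variable_frac = 0.3) {
  d <- couple_descriptors(structure)
  keys <- sprintf("%d|%d|%d|%d", d$phi_bin, d$psi_bin, d$contact_bin, d$terminal)
  aa_idx <- vapply(keys, function(k) {
    variable <- rule_hash(paste0(k, "|var"), rule_seed) %% 1000L <
      1000 * variable_frac
    if (variant > 0L && variable)
      rule_hash(k, rule_seed + 7919L * as.integer(variant)) %% 20L + 1L
    else
      rule_hash(k, rule_seed) %% 20L + 1L
  }, integer(1L), USE.NAMES = FALSE)
  paste(AA_ALPHABET[aa_idx], collapse = "")
}

#' Specification of a simulated base model
#'
#' @param accuracy Probability that a position's argmax equals the native
#'   residue (in (0, 1]).
#' @param coupling Probability that a position's confidence reflects its
#'   correctness: with probability `coupling`, correct positions receive a
#'   sharp (low-entropy) row and incorrect positions a flat one; otherwise
#'   sharpness is assigned by a fair coin independently of correctness.
#'   `coupling = 0` makes entropy uninformative; values near 1 emulate the
#'   well-calibrated confidence structure real base models exhibit.
#' @param concentration Positive logit scale of sharp rows; the argmax of a
#'   sharp row carries probability `1 / (1 + 19 * exp(-concentration))`.
#' @param seed Integer seed.
#' @return An object of class `"base_sim_spec"`.
#' @export
base_sim_spec <- function(accuracy = 0.5, coupling = 0.95,
                          concentration = 4, seed = 1L) {
  stopifnot(accuracy > 0, accuracy <= 1, coupling >= 0, coupling <= 1,
            concentration > 0)
  structure(list(accuracy = accuracy, coupling = coupling,
                 concentration = concentration, seed = as.integer(seed)),
            class = "base_sim_spec")
}

#' Simulate a base model's probability profile
#'
#' Emulates the per-residue output of an inverse-folding base model with a
#' given accuracy and confidence-correctness coupling (see
#' [base_sim_spec()]). Rows put probability mass on a target residue (the
#' native one when "correct") with a sharp or flat logit and are uniform
#' elsewhere, so row entropy is monotone in sharpness.
#'
#' @param native Native sequence (string or integer tokens, no unknowns).
#' @param spec A [base_sim_spec()].
#' @return A [probability_profile()] with `source = "base"`.
#' @export
simulate_base_profile <- function(native, spec) {
  stopifnot(inherits(spec, "base_sim_spec"))
  if (is.character(native)) native <- tokenize(native)
  if (any(native == TOK_UNKNOWN))
    stop("simulate_base_profile: native sequence contains unknown tokens")
  n <- length(native)
  set.seed(spec$seed)
  correct <- stats::runif(n) < spec$accuracy
  target <- native
  wrong <- which(!correct)
  if (length(wrong))
    target[wrong] <- vapply(native[wrong], function(a)
      sample(setdiff(1:20, a), 1L), integer(1L))
  coupled <- stats::runif(n) < spec$coupling
  sharp <- ifelse(coupled, correct, stats::runif(n) < 0.5)
  lambda <- ifelse(sharp,
                   spec$concentration * stats::runif(n, 0.8, 1.2),
                   0.15 * spec$concentration * stats::runif(n, 0.5, 1.5))
  # p_target = 1 / (1 + 19 exp(-lambda)), off-target uniform (stable for
  # arbitrarily large concentration)
  p_t <- 1 / (1 + 19 * exp(-lambda))
  probs <- matrix((1 - p_t) / 19, n, 20L)
  probs[cbind(seq_len(n), target)] <- p_t
  probability_profile(probs, source = "base")
}

#' Generate a reproducible toy dataset
#'
#' Draws `n` toy backbones with lengths uniform in `length_range`, couples
#' sequences with a shared rule seed, and returns structures, sequences
#' and a manifest describing every example.
#'
#' @param n Number of structures.
#' @param length_range Integer 2-vector, inclusive chain-length range.
#' @param coordinate_noise_sd Coordinate noise (A) passed to every spec.
#' @param rule_seed Seed of the shared sequence rule.
#' @param n_rule_variants Number of sequence-rule variants mixed in the
#'   dataset (each protein draws one uniformly); see [couple_sequence()].
#'   With the default 4 variants and `variable_frac = 0.3`, roughly 30%
#'   of positions are predictable only with sequence context.
#' @param variable_frac Fraction of variant-specific descriptor keys.
#' @param seed Master seed; per-example seeds are derived from it.
#' @return A list with `structures` (list of [backbone_structure()], each
#'   with `$native_sequence` set), `sequences` (character vector) and
#'   `manifest` (data.frame: index, seed, length, noise, rule_seed,
#'   variant).
#' @export
make_toy_dataset <- function(n, length_range = c(30L, 60L),
                             coordinate_noise_sd = 0, rule_seed = 42L,
                             n_rule_variants = 4L, variable_frac = 0.3,
                             seed = 1L) {
  set.seed(seed)
  lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
  seeds <- sample.int(1e7, n)
  variants <- if (n_rule_variants > 1L)
    sample.int(n_rule_variants, n, replace = TRUE) else rep(0L, n)
  structures <- vector("list", n)
  sequences <- character(n)
  for (i in seq_len(n)) {
    st <- generate_backbone(toy_spec(lens[i],
                                     coordinate_noise_sd = coordinate_noise_sd,
                                     seed = seeds[i]))
    sq <- couple_sequence(st, rule_seed = rule_seed, variant = variants[i],
                          variable_frac = variable_frac)
    st$native_sequence <- sq
    structures[[i]] <- st
    sequences[i] <- sq
  }
  manifest <- data.frame(index = seq_len(n), seed = seeds, length = lens,
                         coordinate_noise_sd = coordinate_noise_sd,
                         rule_seed = rule_seed, variant = variants)
  list(structures = structures, sequences = sequences, manifest = manifest)
}
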