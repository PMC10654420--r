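# entropy computation, residue selection, fusion, design pipelines,
# mutation scanning

test_that("entropy: uniform, one-hot and two-point cases are exact", {
  expect_equal(entropy(rep(0.05, 20L)), log(20), tolerance = 1e-9)
  expect_equal(entropy(c(1, rep(0, 19L))), 0)
  expect_equal(entropy(c(0.5, 0.5, rep(0, 18L))), log(2), tolerance = 1e-9)
  expect_error(entropy(c(0.5, 0.6)), "probability")
})

test_that("select_low_entropy keeps the exact lowest-entropy set with base argmax", {
  # hand-set entropies via sharpness: rows 2, 5, 9 are near one-hot
  n <- 10L
  P <- matrix(1 / 20, n, 20L)
  sharp <- c(2L, 5L, 9L)
  targets <- c(4L, 17L, 1L)
  for (s in seq_along(sharp)) {
    P[sharp[s], ] <- 0.01 / 19
    P[sharp[s], targets[s]] <- 0.99
  }
  pp <- probability_profile(P / rowSums(P), source = "base")
  ps <- select_low_entropy(pp, 0.35)  # floor(3.5) = 3 kept
  expect_equal(which(ps$visible), sharp)
  expect_equal(ps$tokens[sharp], targets)
  expect_false(any(select_low_entropy(pp, 0)$visible))
  full <- select_low_entropy(pp, 1)
  expect_true(all(full$visible))
  expect_equal(full$tokens, max.col(pp$probs, ties.method = "first"))
})

test_that("entropy ties break by index, argmax ties by alphabet order", {
  P <- matrix(1 / 20, 4L, 20L)  # all rows identical: full tie
  pp <- probability_profile(P, source = "base")
  ps <- select_low_entropy(pp, 0.5)
  expect_equal(which(ps$visible), c(1L, 2L))
  expect_equal(ps$tokens[1:2], c(1L, 1L))  # 'A' wins the argmax tie
})

test_that("fusion arithmetic: equal entropies average; 0 vs ln20 gives 20/21", {
  p1 <- c(0.7, 0.1, rep(0.2 / 18, 18L))
  p2 <- c(0.1, 0.6, rep(0.3 / 18, 18L))
  # force equal entropies by fusing a distribution with itself after
  # permutation-free check: use two rows with identical entropy by symmetry
  pa <- c(0.5, 0.5, rep(0, 18L))
  pb <- c(rep(0, 18L), 0.5, 0.5)
  expect_equal(fuse(pa, pb), (pa + pb) / 2, tolerance = 1e-12)
  onehot <- c(1, rep(0, 19L))
  unif <- rep(0.05, 20L)
  fused <- fuse(onehot, unif)
  w <- 1 / (1 + 1 / 20)  # exp(0) vs exp(-ln 20)
  expect_equal(w, 20 / 21)
  expect_equal(fused, w * onehot + (1 - w) * unif, tolerance = 1e-12)
  # general rows stay valid distributions
  set.seed(5)
  for (r in 1:20) {
    q1 <- rgamma(20, 1); q1 <- q1 / sum(q1)
    q2 <- rgamma(20, 0.3); q2 <- q2 / sum(q2)
    f <- fuse(q1, q2)
    expect_lt(abs(sum(f) - 1), 1e-9)
    expect_true(all(f >= 0))
  }
})

test_that("fused profiles are valid and fused entropy obeys the coarse bound", {
  set.seed(6)
  r1 <- random_profile(30L, concentration = 0.5)
  r2 <- random_profile(30L, concentration = 2)
  fp <- ipfrefine:::fuse_profiles(r1, r2)
  expect_s3_class(fp, "probability_profile")
  expect_equal(fp$source, "fused")
  expect_true(all(fp$entropy <= pmax(r1$entropy, r2$entropy) + log(2) + 1e-9))
})

test_that("design_entire: oracle base recovers natives; fuse switch works", {
  m <- tiny_model(seed = 21L)
  st <- toy_structure(12L, seed = 21L)
  nat <- couple_sequence(st)
  nat_tok <- tokenize(nat)
  onehot <- matrix(0, 12L, 20L)
  onehot[cbind(1:12, nat_tok)] <- 1
  base <- probability_profile(onehot, source = "base")
  res <- design_entire(st, base, m, refine_config(keep_fraction = 0.35))
  # a zero-entropy correct base dominates fusion at every position
  expect_equal(res$sequence, nat)
  expect_equal(res$profile$source, "fused")
  # fuse = FALSE returns the refiner argmax alone
  res2 <- design_entire(st, base, m,
                        refine_config(keep_fraction = 0.35, fuse = FALSE))
  ref <- predict(m, st, ipfrefine:::select_low_entropy(base, 0.35))
  expect_equal(res2$sequence,
               untokenize(max.col(ref$probs, ties.method = "first")))
  expect_error(design_entire(st, random_profile(5L), m), "length")
})

test_that("design_partial preserves fixed residues and fills the rest", {
  m <- tiny_model(seed = 22L)
  st <- toy_structure(14L, seed = 22L)
  nat <- tokenize(couple_sequence(st))
  tk <- nat
  tk[8L] <- 21L  # single unknown site
  res <- design_partial(st, partial_sequence(tk), m)
  out <- tokenize(res$sequence)
  expect_equal(nchar(res$sequence), 14L)
  expect_equal(out[-8L], nat[-8L])  # fixed positions verbatim
  expect_error(design_partial(st, partial_sequence(nat), m), "no unknown")
})

test_that("partial design with context beats entire design on the same positions", {
  tw <- toyworld_model()
  set.seed(72)
  hits_partial <- 0L; hits_entire <- 0L; tot <- 0L
  for (i in 1:20) {
    nat <- tokenize(tw$heldout$sequences[i])
    n <- length(nat)
    vis <- sample(n, round(0.5 * n))
    mask <- setdiff(seq_len(n), vis)
    feats <- featurize_structure(tw$heldout$structures[[i]], tw$fit)
    tk <- rep(21L, n); tk[vis] <- nat[vis]
    p_part <- model_forward(tw$fit, feats, partial_sequence(tk))
    p_full <- model_forward(tw$fit, feats)  # every position unknown
    hits_partial <- hits_partial +
      sum(max.col(p_part$probs, ties.method = "first")[mask] == nat[mask])
    hits_entire <- hits_entire +
      sum(max.col(p_full$probs, ties.method = "first")[mask] == nat[mask])
    tot <- tot + length(mask)
  }
  expect_gt(hits_partial / tot, hits_entire / tot)
})

test_that("keep-fraction lookup matches the per-base-model calibration", {
  expect_equal(keep_fraction_for_base("gvp"), 0.10)
  expect_equal(keep_fraction_for_base("ProteinMPNN"), 0.10)
  expect_equal(keep_fraction_for_base("mpnn-c"), 0.15)
  expect_equal(keep_fraction_for_base("ESM-IF1"), 0.35)
  expect_equal(keep_fraction_for_base("somethingelse"), 0.15)
})

test_that("scan_mutations ranks by the combined percentile score", {
  m <- tiny_model(seed = 23L)
  st <- toy_structure(20L, seed = 23L)
  nat <- couple_sequence(st)
  # pick candidate sites whose native residue is not the target
  target <- "R"
  nat_tok <- tokenize(nat)
  sites <- which(AA_ALPHABET[nat_tok] != target)[1:5]
  center <- colMeans(st$CA)
  res_p <- scan_mutations(st, nat, m,
                          mutation_scan_config(target, sites, center,
                                               combine_weight = 1,
                                               top_n = 3L))
  # combine_weight = 1: order is pure probability order
  expect_true(all(diff(res_p$prob_target) <= 1e-12))
  # combine_weight = 0: order is pure proximity order
  res_d <- scan_mutations(st, nat, m,
                          mutation_scan_config(target, sites, center,
                                               combine_weight = 0))
  expect_true(all(diff(res_d$dist_A) >= -1e-12))
  expect_equal(sum(res_p$recommended), 3L)
  # a site already carrying the target residue is skipped with a warning
  site_r <- which(AA_ALPHABET[nat_tok] == target)
  if (length(site_r) > 0L)
    expect_warning(scan_mutations(st, nat, m,
                                  mutation_scan_config(target,
                                                       c(sites, site_r[1L]),
                                                       center)),
                   "skipping")
})

test_that("hand-set probabilities and distances combine to the expected order", {
  # 5 candidates: probabilities favor 1..5 descending, distances favor
  # 5..1 (candidate 5 closest); with weight 0.7 on probability the
  # hand-computed combined scores order the sites 1, 2, 3, 4, 5
  probs <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  dists <- c(5, 4, 3, 2, 1)
  pp <- c(1.0, 0.8, 0.6, 0.4, 0.2)   # descending percentile of probs
  dp <- c(0.2, 0.4, 0.6, 0.8, 1.0)   # ascending percentile of distances
  expect_equal(ipfrefine:::rank_pct(probs, "desc"), pp)
  expect_equal(ipfrefine:::rank_pct(dists, "asc"), dp)
  w <- 0.7
  score <- w * pp + (1 - w) * dp
  expect_equal(order(-score), 1:5)
  # with weight 0.3 proximity dominates and the order reverses
  score2 <- 0.3 * pp + 0.7 * dp
  expect_equal(order(-score2), 5:1)
})
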