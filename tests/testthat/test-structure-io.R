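# PDB / FASTA / probability-profile input and output

make_pdb_fixture <- function(path, lines) writeLines(lines, path)

# hand-written 3-residue PDB, complete backbones, two chains
pdb3_lines <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.004   1.424   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       1.251   2.390   0.123  1.00  0.00           O",
  "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
  "ATOM      6  CA  GLY A   2       3.988   2.840   0.096  1.00  0.00           C",
  "ATOM      7  C   GLY A   2       5.496   2.690   0.112  1.00  0.00           C",
  "ATOM      8  O   GLY A   2       6.030   1.580   0.103  1.00  0.00           O",
  "ATOM      9  N   TRP A   3       6.210   3.810   0.140  1.00  0.00           N",
  "ATOM     10  CA  TRP A   3       7.663   3.820   0.160  1.00  0.00           C",
  "ATOM     11  C   TRP A   3       8.220   5.230   0.180  1.00  0.00           C",
  "ATOM     12  O   TRP A   3       7.480   6.210   0.200  1.00  0.00           O",
  "ATOM     13  N   LYS B  10       0.000   0.000   5.000  1.00  0.00           N",
  "ATOM     14  CA  LYS B  10       1.458   0.000   5.000  1.00  0.00           C",
  "ATOM     15  C   LYS B  10       2.004   1.424   5.000  1.00  0.00           C",
  "ATOM     16  O   LYS B  10       1.251   2.390   5.123  1.00  0.00           O",
  "END")

test_that("read_backbone reads coordinates, chains and sequences back exactly", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  make_pdb_fixture(tf, pdb3_lines())
  st <- read_backbone(tf, "A")
  expect_s3_class(st, "backbone_structure")
  expect_equal(st$n_residues, 3L)
  expect_equal(st$N[1L, ], c(0, 0, 0), tolerance = 1e-3)
  expect_equal(st$CA[2L, ], c(3.988, 2.840, 0.096), tolerance = 1e-3)
  expect_equal(st$O[3L, ], c(7.480, 6.210, 0.200), tolerance = 1e-3)
  expect_equal(st$native_sequence, "AGW")
  expect_equal(st$residue_numbers, 1:3)
  # chain selection: B has a single (complete) residue
  stB <- read_backbone(tf, "B")
  expect_equal(stB$n_residues, 1L)
  expect_equal(stB$native_sequence, "K")
  expect_equal(stB$residue_numbers, 10L)
  expect_equal(stB$CA[1L, 3L], 5.0, tolerance = 1e-3)
})

test_that("read_backbone drops incomplete residues with a warning and errors cleanly", {
  lines <- pdb3_lines()
  tf <- withr::local_tempfile(fileext = ".pdb")
  make_pdb_fixture(tf, lines[-8L])  # drop residue 2's O atom
  expect_warning(st <- read_backbone(tf, "A"), "incomplete backbone")
  expect_equal(st$n_residues, 2L)
  expect_equal(st$native_sequence, "AW")
  expect_error(read_backbone(tf, "Z"), "chain 'Z'")
  expect_error(read_backbone(tempfile(), "A"), "no such file")
})

test_that("MSE maps to methionine; altloc resolves to highest occupancy", {
  lines <- c(
    "ATOM      1  N   MSE A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AMSE A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BMSE A   1       1.500   0.100   0.000  0.60  0.00           C",
    "ATOM      4  C   MSE A   1       2.004   1.424   0.000  1.00  0.00           C",
    "ATOM      5  O   MSE A   1       1.251   2.390   0.123  1.00  0.00           O",
    "END")
  tf <- withr::local_tempfile(fileext = ".pdb")
  make_pdb_fixture(tf, lines)
  st <- read_backbone(tf, "A")
  expect_equal(st$native_sequence, "M")
  expect_equal(st$CA[1L, 1L], 1.500, tolerance = 1e-3)  # the 0.60 altloc
})

test_that("synthetic structure -> PDB -> read_backbone round-trips to 0.001 A", {
  st <- toy_structure(20L, seed = 4L)
  st$native_sequence <- couple_sequence(st)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(st, tf)
  st2 <- read_backbone(tf, "A")
  expect_equal(st2$n_residues, st$n_residues)
  for (atom in c("N", "CA", "C", "O"))
    expect_lt(max(abs(st2[[atom]] - st[[atom]])), 1e-3 + 1e-9)
  expect_equal(st2$native_sequence, st$native_sequence)
})

test_that("read_partial_sequence handles X, case and length checking", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p", "ACDX"), tf)
  ps <- read_partial_sequence(tf, 4L)
  expect_equal(ps$visible, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(ps$tokens, c(1L, 2L, 3L, 21L))
  writeLines(c(">p", "XXXX"), tf)
  expect_false(any(read_partial_sequence(tf, 4L)$visible))
  writeLines(c(">p", "acdx"), tf)  # lowercase accepted, upper-cased
  expect_equal(read_partial_sequence(tf, 4L)$tokens, c(1L, 2L, 3L, 21L))
  expect_error(read_partial_sequence(tf, 5L), "length")
  writeLines(c(">p", "ACDB"), tf)  # B is outside the alphabet
  expect_error(read_partial_sequence(tf, 4L), "alphabet")
})

test_that("write_design emits 60-column FASTA and round-trips", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_design(tf, "ACD", "design_1")
  expect_identical(readLines(tf), c(">design_1", "ACD"))
  seq61 <- paste(rep("A", 61L), collapse = "")
  write_design(tf, seq61, "long")
  lines <- readLines(tf)
  expect_length(lines, 3L)  # header + 60 + 1
  expect_equal(nchar(lines[2L]), 60L)
  ps <- read_partial_sequence(tf, 61L)
  expect_equal(untokenize(ps$tokens), seq61)
})

test_that("probability profiles read, renormalize, reject bad rows", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(paste(rep("0.05", 20L), collapse = "\t"),       # uniform
            paste(c("1", rep("0", 19L)), collapse = "\t"),  # one-hot
            paste(c("0.0505", rep("0.05", 19L)), collapse = "\t"))  # sums 1.0005
  writeLines(c(paste0("#", paste(AA_ALPHABET, collapse = "")), rows), tf)
  pp <- read_probability_profile(tf, 3L)
  expect_equal(pp$entropy[1L], log(20), tolerance = 1e-9)
  expect_equal(pp$entropy[2L], 0, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(pp$probs) - 1)), 1e-9)
  # row off by more than 1e-3 is rejected
  writeLines(c(rows[1L], paste(rep("0.051", 20L), collapse = "\t")), tf)
  expect_error(read_probability_profile(tf, 2L), "tolerance")
  # wrong column count
  writeLines(paste(rep("0.1", 10L), collapse = "\t"), tf)
  expect_error(read_probability_profile(tf, 1L), "20 columns")
  # negative entry
  writeLines(paste(c("-0.05", "0.1", rep("0.05", 18L)), collapse = "\t"), tf)
  expect_error(read_probability_profile(tf, 1L), "negative")
})

test_that("partial_sequence enforces the token/visibility invariant", {
  ps <- partial_sequence("AXC")
  expect_equal(ps$visible, c(TRUE, FALSE, TRUE))
  bad <- ps
  bad$visible[2L] <- TRUE
  expect_error(ipfrefine:::validate_partial_sequence(bad))
})
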