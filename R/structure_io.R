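#' Backbone structure container
#'
#' Holds the per-residue heavy-atom coordinates of a single protein chain:
#' N, C-alpha, C and O as N x 3 matrices (Angstroms), author residue
#' numbering, and optionally the native sequence.
#'
#' @param chain_id Chain identifier (single string).
#' @param N,CA,C,O N x 3 coordinate matrices.
#' @param residue_numbers Integer vector of author residue numbers.
#' @param native_sequence Optional length-N sequence string.
#' @return An object of class `"backbone_structure"`.
#' @export
backbone_structure <- function(chain_id, N, CA, C, O, residue_numbers,
                               native_sequence = NULL) {
  st <- structure(list(chain_id = as.character(chain_id),
                       n_residues = nrow(CA),
                       N = N, CA = CA, C = C, O = O,
                       residue_numbers = as.integer(residue_numbers),
                       native_sequence = native_sequence),
                  class = "backbone_structure")
  validate_backbone_structure(st)
}

validate_backbone_structure <- function(st) {
  stopifnot(inherits(st, "backbone_structure"))
  n <- st$n_residues
  for (atom in c("N", "CA", "C", "O")) {
    X <- st[[atom]]
    if (!is.matrix(X) || nrow(X) != n || ncol(X) != 3L)
      stop("backbone_structure: ", atom, " must be an N x 3 matrix")
    if (!all(is.finite(X)))
      stop("backbone_structure: non-finite coordinates in ", atom)
  }
  if (length(st$residue_numbers) != n)
    stop("backbone_structure: residue_numbers length mismatch")
  if (n >= 2L) {
    dca <- sqrt(rowSums((st$CA[-1L, , drop = FALSE] -
                           st$CA[-n, , drop = FALSE])^2))
    if (any(dca <= 0))
      stop("backbone_structure: consecutive C-alpha positions coincide")
  }
  if (!is.null(st$native_sequence)) {
    if (nchar(st$native_sequence) != n)
      stop("backbone_structure: native_sequence length != n_residues")
    tokenize(st$native_sequence)  # validates the alphabet
  }
  st
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat(sprintf("<backbone_structure> chain %s, %d residues%s\n",
              x$chain_id, x$n_residues,
              if (is.null(x$native_sequence)) "" else ", with native sequence"))
  invisible(x)
}

#' Read a single-chain backbone from a PDB file
#'
#' Parses one chain from a PDB file via \pkg{bio3d} and extracts the
#' backbone N, CA, C, O atoms per residue. Alternate locations are
#' resolved to the highest occupancy; residues missing any of the four
#' backbone atoms are dropped with a warning; non-standard residues with a
#' 20-letter parent (e.g. MSE -> M) are mapped to it, others dropped with
#' a warning. Residue order follows file order.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier to extract.
#' @return A [backbone_structure()]; `native_sequence` is filled from the
#'   residue names.
#' @export
read_backbone <- function(path, chain = "A") {
  if (!file.exists(path)) stop("read_backbone: no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" | at$type == "HETATM", , drop = FALSE]
  at <- at[!is.na(at$chain) & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("read_backbone: chain '", chain, "' not found in ", path)
  at <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  # one residue = (resno, insert) in file order
  ins <- ifelse(is.na(at$insert), "", at$insert)
  resk <- paste0(at$resno, "_", ins)
  res_order <- unique(resk)

  n_all <- length(res_order)
  coords <- list(N = matrix(NA_real_, n_all, 3L), CA = matrix(NA_real_, n_all, 3L),
                 C = matrix(NA_real_, n_all, 3L), O = matrix(NA_real_, n_all, 3L))
  resno <- integer(n_all)
  resid3 <- character(n_all)
  for (r in seq_along(res_order)) {
    sub <- at[resk == res_order[r], , drop = FALSE]
    resno[r] <- sub$resno[1L]
    resid3[r] <- sub$resid[1L]
    for (atom in c("N", "CA", "C", "O")) {
      rows <- sub[sub$elety == atom, , drop = FALSE]
      if (nrow(rows) == 0L) next
      if (nrow(rows) > 1L) {
        occ <- rows$o
        occ[is.na(occ)] <- 1
        rows <- rows[which.max(occ), , drop = FALSE]
      }
      coords[[atom]][r, ] <- c(rows$x, rows$y, rows$z)
    }
  }
  aa1 <- AA_THREE_TO_ONE[resid3]
  complete <- !is.na(coords$N[, 1L]) & !is.na(coords$CA[, 1L]) &
    !is.na(coords$C[, 1L]) & !is.na(coords$O[, 1L])
  if (any(!complete))
    warning("read_backbone: dropping ", sum(!complete),
            " residue(s) with incomplete backbone (chain ", chain, ")")
  known <- !is.na(aa1)
  if (any(!known & complete))
    warning("read_backbone: dropping ", sum(!known & complete),
            " residue(s) with unmappable residue name: ",
            paste(unique(resid3[!known & complete]), collapse = ", "))
  keep <- complete & known
  if (!any(keep))
    stop("read_backbone: chain '", chain,
         "' has no residues with a complete N/CA/C/O backbone")
  backbone_structure(chain_id = chain,
                     N = coords$N[keep, , drop = FALSE],
                     CA = coords$CA[keep, , drop = FALSE],
                     C = coords$C[keep, , drop = FALSE],
                     O = coords$O[keep, , drop = FALSE],
                     residue_numbers = resno[keep],
                     native_sequence = paste(aa1[keep], collapse = ""))
}

#' Write a backbone structure as a PDB file
#'
#' Writes the four backbone atoms per residue as ATOM records (residue
#' names from the native sequence if present, else ALA). Coordinates
#' survive a round trip through [read_backbone()] to the PDB format's
#' 0.001 A precision.
#'
#' @param structure A [backbone_structure()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_backbone_pdb <- function(structure, path) {
  st <- validate_backbone_structure(structure)
  n <- st$n_residues
  one2three <- names(AA_THREE_TO_ONE)[match(
    if (is.null(st$native_sequence)) rep("A", n)
    else strsplit(st$native_sequence, "")[[1L]],
    AA_THREE_TO_ONE)]
  xyz <- numeric(0)
  elety <- character(0); resno <- integer(0); resid <- character(0)
  for (i in seq_len(n)) {
    xyz <- c(xyz, st$N[i, ], st$CA[i, ], st$C[i, ], st$O[i, ])
    elety <- c(elety, "N", "CA", "C", "O")
    resno <- c(resno, rep(st$residue_numbers[i], 4L))
    resid <- c(resid, rep(one2three[i], 4L))
  }
  bio3d::write.pdb(file = path, xyz = xyz, elety = elety, resno = resno,
                   resid = resid, chain = rep(st$chain_id, length(elety)))
  invisible(path)
}

#' Read a partial sequence from FASTA
#'
#' Single-record FASTA; `X` (any case) marks unknown positions. Lowercase
#' letters are accepted and upper-cased.
#'
#' @param path FASTA file path.
#' @param expected_length Required sequence length.
#' @return A [partial_sequence()].
#' @export
read_partial_sequence <- function(path, expected_length) {
  if (!file.exists(path)) stop("read_partial_sequence: no such file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) < 1L) stop("read_partial_sequence: empty FASTA")
  s <- toupper(as.character(recs[[1L]]))
  if (nchar(s) != expected_length)
    stop("read_partial_sequence: sequence length ", nchar(s),
         " != expected ", expected_length)
  partial_sequence(s)
}

#' Write a designed sequence as FASTA
#'
#' Single-record FASTA with 60 columns per sequence line.
#'
#' @param path Output path.
#' @param sequence Sequence string.
#' @param header Record header (without `>`).
#' @return Invisibly, `path`.
#' @export
write_design <- function(path, sequence, header = "design") {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("write_design: cannot write ", path))
  on.exit(close(con))
  writeLines(paste0(">", header), con)
  n <- nchar(sequence)
  starts <- seq(1L, n, by = 60L)
  writeLines(substring(sequence, starts, pmin(starts + 59L, n)), con)
  invisible(path)
}

#' Probability profile container
#'
#' An N x 20 row-stochastic matrix of per-residue amino-acid
#' probabilities (columns in canonical alphabet order) with per-row
#' Shannon entropies (natural log).
#'
#' @param probs N x 20 matrix; rows must sum to 1 within 1e-6 (use
#'   [read_probability_profile()] for file input with renormalization).
#' @param source Tag: `"refiner"`, `"base"` or `"fused"`.
#' @return An object of class `"probability_profile"` with elements
#'   `probs`, `entropy`, `source`.
#' @export
probability_profile <- function(probs, source = "refiner") {
  if (!is.matrix(probs) || ncol(probs) != 20L)
    stop("probability_profile: probs must be an N x 20 matrix")
  if (any(probs < 0) || any(!is.finite(probs)))
    stop("probability_profile: probabilities must be finite and nonnegative")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6))
    stop("probability_profile: rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  structure(list(probs = probs, entropy = row_entropy(probs),
                 source = source),
            class = "probability_profile")
}

# -sum p log p per row, with 0 log 0 := 0
row_entropy <- function(P) {
  L <- ifelse(P > 0, log(P), 0)
  -rowSums(P * L)
}

#' @export
print.probability_profile <- function(x, ...) {
  cat(sprintf("<probability_profile> %d residues, source = %s, mean entropy %.3f nats\n",
              nrow(x$probs), x$source, mean(x$entropy)))
  invisible(x)
}

#' Read a probability profile from TSV
#'
#' Tab-separated text, one row per residue, 20 columns in canonical
#' alphabet order (optional header line `#ACDEFGHIKLMNPQRSTVWY`). Rows
#' whose sum deviates from 1 by at most 1e-3 are renormalized; larger
#' deviations, negative entries or a wrong column count are errors.
#'
#' @param path TSV file path.
#' @param expected_length Required number of rows.
#' @return A [probability_profile()] with `source = "base"`.
#' @export
read_probability_profile <- function(path, expected_length) {
  if (!file.exists(path)) stop("read_probability_profile: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) != expected_length)
    stop("read_probability_profile: ", length(lines), " rows, expected ",
         expected_length)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 20L))
    stop("read_probability_profile: expected 20 columns, found ",
         paste(unique(ncols[ncols != 20L]), collapse = ","))
  P <- matrix(as.numeric(unlist(fields)), ncol = 20L, byrow = TRUE)
  if (any(!is.finite(P))) stop("read_probability_profile: non-numeric entry")
  if (any(P < 0)) stop("read_probability_profile: negative probability")
  rs <- rowSums(P)
  bad <- abs(rs - 1) > 1e-3
  if (any(bad))
    stop("read_probability_profile: row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ","),
         " sum to ", format(rs[which(bad)[1L]]), "; tolerance is 1e-3")
  P <- P / rs
  probability_profile(P, source = "base")
}

#' Write a probability profile as TSV
#'
#' Inverse of [read_probability_profile()]: header line
#' `#ACDEFGHIKLMNPQRSTVWY`, then one tab-separated row per residue.
#'
#' @param profile A [probability_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_probability_profile <- function(profile, path) {
  stopifnot(inherits(profile, "probability_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(AA_ALPHABET, collapse = "")), con)
  writeLines(apply(profile$probs, 1L, function(r)
    paste(format(r, digits = 10, scientific = FALSE, trim = TRUE),
          collapse = "\t")), con)
  invisible(path)
}
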