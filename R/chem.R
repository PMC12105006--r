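# Molecule identity, circular fingerprints and Tanimoto similarity.
#
# SMILES handling is delegated to OpenBabel: canonicalization and fingerprint
# generation run through the `obabel` executable in batch mode (one process
# per call, arbitrarily many molecules), which is orders of magnitude faster
# than per-molecule in-process conversion and gives identical results.

ob_binary <- function() {
  path <- Sys.which("obabel")
  if (!nzchar(path)) {
    stop("the 'obabel' executable (OpenBabel) was not found on PATH", call. = FALSE)
  }
  path
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form, so that two encodings of the
#' same structure map to the same string. Canonicalization is idempotent:
#' applying it to an already-canonical string returns the string unchanged.
#'
#' @param smiles character vector of SMILES strings.
#' @param skip_invalid if `TRUE`, unparsable entries are returned as `NA`
#'   with a warning naming the offending positions; if `FALSE` (default) any
#'   unparsable entry is an error.
#' @return character vector of canonical SMILES, same length as the input
#'   (with `NA` for skipped entries when `skip_invalid = TRUE`).
#' @examples
#' canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1")) # both "c1ccccc1"
#' @export
canonical_smiles <- function(smiles, skip_invalid = FALSE) {
  if (!is.character(smiles) || length(smiles) == 0L) {
    stop("'smiles' must be a non-empty character vector")
  }
  if (anyNA(smiles) || any(!nzchar(smiles))) {
    stop("'smiles' contains empty or NA entries")
  }
  if (any(grepl("[ \t]", smiles))) {
    stop("SMILES strings must not contain whitespace")
  }
  out <- ob_smiles_convert(smiles)
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    msg <- sprintf(
      "unparsable SMILES at position%s %s: %s",
      if (length(bad) > 1L) "s" else "",
      paste(bad, collapse = ", "),
      paste(utils::head(smiles[bad], 5L), collapse = ", ")
    )
    if (skip_invalid) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  out
}

# Batch SMILES -> canonical SMILES through obabel; NA where parsing failed.
ob_smiles_convert <- function(smiles) {
  inf <- tempfile(fileext = ".smi")
  outf <- tempfile(fileext = ".can")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), inf)
  system2(ob_binary(), c(inf, "-ocan", "-O", outf),
          stdout = FALSE, stderr = FALSE)
  out <- rep(NA_character_, length(smiles))
  if (file.exists(outf)) {
    lines <- readLines(outf, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) > 0L) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      idx <- suppressWarnings(as.integer(vapply(parts, function(p) p[2], "")))
      smi <- vapply(parts, function(p) p[1], "")
      keep <- !is.na(idx) & nzchar(smi)
      out[idx[keep]] <- smi[keep]
    }
  }
  out
}

#' Circular (Morgan-type) fingerprints
#'
#' Computes extended-connectivity fingerprints (atom-centered circular
#' environments up to `radius` bonds) folded to a fixed-length bit vector.
#'
#' @param smiles character vector of SMILES.
#' @param radius neighborhood radius in bonds (default 2, i.e. ECFP4-class).
#' @param n_bits folded fingerprint length; a power of two, at least 32
#'   (default 2048).
#' @return integer 0/1 matrix with one row per molecule (`length(smiles)` x
#'   `n_bits`), rows named by the input SMILES.
#' @export
morgan_fp <- function(smiles, radius = 2L, n_bits = 2048L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0 ||
      radius != as.integer(radius)) {
    stop("'radius' must be a single non-negative integer")
  }
  if (!is.numeric(n_bits) || length(n_bits) != 1L || n_bits <= 0 ||
      n_bits != as.integer(n_bits)) {
    stop("'n_bits' must be a single positive integer")
  }
  n_bits <- as.integer(n_bits)
  if (n_bits < 32L || bitwAnd(n_bits, n_bits - 1L) != 0L) {
    stop("'n_bits' must be a power of two >= 32")
  }
  if (radius > 5) {
    stop("'radius' larger than 5 is not supported by the ECFP backend")
  }
  ob_fingerprint(smiles, sprintf("ECFP%d", 2L * as.integer(radius)), n_bits)
}

#' Path-based fingerprints
#'
#' Linear-fragment (path) fingerprints of up to 7 atoms, 1024 bits; the
#' bit-vector substructure representation used alongside circular
#' fingerprints for model featurization.
#'
#' @inheritParams morgan_fp
#' @param n_bits folded length (power of two, default 1024).
#' @return integer 0/1 matrix, `length(smiles)` x `n_bits`.
#' @export
path_fp <- function(smiles, n_bits = 1024L) {
  n_bits <- as.integer(n_bits)
  if (n_bits < 32L || bitwAnd(n_bits, n_bits - 1L) != 0L) {
    stop("'n_bits' must be a power of two >= 32")
  }
  ob_fingerprint(smiles, "FP2", n_bits)
}

#' MACCS structural keys
#'
#' 166-class SMARTS key fingerprint used as part of the substructure-key
#' descriptor vector.
#'
#' @inheritParams morgan_fp
#' @return integer 0/1 matrix, `length(smiles)` x 256 (OpenBabel folds MACCS
#'   into a 256-bit vector).
#' @export
maccs_fp <- function(smiles) {
  ob_fingerprint(smiles, "MACCS", 256L)
}

# Batch fingerprints through `obabel -ofpt`, parsed from hex output.
# Any fixed hex-to-bit-position mapping preserves Tanimoto values; bits are
# numbered LSB-first within each 32-bit word.
ob_fingerprint <- function(smiles, fp_name, n_bits) {
  if (!is.character(smiles) || length(smiles) == 0L) {
    stop("'smiles' must be a non-empty character vector")
  }
  inf <- tempfile(fileext = ".smi")
  outf <- tempfile(fileext = ".fpt")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), inf)
  system2(ob_binary(),
          c(inf, "-ofpt", paste0("-xf", fp_name), "-xN", n_bits, "-xh",
            "-O", outf),
          stdout = FALSE, stderr = FALSE)
  lines <- if (file.exists(outf)) readLines(outf, warn = FALSE) else character(0)
  rec_starts <- grep("^>", lines)
  mat <- matrix(0L, nrow = length(smiles), ncol = n_bits,
                dimnames = list(smiles, NULL))
  seen <- logical(length(smiles))
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  for (r in seq_along(rec_starts)) {
    hdr <- lines[rec_starts[r]]
    idx <- as.integer(sub("^>([0-9]+).*$", "\\1", hdr))
    if (is.na(idx)) next
    seen[idx] <- TRUE
    body <- if (rec_ends[r] >= rec_starts[r] + 1L) {
      lines[seq(rec_starts[r] + 1L, rec_ends[r])]
    } else {
      character(0)
    }
    words <- unlist(strsplit(paste(body, collapse = " "), "\\s+"))
    # records may carry annotation lines (e.g. substructure notes); keep
    # only the 32-bit hex words
    words <- words[grepl("^[0-9a-fA-F]{8}$", words)]
    if (length(words) == 0L) next
    mat[idx, ] <- hex_words_to_bits(words, n_bits)
  }
  if (!all(seen)) {
    bad <- which(!seen)
    stop(sprintf("fingerprint generation failed for molecule%s %s (%s)",
                 if (length(bad) > 1L) "s" else "",
                 paste(bad, collapse = ", "),
                 paste(utils::head(smiles[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  mat
}

hex_words_to_bits <- function(words, n_bits) {
  n_words <- n_bits %/% 32L
  if (length(words) != n_words) {
    stop(sprintf("unexpected fingerprint width: %d hex words for %d bits",
                 length(words), n_bits))
  }
  hi <- strtoi(substr(words, 1L, 4L), 16L)
  lo <- strtoi(substr(words, 5L, 8L), 16L)
  halves <- as.integer(rbind(lo, hi)) # per word: low 16 bits, high 16 bits
  bits <- matrix(0L, nrow = 16L, ncol = 2L * n_words)
  for (b in 0:15) {
    bits[b + 1L, ] <- bitwAnd(bitwShiftR(halves, b), 1L)
  }
  as.integer(bits)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|` over bit vectors. Defined as 1 when both vectors are
#' all-zero (two featureless objects are treated as identical; this degenerate
#' case is a documented convention).
#'
#' @param a,b 0/1 (or logical) vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)) # 2/4 = 0.5
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) {
    stop(sprintf("fingerprint lengths differ (%d vs %d)", length(a), length(b)))
  }
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(1.0)
  inter / uni
}

# All pairwise Tanimoto similarities between the rows of two 0/1 matrices.
# Returns nrow(A) x nrow(B). All-zero vs all-zero pairs are 1 by convention.
tanimoto_matrix <- function(A, B) {
  if (ncol(A) != ncol(B)) {
    stop(sprintf("fingerprint lengths differ (%d vs %d)", ncol(A), ncol(B)))
  }
  storage.mode(A) <- "double"
  storage.mode(B) <- "double"
  inter <- A %*% t(B)
  na <- rowSums(A)
  nb <- rowSums(B)
  uni <- outer(na, nb, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  sim
}

#' Maximum Tanimoto similarity against a reference set
#'
#' For each query molecule, the maximum Tanimoto similarity of its circular
#' fingerprint against every member of a reference set -- the novelty
#' statistic s_D(G) of the similarity filter.
#'
#' @param query matrix of query fingerprints (rows), or a character vector of
#'   SMILES (fingerprinted with `radius`/`n_bits` defaults).
#' @param reference matrix of reference fingerprints, or character vector of
#'   SMILES. Must be non-empty.
#' @param radius,n_bits fingerprint parameters used when SMILES are given.
#' @return numeric vector of maxima, one per query row.
#' @export
max_similarity <- function(query, reference, radius = 2L, n_bits = 2048L) {
  if (is.character(query)) query <- morgan_fp(query, radius, n_bits)
  if (is.character(reference)) {
    if (length(reference) == 0L) stop("'reference' set must be non-empty")
    reference <- morgan_fp(reference, radius, n_bits)
  }
  if (!is.matrix(reference) || nrow(reference) == 0L) {
    stop("'reference' set must be non-empty")
  }
  if (!is.matrix(query)) query <- matrix(query, nrow = 1L)
  sims <- tanimoto_matrix(query, reference)
  unname(apply(sims, 1L, max))
}

#' Read molecules from a .smi or CSV file
#'
#' `.smi` files hold one molecule per line (SMILES, optional title); CSV
#' files must contain a `smiles` column. Rows that fail to parse are an
#' error naming the line numbers, unless `skip_invalid = TRUE`, in which
#' case they are dropped with a warning.
#'
#' @param path input file; format chosen by extension (`.smi` vs `.csv`).
#' @param skip_invalid drop unparsable rows instead of failing.
#' @return character vector of canonical SMILES.
#' @export
read_smiles <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("CSV must contain a 'smiles' column")
    raw <- as.character(df$smiles)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    raw <- vapply(strsplit(trimws(lines), "[ \t]+"), `[[`, "", 1L)
  }
  can <- canonical_smiles(raw, skip_invalid = skip_invalid)
  can[!is.na(can)]
}

#' Write molecules to a .smi file
#'
#' @param smiles character vector of SMILES.
#' @param path output path.
#' @export
write_smiles <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
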