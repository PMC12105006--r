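# Pluggable molecule generator with a fragment-recombination default.
# Training molecules are cleaved at acyclic single bonds (retrosynthetic-
# style: ring systems stay intact), yielding a multiset of fragments with a
# marked attachment atom. New molecules are assembled by joining two
# fragments with a single bond between their attachment atoms. Because each
# attachment atom lost exactly one single bond at cleavage, every
# recombination is valence-consistent by construction; products are
# validity-checked by reparsing and canonicalization.
#
# Any generator exposing `generate_batch(state, n, seed)` semantics can stand
# in (hierarchical graph generators, pocket-conditioned models, ...); this
# default keeps the loop free of learned components.

# Atom/bond tables for a batch of molecules, via their V2000 blocks.
mol_tables <- function(smiles) {
  sdfs <- ChemmineR::smiles2sdf(stats::setNames(smiles, seq_along(smiles)))
  lapply(seq_along(smiles), function(i) {
    s <- sdfs[[i]]
    bb <- ChemmineR::bondblock(s)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1L,
                                       dimnames = list(NULL, names(bb)))
    list(smiles = smiles[i],
         atoms = ChemmineR::atomblock(s),
         bonds = bb[, 1:3, drop = FALSE])
  })
}

# Indices of cleavable bonds: single order, acyclic (graph bridges).
cleavable_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(integer(0))
  g <- igraph::graph_from_edgelist(mol$bonds[, 1:2, drop = FALSE],
                                   directed = FALSE)
  br <- igraph::bridges(g)
  intersect(as.integer(br), which(mol$bonds[, 3] == 1))
}

# Split a molecule at bond `b` into two fragments, each with a local
# attachment-atom index.
split_at_bond <- function(mol, b) {
  i <- mol$bonds[b, 1]
  j <- mol$bonds[b, 2]
  bonds <- mol$bonds[-b, , drop = FALSE]
  g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mol$atoms) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lapply(c(i, j), function(a) {
    keep <- which(comp == comp[a])
    remap <- match(seq_len(nrow(mol$atoms)), keep)
    kb <- bonds[bonds[, 1] %in% keep & bonds[, 2] %in% keep, , drop = FALSE]
    kb[, 1] <- remap[kb[, 1]]
    kb[, 2] <- remap[kb[, 2]]
    list(atoms = mol$atoms[keep, , drop = FALSE],
         bonds = kb,
         attach = remap[a])
  })
}

atom_symbols <- function(atoms) sub("_.*$", "", rownames(atoms))

# V2000 molfile text for one fragment/molecule record.
molfile_text <- function(atoms, bonds, name = "mol") {
  sym <- atom_symbols(atoms)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(atoms), nrow(bonds))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        atoms[, 1], atoms[, 2], 0, sym)
  bond_lines <- if (nrow(bonds) > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], bonds[, 3])
  } else {
    character(0)
  }
  c(name, " denovoscreen 2D", "", counts, atom_lines, bond_lines,
    "M  END", "$$$$")
}

# Batch SDF -> canonical SMILES through obabel; NA where conversion failed.
sdf_to_canonical <- function(records) {
  inf <- tempfile(fileext = ".sdf")
  outf <- tempfile(fileext = ".can")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  writeLines(unlist(lapply(seq_along(records), function(i) {
    molfile_text(records[[i]]$atoms, records[[i]]$bonds, name = as.character(i))
  })), inf)
  system2(ob_binary(), c(inf, "-ocan", "-O", outf),
          stdout = FALSE, stderr = FALSE)
  out <- rep(NA_character_, length(records))
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

#' Build a fragment-recombination generator
#'
#' Cleaves every training molecule at each acyclic single bond and collects
#' the resulting fragments (with attachment-point markers) into a
#' deduplicated multiset. Rebuilding from the same inputs and seed is
#' bit-identical.
#'
#' @param smiles at least 20 valid training molecules (SMILES).
#' @param seed integer seed stored in the state and combined with the
#'   per-batch seed at generation time.
#' @return object of class `fragment_generator` with the canonical training
#'   set, the fragment pool and per-fragment multiplicities.
#' @export
fragment_generator <- function(smiles, seed = 1L) {
  can <- unique(canonical_smiles(smiles))
  if (length(can) < 20L) {
    stop(sprintf("at least 20 valid molecules are required to build the generator (got %d)",
                 length(can)))
  }
  mols <- mol_tables(can)
  frags <- list()
  for (mol in mols) {
    for (b in cleavable_bonds(mol)) {
      frags <- c(frags, split_at_bond(mol, b))
    }
  }
  if (length(frags) == 0L) {
    stop("no cleavable bonds in the training set; cannot build a fragment pool")
  }
  frag_smi <- sdf_to_canonical(frags)
  keys <- vapply(seq_along(frags), function(i) {
    f <- frags[[i]]
    paste(frag_smi[i], atom_symbols(f$atoms)[f$attach],
          sum(f$bonds[, 1] == f$attach | f$bonds[, 2] == f$attach),
          sep = "|")
  }, "")
  ok <- !is.na(frag_smi)
  frags <- frags[ok]
  keys <- keys[ok]
  first <- !duplicated(keys)
  pool <- frags[first]
  multiplicity <- as.integer(table(keys)[keys[first]])
  structure(list(training = can, pool = pool, multiplicity = multiplicity,
                 keys = keys[first], seed = seed),
            class = "fragment_generator")
}

#' @export
print.fragment_generator <- function(x, ...) {
  cat(sprintf("Fragment-recombination generator: %d training molecules, %d unique fragments (pool size %d)\n",
              length(x$training), length(x$pool), sum(x$multiplicity)))
  invisible(x)
}

# Join two fragments with a single bond between their attachment atoms.
join_fragments <- function(a, b) {
  na <- nrow(a$atoms)
  atoms <- rbind(a$atoms, b$atoms)
  rownames(atoms) <- paste(atom_symbols(atoms), seq_len(nrow(atoms)),
                           sep = "_")
  bb <- b$bonds
  if (nrow(bb) > 0L) {
    bb[, 1] <- bb[, 1] + na
    bb[, 2] <- bb[, 2] + na
  }
  bonds <- rbind(a$bonds, bb,
                 matrix(c(a$attach, b$attach + na, 1), nrow = 1L))
  list(atoms = atoms, bonds = bonds)
}

#' Generate a batch of novel molecules
#'
#' Samples fragment pairs (weighted by pool multiplicity), joins them, and
#' keeps products that parse, canonicalize, and are absent from the training
#' set and from earlier positions in the batch. Deterministic given the
#' state and `seed`. If the pool cannot produce `n` novel molecules within
#' an attempt budget of `50 * n` assemblies, fewer are returned with a
#' warning.
#'
#' @param state a `fragment_generator`.
#' @param n number of molecules requested.
#' @param seed integer seed for this batch.
#' @return character vector of at most `n` canonical SMILES.
#' @export
generate_batch <- function(state, n, seed = 1L) {
  stopifnot(inherits(state, "fragment_generator"))
  if (n < 0) stop("'n' must be non-negative")
  if (n == 0L) return(character(0))
  if (length(state$pool) == 0L) stop("empty fragment pool")
  set.seed(as.integer((as.numeric(state$seed) * 1009 + as.numeric(seed)) %%
                        2147483647))
  out <- character(0)
  known <- state$training
  attempts <- 0L
  budget <- 50L * n
  w <- state$multiplicity
  while (length(out) < n && attempts < budget) {
    chunk <- min(max(2L * (n - length(out)), 50L), budget - attempts)
    ia <- sample.int(length(state$pool), chunk, replace = TRUE, prob = w)
    ib <- sample.int(length(state$pool), chunk, replace = TRUE, prob = w)
    joined <- lapply(seq_len(chunk), function(k) {
      join_fragments(state$pool[[ia[k]]], state$pool[[ib[k]]])
    })
    smi <- sdf_to_canonical(joined)
    attempts <- attempts + chunk
    smi <- smi[!is.na(smi)]
    smi <- smi[!grepl(".", smi, fixed = TRUE)]
    smi <- smi[!(smi %in% known) & !duplicated(smi)]
    if (length(smi) > 0L) {
      take <- utils::head(smi, n - length(out))
      out <- c(out, take)
      known <- c(known, take)
    }
  }
  if (length(out) < n) {
    warning(sprintf("generator produced %d of %d requested molecules within the attempt budget",
                    length(out), n), call. = FALSE)
  }
  out
}
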