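# Molecular featurization for the QSAR members. Three feature families are
# provided, mirroring the roles of the descriptor sets used with each model
# family: circular fingerprints, path-based fingerprint bits, and a
# substructure-key descriptor vector (physicochemical properties + MACCS
# keys, a documented stand-in for substructure-frequency descriptors).

FEATURIZATIONS <- c("circular_fp", "path_fp_bits", "descriptor_vector")

# Physicochemical property block computed in-process through OpenBabel.
physchem_descriptors <- function(smiles) {
  obs <- ChemmineOB::forEachMol("SMILES",
                                paste(paste(smiles, seq_along(smiles)),
                                      collapse = "\n"),
                                identity)
  if (length(obs) != length(smiles)) {
    stop("descriptor computation failed: could not parse all molecules")
  }
  props <- ChemmineOB::prop_OB(obs)
  cols <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  m <- as.matrix(props[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- smiles
  m
}

#' Compute the model feature families for a set of molecules
#'
#' @param smiles character vector of (canonical) SMILES.
#' @param families subset of `c("circular_fp", "path_fp_bits",
#'   "descriptor_vector")`; all three by default.
#' @param circular_bits folded length of the modeling circular fingerprint
#'   (default 256; the similarity filter uses its own 2048-bit fingerprint).
#' @param path_bits folded length of the modeling path fingerprint
#'   (default 256).
#' @return named list of numeric matrices, one per requested family.
#' @export
featurize_set <- function(smiles, families = FEATURIZATIONS,
                          circular_bits = 256L, path_bits = 256L) {
  families <- match.arg(families, FEATURIZATIONS, several.ok = TRUE)
  out <- list()
  if ("circular_fp" %in% families) {
    out$circular_fp <- morgan_fp(smiles, radius = 2L, n_bits = circular_bits)
  }
  if ("path_fp_bits" %in% families) {
    out$path_fp_bits <- path_fp(smiles, n_bits = path_bits)
  }
  if ("descriptor_vector" %in% families) {
    out$descriptor_vector <- cbind(physchem_descriptors(smiles),
                                   maccs_fp(smiles))
  }
  out
}

# Column-bind the feature families a member spec asks for.
member_features <- function(feats, families) {
  missing <- setdiff(families, names(feats))
  if (length(missing) > 0L) {
    stop("feature families not computed: ", paste(missing, collapse = ", "))
  }
  do.call(cbind, unname(feats[families]))
}
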