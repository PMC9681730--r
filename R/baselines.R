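# Classical feature constructions for the SVM / random-forest baselines:
# auto cross-covariance protein descriptors, MACCS keys, Morgan-class
# circular fingerprints, and the concatenated ternary-complex vector.

# First three Sandberg z-scales (z1 lipophilicity, z2 steric bulk,
# z3 polarity) for the 20 standard amino acids.
Z_SCALES <- matrix(c(
   0.24, -2.32,  0.60,   # A
   3.52,  2.50, -3.50,   # R
   3.05,  1.62,  1.04,   # N
   3.98,  0.93,  1.93,   # D
   0.84, -1.67,  3.71,   # C
   1.75,  0.50, -1.44,   # Q
   3.11,  0.26, -0.11,   # E
   2.05, -4.06,  0.36,   # G
   2.47,  1.95,  0.26,   # H
  -3.89, -1.73, -1.71,   # I
  -4.28, -1.30, -1.49,   # L
   2.29,  0.89, -2.49,   # K
  -2.85, -0.22,  0.47,   # M
  -4.22,  1.94,  1.06,   # F
  -1.66,  0.27,  1.84,   # P
   2.39, -1.07,  1.15,   # S
   0.75, -2.18, -1.12,   # T
  -4.36,  3.94,  0.59,   # W
  -2.54,  2.44,  0.43,   # Y
  -2.59, -2.64, -1.54),  # V
  nrow = 20, byrow = TRUE,
  dimnames = list(c("A","R","N","D","C","Q","E","G","H","I",
                    "L","K","M","F","P","S","T","W","Y","V"),
                  c("z1", "z2", "z3")))

ACC_LAGS <- c(1L, 2L)

#' Auto cross-covariance descriptor of a protein sequence
#'
#' Each residue is mapped to three physicochemical property scales (the
#' first three z-scales); for lags 1 and 2 and every ordered property pair
#' (p, q) the component is the lagged cross-covariance
#' (1/(n - lag)) * sum_i (x[p, i] - mean_p) (x[q, i + lag] - mean_q),
#' ordered lexicographically by (lag, p, q), giving 18 values. Unknown
#' residues take the mean of each scale (zero contribution after
#' centering).
#'
#' @param sequence amino-acid string (one-letter codes).
#' @param scales residue-by-property matrix of physicochemical scales;
#'   defaults to the first three z-scales.
#' @return numeric vector of length 18 with provenance attribute `"acc"`.
#' @export
acc_descriptor <- function(sequence, scales = Z_SCALES) {
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n < 3L) stop("sequence must have at least 3 residues, got ", n)
  idx <- match(aa, rownames(scales))
  X <- scales[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  if (anyNA(idx))
    X[is.na(idx), ] <- matrix(colMeans(scales), sum(is.na(idx)),
                              ncol(scales), byrow = TRUE)
  Xc <- sweep(X, 2, colMeans(X))
  out <- numeric(0)
  for (lag in ACC_LAGS) {
    head_ <- Xc[seq_len(n - lag), , drop = FALSE]
    tail_ <- Xc[(lag + 1L):n, , drop = FALSE]
    cc <- crossprod(head_, tail_) / (n - lag)   # cc[p, q]
    out <- c(out, as.vector(t(cc)))             # lexicographic (p, q)
  }
  structure(out, provenance = "acc")
}

ob_mols <- function(mol) {
  if (inherits(mol, "molecule_record")) {
    tmp <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp))
    write_mol2(mol, tmp)
    ChemmineOB::forEachMol("MOL2",
                           paste0(paste(readLines(tmp), collapse = "\n"), "\n"),
                           identity)
  } else if (is.character(mol) && length(mol) == 1L) {
    ChemmineOB::forEachMol("SMI", paste0(mol, "\n"), identity)
  } else stop("mol must be a molecule_record or a SMILES string")
}

#' MACCS-key fingerprint (166 bits)
#'
#' Standard 166-key substructure fingerprint computed through OpenBabel's
#' MACCS pattern set.
#' @param mol a `molecule_record` or a SMILES string.
#' @return binary numeric vector of length 166 with provenance `"maccs"`.
#' @export
maccs_fp <- function(mol) {
  bits <- tryCatch(ChemmineOB::fingerprint_OB(ob_mols(mol), "MACCS"),
                   error = function(e)
                     stop("MACCS featurization failed for '",
                          if (is.character(mol)) mol else mol$name, "': ",
                          conditionMessage(e)))
  # OpenBabel pads the key set to a 256-bit word vector; keys are 1..166
  structure(as.numeric(bits[seq_len(166L)]), provenance = "maccs")
}

#' Morgan (circular, ECFP-class) fingerprint
#'
#' Radius-2 extended-connectivity fingerprint computed through OpenBabel
#' (ECFP4), folded by bitwise OR to `nbits`.
#' @param mol a `molecule_record` or a SMILES string.
#' @param radius circular radius; 2 (ECFP4) and 3 (ECFP6) are supported.
#' @param nbits folded length, default 1024.
#' @return binary numeric vector of length `nbits` with provenance
#'   `"morgan"`.
#' @export
morgan_fp <- function(mol, radius = 2L, nbits = 1024L) {
  fpname <- switch(as.character(radius), "1" = "ECFP2", "2" = "ECFP4",
                   "3" = "ECFP6", stop("unsupported Morgan radius ", radius))
  bits <- tryCatch(ChemmineOB::fingerprint_OB(ob_mols(mol), fpname),
                   error = function(e)
                     stop("Morgan featurization failed for '",
                          if (is.character(mol)) mol else mol$name, "': ",
                          conditionMessage(e)))
  bits <- as.numeric(bits)
  stopifnot(length(bits) %% nbits == 0L)
  folded <- rowSums(matrix(bits, nrow = nbits)) > 0
  structure(as.numeric(folded), provenance = "morgan")
}

#' Concatenated ternary-complex feature vector
#'
#' POI ACC descriptor, E3-ligase ACC descriptor, then the whole-molecule
#' fingerprint, in that order: length 202 with MACCS keys, 1060 with Morgan
#' fingerprints.
#' @param poi_seq,e3_seq amino-acid sequences of the POI and the E3 ligase.
#' @param protac the PROTAC molecule (`molecule_record` or SMILES).
#' @param fp_kind `"maccs"` or `"morgan"`.
#' @return numeric vector with provenance `"ternary_concat"`.
#' @export
ternary_features <- function(poi_seq, e3_seq, protac,
                             fp_kind = c("maccs", "morgan")) {
  fp_kind <- match.arg(fp_kind)
  fp <- if (fp_kind == "maccs") maccs_fp(protac) else morgan_fp(protac)
  structure(c(acc_descriptor(poi_seq), acc_descriptor(e3_seq), fp),
            provenance = "ternary_concat")
}

#' Feature matrix for a set of labeled records
#'
#' Builds one [ternary_features()] row per record; POI and E3 sequences are
#' looked up in `sequences` by `poi_name` / `e3_name`.
#' @param records labeled manifest data.frame.
#' @param sequences named character vector of protein sequences.
#' @param fp_kind `"maccs"` or `"morgan"`.
#' @param protac_smiles_fun function(record row) returning the assembled
#'   PROTAC SMILES; the default concatenates warhead, linker and E3-ligand
#'   SMILES fragments.
#' @return list with `X` (matrix) and `y` (factor of labels).
#' @export
ternary_feature_matrix <- function(records, sequences,
                                   fp_kind = c("maccs", "morgan"),
                                   protac_smiles_fun = default_protac_smiles) {
  fp_kind <- match.arg(fp_kind)
  rows <- lapply(seq_len(nrow(records)), function(k) {
    r <- records[k, ]
    ternary_features(sequences[[r$poi_name]], sequences[[r$e3_name]],
                     protac_smiles_fun(r), fp_kind)
  })
  X <- do.call(rbind, rows)
  colnames(X) <- paste0(fp_kind_header(fp_kind), seq_len(ncol(X)))
  list(X = X, y = factor(records$label, levels = c("inactive", "active")))
}

fp_kind_header <- function(fp_kind)
  c(rep("acc_poi_", 0L), paste0("ternary_", fp_kind, "_"))

default_protac_smiles <- function(r) {
  paste0(r$warhead, ".", r$linker_smiles, ".", r$e3_ligand)
}

#' Write a feature matrix as CSV with a provenance header row
#' @param features list from [ternary_feature_matrix()].
#' @param path CSV path.
#' @param provenance provenance string recorded as a comment line.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path, provenance = "ternary_concat") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", provenance), con)
  utils::write.csv(data.frame(label = features$y, features$X,
                              check.names = FALSE), con, row.names = FALSE)
  invisible(path)
}
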