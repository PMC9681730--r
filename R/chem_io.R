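# Structure I/O: PDB / Mol2 / SDF / SMILES readers, pocket extraction, Mol2 writer.

MOL2_BOND_LABELS <- c("1" = "single", "2" = "double", "3" = "triple",
                      "ar" = "aromatic", "am" = "amide")
BOND_LABELS <- unname(MOL2_BOND_LABELS)
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")
ION_RESIDUES <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI",
                  "CO", "CD", "IOD", "BR", "SO4", "PO4")

#' Construct a molecule record
#'
#' A molecule record is the parsed, role-tagged form of a structure file:
#' an ordered atom table plus typed bonds. It is the ground truth from which
#' graphs are built.
#'
#' @param name molecule name.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `residue_name`, `residue_id`, `chain_id`, `role`
#'   (one of `"protein"`, `"ligand"`, `"other"`).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `label` (one of single, double, triple, aromatic, amide).
#' @return an object of class `molecule_record`.
#' @export
molecule_record <- function(name, atoms, bonds) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  if (nrow(atoms) == 0L) stop("molecule '", name, "' has no atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("molecule '", name, "' has non-finite coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element symbol in '", name, "'")
  if (nrow(bonds) > 0L) {
    if (any(bonds$i < 1L | bonds$j < 1L | bonds$i > nrow(atoms) |
            bonds$j > nrow(atoms)))
      stop("bond indices out of range in '", name, "'")
    if (any(bonds$i == bonds$j)) stop("self-bond in '", name, "'")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond in '", name, "'")
    bad <- setdiff(unique(bonds$label), BOND_LABELS)
    if (length(bad))
      stop("unknown bond label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, atoms = atoms, bonds = bonds),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record>", x$name, "-", nrow(x$atoms), "atoms,",
      nrow(x$bonds), "bonds\n")
  tab <- table(x$atoms$role)
  cat("  roles:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

element_from_sybyl <- function(elety) {
  # "C.ar" -> "C", "N.am" -> "N", "Cl" -> "Cl", "Du" stays as-is
  sub("\\..*$", "", elety)
}

is_heavy <- function(element) toupper(element) != "H"

atom_role <- function(residue_name, record_type = NULL) {
  rn <- toupper(residue_name)
  role <- rep("protein", length(rn))
  if (!is.null(record_type)) role[record_type == "HETATM"] <- "ligand"
  role[startsWith(rn, "LIG") | rn %in% c("UNL", "UNK1")] <- "ligand"
  role[rn %in% c(WATER_RESIDUES, ION_RESIDUES)] <- "other"
  role
}

#' Read a protein or small-molecule structure file
#'
#' Parses a PDB or Mol2 file into a [molecule_record()] with role-tagged
#' atoms. Atom order is preserved from the file; Mol2 bond types
#' (1/2/3/ar/am) are normalized to single/double/triple/aromatic/amide.
#' Hydrogens are retained in the record; they are filtered downstream
#' (distance tests and graphs use heavy atoms only). Waters and common ions
#' are tagged `"other"` and dropped from pockets; alternate locations other
#' than '' or 'A' are dropped at parse time.
#'
#' @param path path to the structure file.
#' @param format `"pdb"` or `"mol2"`; inferred from the file extension when
#'   missing.
#' @return a `molecule_record`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", mol2 = "mol2",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (format == "mol2") read_mol2_structure(path) else read_pdb_structure(path)
}

read_mol2_structure <- function(path) {
  m <- tryCatch(suppressWarnings(bio3d::read.mol2(path)),
                error = function(e) stop("failed to parse Mol2 file ", path,
                                         ": ", conditionMessage(e)))
  if (is.null(m$atom) || nrow(m$atom) == 0L)
    stop("Mol2 file ", path, " contains no atoms")
  at <- m$atom
  element <- element_from_sybyl(at$elety)
  atoms <- data.frame(
    element = element,
    x = at$x, y = at$y, z = at$z,
    residue_name = as.character(at$resid),
    residue_id = as.integer(at$resno),
    chain_id = "A",
    role = atom_role(as.character(at$resid)),
    stringsAsFactors = FALSE)
  bonds <- data.frame(i = integer(0), j = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (!is.null(m$bond) && nrow(m$bond) > 0L) {
    type <- as.character(m$bond$type)
    bad <- setdiff(unique(type), names(MOL2_BOND_LABELS))
    if (length(bad))
      stop("unknown Mol2 bond label(s) in ", path, ": ",
           paste(bad, collapse = ", "))
    bonds <- data.frame(i = as.integer(m$bond$origin),
                        j = as.integer(m$bond$target),
                        label = unname(MOL2_BOND_LABELS[type]),
                        stringsAsFactors = FALSE)
  }
  molecule_record(tools::file_path_sans_ext(basename(path)), atoms, bonds)
}

read_pdb_structure <- function(path) {
  p <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                error = function(e) stop("failed to parse PDB file ", path,
                                         ": ", conditionMessage(e)))
  at <- p$atom
  if (is.null(at) || nrow(at) == 0L) stop("PDB file ", path, " has no atoms")
  element <- at$elesy
  missing_el <- is.na(element) | !nzchar(element)
  # fall back to the first letter of the atom name
  element[missing_el] <- sub("^[0-9]*", "", at$elety[missing_el])
  element[missing_el] <- substr(element[missing_el], 1, 1)
  atoms <- data.frame(
    element = element,
    x = at$x, y = at$y, z = at$z,
    residue_name = as.character(at$resid),
    residue_id = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain) | !nzchar(at$chain), "A",
                      as.character(at$chain)),
    role = atom_role(as.character(at$resid), at$type),
    stringsAsFactors = FALSE)
  # PDB carries no bond table (CONECT is not trusted for topology);
  # graphs are built from Mol2 records.
  bonds <- data.frame(i = integer(0), j = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  molecule_record(basename(path), atoms, bonds)
}

#' Read a small molecule from a file or a SMILES string
#'
#' Accepts a Mol2/SDF/PDB file path or a SMILES string. SMILES and SDF
#' inputs are converted to Mol2 through OpenBabel so that aromatic bonds are
#' perceived from aromaticity flags. The C–N single bond of any C(=O)N group
#' is labeled `amide`, taking precedence over a plain single-bond label.
#'
#' @param source a file path or a SMILES string.
#' @param name molecule name used in error messages.
#' @return a `molecule_record` whose atoms are all tagged `"ligand"`.
#' @export
read_small_molecule <- function(source, name = "mol") {
  stopifnot(is.character(source), length(source) == 1L)
  if (file.exists(source) && !identical(source, "")) {
    ext <- tolower(tools::file_ext(source))
    mol <- switch(ext,
      mol2 = read_structure(source, "mol2"),
      pdb  = read_structure(source, "pdb"),
      sdf  = ,
      mol  = mol2_from_text(ChemmineOB::convertFormat(
               "SDF", "MOL2", paste0(paste(readLines(source), collapse = "\n"),
                                     "\n")), source),
      stop("unsupported small-molecule file extension '", ext, "'"))
  } else {
    txt <- tryCatch(
      ChemmineOB::convertFormat("SMI", "MOL2", paste0(source, " ", name, "\n")),
      error = function(e) "")
    if (!nzchar(txt) || !grepl("@<TRIPOS>ATOM", txt, fixed = TRUE))
      stop("invalid SMILES string: '", source, "'")
    mol <- mol2_from_text(txt, name)
    if (nrow(mol$atoms) == 0L) stop("invalid SMILES string: '", source, "'")
  }
  mol$atoms$role <- "ligand"
  perceive_amide(mol)
}

mol2_from_text <- function(txt, name) {
  tmp <- tempfile(fileext = ".mol2")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  mol <- read_mol2_structure(tmp)
  mol$name <- name
  mol
}

#' Relabel amide C-N bonds
#'
#' Any single C-N bond whose carbon also carries a double bond to oxygen is
#' relabeled `amide`. Bonds already labeled aromatic/double/triple are left
#' untouched.
#' @param mol a `molecule_record`.
#' @return the record with amide bonds labeled.
#' @export
perceive_amide <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(mol)
  el <- mol$atoms$element
  # carbons with a C=O double bond
  dbl <- b[b$label == "double", , drop = FALSE]
  carbonyl_c <- unique(c(
    dbl$i[el[dbl$i] == "C" & el[dbl$j] == "O"],
    dbl$j[el[dbl$j] == "C" & el[dbl$i] == "O"]))
  if (length(carbonyl_c)) {
    single <- which(b$label == "single")
    for (k in single) {
      i <- b$i[k]; j <- b$j[k]
      cn <- (el[i] == "C" && el[j] == "N" && i %in% carbonyl_c) ||
            (el[j] == "C" && el[i] == "N" && j %in% carbonyl_c)
      if (cn) b$label[k] <- "amide"
    }
  }
  mol$bonds <- b
  mol
}

#' Extract the ligand-binding pocket from a protein structure
#'
#' A residue is selected iff the minimum heavy-atom distance between any of
#' its atoms and any ligand heavy atom is at most `radius` (closed boundary).
#' All heavy atoms of every selected residue are returned; ligand atoms and
#' hydrogens are never included.
#'
#' @param protein_atoms data.frame of protein atoms (columns as in
#'   [molecule_record()] atoms).
#' @param ligand_atoms data.frame of ligand atoms.
#' @param radius selection radius in Angstrom; default 5.0.
#' @param bonds optional bond table whose indices refer to the row numbers
#'   of `protein_atoms`; the induced, reindexed subset is carried into the
#'   selection so the pocket can be turned into a graph.
#' @param structure_id identifier recorded in the selection.
#' @return an object of class `pocket_selection` with fields `structure_id`,
#'   `radius`, `residues` (chain_id, residue_id keys), `atoms`, `bonds`.
#' @export
extract_pocket <- function(protein_atoms, ligand_atoms, radius = 5.0,
                           bonds = NULL, structure_id = "") {
  if (nrow(protein_atoms) == 0L) stop("no protein atoms supplied")
  if (nrow(ligand_atoms) == 0L) stop("no ligand atoms supplied")
  stopifnot(radius > 0)
  ph <- which(is_heavy(protein_atoms$element))
  lig <- ligand_atoms[is_heavy(ligand_atoms$element), , drop = FALSE]
  if (length(ph) == 0L) stop("protein has no heavy atoms")
  if (nrow(lig) == 0L) stop("ligand has no heavy atoms")

  pxyz <- as.matrix(protein_atoms[ph, c("x", "y", "z")])
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  # min distance from each protein heavy atom to the ligand
  d2 <- vapply(seq_len(nrow(pxyz)), function(k) {
    min(colSums((t(lxyz) - pxyz[k, ])^2))
  }, numeric(1))
  within <- d2 <= radius^2

  key_all <- paste(protein_atoms$chain_id, protein_atoms$residue_id, sep = "|")
  sel_keys <- unique(key_all[ph][within])
  if (length(sel_keys) == 0L)
    stop("empty pocket: no residue within ", radius,
         " Angstrom of the ligand (mis-paired structure/ligand?)")

  keep <- which(key_all %in% sel_keys & is_heavy(protein_atoms$element))
  atoms <- protein_atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL

  pb <- data.frame(i = integer(0), j = integer(0), label = character(0),
                   stringsAsFactors = FALSE)
  if (!is.null(bonds) && nrow(bonds) > 0L) {
    map <- integer(nrow(protein_atoms))
    map[keep] <- seq_along(keep)
    sel <- bonds$i %in% keep & bonds$j %in% keep
    if (any(sel))
      pb <- data.frame(i = map[bonds$i[sel]], j = map[bonds$j[sel]],
                       label = bonds$label[sel], stringsAsFactors = FALSE)
  }
  res <- unique(atoms[, c("chain_id", "residue_id")])
  rownames(res) <- NULL
  structure(list(structure_id = structure_id, radius = radius,
                 residues = res, atoms = atoms, bonds = pb),
            class = "pocket_selection")
}

#' @export
print.pocket_selection <- function(x, ...) {
  cat("<pocket_selection>", x$structure_id, "- radius", x$radius, "A:",
      nrow(x$residues), "residues,", nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' Extract the pocket from a parsed complex
#'
#' Convenience wrapper splitting a complex `molecule_record` by atom role
#' and carrying its bond table into the pocket selection.
#' @param mol a `molecule_record` holding both protein and ligand atoms.
#' @param radius selection radius in Angstrom.
#' @return a `pocket_selection`.
#' @export
pocket_from_structure <- function(mol, radius = 5.0) {
  prot <- mol$atoms$role == "protein"
  lig <- mol$atoms$role == "ligand"
  if (!any(lig)) stop("no ligand atoms in '", mol$name, "'")
  b <- mol$bonds
  if (nrow(b) > 0L) {
    # reindex bonds onto the protein-only atom table
    map <- integer(nrow(mol$atoms))
    map[prot] <- seq_len(sum(prot))
    keep <- prot[b$i] & prot[b$j]
    b <- data.frame(i = map[b$i[keep]], j = map[b$j[keep]],
                    label = b$label[keep], stringsAsFactors = FALSE)
  }
  pa <- mol$atoms[prot, , drop = FALSE]; rownames(pa) <- NULL
  extract_pocket(pa, mol$atoms[lig, , drop = FALSE], radius = radius,
                 bonds = b, structure_id = mol$name)
}

SYBYL_FROM_LABEL <- c(single = "1", double = "2", triple = "3",
                      aromatic = "ar", amide = "am")

#' Write a molecule or pocket selection as Mol2
#'
#' Emits a normalized TRIPOS Mol2 file (ATOM and BOND blocks) for
#' inspection and round-tripping of extracted pockets.
#' @param x a `molecule_record` or `pocket_selection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mol2 <- function(x, path) {
  if (inherits(x, "pocket_selection")) {
    atoms <- x$atoms; bonds <- x$bonds; name <- x$structure_id
  } else {
    atoms <- x$atoms; bonds <- x$bonds; name <- x$name
  }
  n <- nrow(atoms)
  lines <- c("@<TRIPOS>MOLECULE", name,
             sprintf(" %d %d 0 0 0", n, nrow(bonds)),
             "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM")
  resnm <- if (is.null(atoms$residue_name)) rep("UNL", n) else atoms$residue_name
  resno <- if (is.null(atoms$residue_id)) rep(1L, n) else atoms$residue_id
  lines <- c(lines, sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s %4d %-8s %9.4f",
                            seq_len(n), atoms$element, atoms$x, atoms$y,
                            atoms$z, atoms$element, resno,
                            paste0(resnm, resno), 0))
  lines <- c(lines, "@<TRIPOS>BOND")
  if (nrow(bonds) > 0L)
    lines <- c(lines, sprintf("%6d %5d %5d %4s", seq_len(nrow(bonds)),
                              bonds$i, bonds$j, SYBYL_FROM_LABEL[bonds$label]))
  writeLines(lines, path)
  invisible(path)
}
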