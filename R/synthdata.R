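# Synthetic structure and dataset generator: pocket fixtures with a bound
# ligand, warhead/E3-ligand scaffolds, alkyl and PEG linker series, and
# binary labels planted by a configurable rule so that every stage of the
# pipeline (and the trained network) can be exercised without any download.

# Rigid heavy-atom residue templates: local coordinates with ~1.4-1.8 A
# bonds. SEC carries selenium, which lands in the "other" pocket code.
residue_templates <- function() {
  bb <- function(extra_el, extra_xyz, extra_bonds) {
    list(elements = c("N", "C", "C", "O", extra_el),
         xyz = rbind(c(0, 0, 0), c(1.45, 0, 0), c(2.15, 1.25, 0),
                     c(3.35, 1.25, 0.2), extra_xyz),
         bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 2), extra_bonds))
  }
  list(
    GLY = bb(character(0), NULL, NULL),
    SER = bb(c("C", "O"), rbind(c(1.95, -1.35, 0.3), c(1.25, -2.45, -0.2)),
             rbind(c(2, 5, 1), c(5, 6, 1))),
    CYS = bb(c("C", "S"), rbind(c(1.95, -1.35, 0.3), c(2.9, -2.6, -0.2)),
             rbind(c(2, 5, 1), c(5, 6, 1))),
    ASN = bb(c("C", "C", "O", "N"),
             rbind(c(1.95, -1.35, 0.3), c(1.2, -2.6, 0), c(0.0, -2.7, 0.3),
                   c(1.85, -3.7, -0.4)),
             rbind(c(2, 5, 1), c(5, 6, 1), c(6, 7, 2), c(6, 8, 5))),
    THR = bb(c("C", "O", "C"),
             rbind(c(1.95, -1.35, 0.3), c(1.2, -2.45, -0.25),
                   c(3.4, -1.65, 0.6)),
             rbind(c(2, 5, 1), c(5, 6, 1), c(5, 7, 1))),
    SEC = bb(c("C", "Se"), rbind(c(1.95, -1.35, 0.3), c(3.0, -2.65, -0.2)),
             rbind(c(2, 5, 1), c(5, 6, 1))))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed: uniform over O(3) is fine here
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

#' Generate a synthetic pocket fixture with a bound ligand
#'
#' Places rigid residue templates on random orientations around a small
#' ligand: at least one residue has an atom within the 5-Angstrom shell of
#' a ligand heavy atom and at least one residue lies well outside it, so
#' pocket extraction is exercised non-trivially. Element composition is
#' C/N/O/S with an optional planted selenium ("other"-code) residue. Writes
#' a complex Mol2 (with bonds; the graph source) and a PDB of the same
#' atoms.
#'
#' @param path_prefix output prefix; `<prefix>.mol2` and `<prefix>.pdb` are
#'   written.
#' @param seed integer RNG seed; the same seed reproduces identical files.
#' @param n_residues number of residues (>= 2).
#' @param ligand_smiles the bound ligand.
#' @param plant_selenium include one selenocysteine-like residue inside the
#'   shell.
#' @param n_inside how many residues are guaranteed inside the shell.
#' @return invisible list with the written paths and a manifest of residue
#'   placements (template, inside/outside, min distance to ligand).
#' @export
make_pocket <- function(path_prefix, seed = 1L, n_residues = 6L,
                        ligand_smiles = "c1ccc(CC(=O)N)cc1",
                        plant_selenium = FALSE, n_inside = NULL) {
  stopifnot(n_residues >= 2L)
  set.seed(seed)
  if (is.null(n_inside)) n_inside <- max(1L, ceiling(n_residues / 2))
  stopifnot(n_inside >= 1L, n_inside < n_residues)

  lig <- read_small_molecule(ligand_smiles, "LIG")
  lig$atoms[, c("x", "y", "z")] <-
    sweep(lig$atoms[, c("x", "y", "z")], 2,
          colMeans(lig$atoms[, c("x", "y", "z")]))
  lxyz <- as.matrix(lig$atoms[, c("x", "y", "z")])

  tmpl <- residue_templates()
  pick <- sample(setdiff(names(tmpl), "SEC"), n_residues, replace = TRUE)
  if (plant_selenium) pick[sample.int(n_inside, 1L)] <- "SEC"

  atoms <- NULL; bonds <- NULL; manifest <- NULL
  res_id <- 0L
  for (k in seq_len(n_residues)) {
    res_id <- res_id + 1L
    tm <- tmpl[[pick[k]]]
    inside <- k <= n_inside
    repeat {
      R <- random_rotation()
      local <- tm$xyz %*% t(R)
      anchor_lig <- lxyz[sample.int(nrow(lxyz), 1L), ]
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      d <- if (inside) stats::runif(1, 3.2, 4.6) else stats::runif(1, 8, 13)
      base <- if (inside) anchor_lig else c(0, 0, 0)
      shift <- base + dir * d - local[sample.int(nrow(local), 1L), ]
      xyz <- sweep(local, 2, -shift)
      dmin <- sqrt(min(outer(rowSums(xyz^2), rowSums(lxyz^2), "+") -
                         2 * xyz %*% t(lxyz)))
      if (inside && dmin <= 4.8 && dmin >= 1.8) break
      if (!inside && dmin >= 6.0) break
    }
    off <- if (is.null(atoms)) 0L else nrow(atoms)
    atoms <- rbind(atoms, data.frame(
      element = tm$elements, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      residue_name = pick[k], residue_id = res_id, chain_id = "A",
      role = "protein", stringsAsFactors = FALSE))
    bonds <- rbind(bonds, data.frame(
      i = tm$bonds[, 1] + off, j = tm$bonds[, 2] + off,
      label = BOND_LABELS[tm$bonds[, 3]], stringsAsFactors = FALSE))
    manifest <- rbind(manifest, data.frame(
      residue_id = res_id, template = pick[k], inside = inside,
      min_dist = dmin, stringsAsFactors = FALSE))
  }

  n_prot <- nrow(atoms)
  lig_atoms <- lig$atoms
  lig_atoms$residue_name <- "LIG"
  lig_atoms$residue_id <- res_id + 1L
  lig_atoms$chain_id <- "A"
  lig_atoms$role <- "ligand"
  atoms <- rbind(atoms, lig_atoms)
  bonds <- rbind(bonds, data.frame(i = lig$bonds$i + n_prot,
                                   j = lig$bonds$j + n_prot,
                                   label = lig$bonds$label,
                                   stringsAsFactors = FALSE))
  mol <- molecule_record(basename(path_prefix), atoms, bonds)
  mol2_path <- paste0(path_prefix, ".mol2")
  pdb_path <- paste0(path_prefix, ".pdb")
  write_mol2(mol, mol2_path)
  write_pdb(mol, pdb_path)
  invisible(list(mol2 = mol2_path, pdb = pdb_path, manifest = manifest,
                 record = mol))
}

#' Write a minimal PDB file (ATOM for protein, HETATM for the ligand)
#' @param mol a `molecule_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(mol, path) {
  a <- mol$atoms
  rec <- ifelse(a$role == "protein", "ATOM  ", "HETATM")
  resname <- substr(ifelse(a$role == "ligand", "LIG", a$residue_name), 1, 3)
  lines <- sprintf(
    "%s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    rec, seq_len(nrow(a)),
    substr(paste0(a$element, seq_len(nrow(a)) %% 10), 1, 4),
    resname, a$chain_id, a$residue_id, a$x, a$y, a$z, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Linker SMILES of a given family and length
#'
#' Alkyl linkers are plain carbon chains `"C" * length`; PEG linkers repeat
#' the `"CCO"` ethylene-glycol unit.
#' @param family `"alkyl"` or `"PEG"`.
#' @param length chain length: carbons for alkyl, units for PEG.
#' @return a SMILES string with attribute `heavy_atoms`.
#' @export
make_linker <- function(family = c("alkyl", "PEG"), length) {
  family <- match.arg(family)
  stopifnot(length >= 1L)
  smi <- if (family == "alkyl") strrep("C", length) else strrep("CCO", length)
  structure(smi, heavy_atoms = nchar(smi))
}

# small drug-like scaffold pool for warheads / E3 ligands
scaffold_pool <- function() c(
  "c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "c1ccc(Cl)cc1", "c1ccc(F)cc1",
  "c1ccc(O)cc1", "c1ccc(N)cc1", "CC(=O)Nc1ccccc1", "c1ccc(C#N)cc1",
  "c1ccsc1", "c1cnc2[nH]ccc2c1", "OC(=O)c1ccccc1", "c1ccc(CN)cc1",
  "CC(C)c1ccccc1", "c1ccc(Br)cc1", "c1cc(C)ccc1O", "c1ccc(S(N)(=O)=O)cc1",
  "c1ccoc1", "CN1CCNCC1", "C1CCNCC1")

#' Synthetic dataset specification
#'
#' @param n_records number of degradation records.
#' @param seed master RNG seed.
#' @param active_rule the planted label rule: `"linker_band"` (active iff
#'   the linker has 6..12 heavy atoms — a medium-length-linker rule),
#'   `"pocket_match"` (active iff the warhead scaffold is the one matched
#'   to the record's POI pocket) or `"mixed"` (both must hold).
#' @param linker_families subset of `c("alkyl", "PEG")`.
#' @param label_noise probability of flipping the rule's outcome;
#'   0 <= noise < 0.5.
#' @param pocket_residues integer range (length-2 vector) of residues per
#'   generated pocket.
#' @param n_pois,n_e3s numbers of distinct POI and E3 structures.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_records = 400L, seed = 1L,
                       active_rule = c("linker_band", "pocket_match",
                                       "mixed"),
                       linker_families = c("alkyl", "PEG"),
                       label_noise = 0, pocket_residues = c(4L, 7L),
                       n_pois = 6L, n_e3s = 2L) {
  active_rule <- match.arg(active_rule)
  stopifnot(label_noise >= 0, label_noise < 0.5,
            all(linker_families %in% c("alkyl", "PEG")),
            length(pocket_residues) == 2L, n_records >= 4L,
            n_pois >= 1L, n_e3s >= 1L)
  structure(list(n_records = as.integer(n_records), seed = as.integer(seed),
                 active_rule = active_rule,
                 linker_families = linker_families,
                 label_noise = label_noise,
                 pocket_residues = as.integer(pocket_residues),
                 n_pois = as.integer(n_pois), n_e3s = as.integer(n_e3s)),
            class = "synth_spec")
}

LINKER_BAND <- c(6L, 12L)

#' Generate a synthetic degradation dataset
#'
#' Writes a structure directory (one pocket Mol2+PDB per POI and per E3),
#' a manifest CSV in the dataset-module schema, and a ground-truth sidecar
#' JSON (rule, per-record predicate values and noise flips) used only by
#' tests. DC50/Dmax values are drawn consistently with the planted label so
#' that relabeling the manifest under the default cutoff scheme reproduces
#' the planted labels exactly.
#'
#' @param spec a [synth_spec()].
#' @param out_dir output directory (created).
#' @return invisible list with `manifest` (data.frame), `manifest_path`,
#'   `structures_dir`, `truth_path`.
#' @export
generate_dataset <- function(spec = synth_spec(), out_dir = tempfile("synth")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sdir <- file.path(out_dir, "structures")
  dir.create(sdir, showWarnings = FALSE)
  set.seed(spec$seed)

  pool <- scaffold_pool()
  # one scaffold declared "matched" per POI for the pocket_match rule
  poi_match <- sample.int(length(pool), spec$n_pois, replace = TRUE)

  pois <- sprintf("POI%d", seq_len(spec$n_pois))
  e3s <- sprintf("E3_%d", seq_len(spec$n_e3s))
  poi_files <- character(spec$n_pois)
  for (k in seq_len(spec$n_pois)) {
    nres <- sample(spec$pocket_residues[1]:spec$pocket_residues[2], 1L)
    make_pocket(file.path(sdir, pois[k]), seed = spec$seed + 100L + k,
                n_residues = nres, ligand_smiles = pool[poi_match[k]],
                plant_selenium = k == 1L)
    poi_files[k] <- file.path("structures", paste0(pois[k], ".mol2"))
  }
  e3_files <- character(spec$n_e3s)
  for (k in seq_len(spec$n_e3s)) {
    nres <- sample(spec$pocket_residues[1]:spec$pocket_residues[2], 1L)
    make_pocket(file.path(sdir, e3s[k]), seed = spec$seed + 200L + k,
                n_residues = nres,
                ligand_smiles = pool[(k %% length(pool)) + 1L])
    e3_files[k] <- file.path("structures", paste0(e3s[k], ".mol2"))
  }

  n <- spec$n_records
  poi_idx <- sample.int(spec$n_pois, n, replace = TRUE)
  e3_idx <- sample.int(spec$n_e3s, n, replace = TRUE)
  warhead_idx <- integer(n)
  fam <- sample(spec$linker_families, n, replace = TRUE)
  len <- integer(n)
  # sample linker lengths so that roughly half the records satisfy the band
  in_band <- stats::runif(n) < 0.5
  for (k in seq_len(n)) {
    if (fam[k] == "alkyl") {
      len[k] <- if (in_band[k]) sample(LINKER_BAND[1]:LINKER_BAND[2], 1L)
                else sample(c(1:(LINKER_BAND[1] - 1L),
                              (LINKER_BAND[2] + 1L):20L), 1L)
    } else {
      # PEG heavy atoms = 3 * units; band 6..12 <-> units 2..4
      len[k] <- if (in_band[k]) sample(2:4, 1L) else sample(c(1L, 5L, 6L), 1L)
    }
    warhead_idx[k] <- if (spec$active_rule == "linker_band")
      sample.int(length(pool), 1L)
    else if (stats::runif(1) < 0.5) poi_match[poi_idx[k]]
    else sample(setdiff(seq_along(pool), poi_match[poi_idx[k]]), 1L)
  }
  linker <- vapply(seq_len(n), function(k)
    as.character(make_linker(fam[k], len[k])), character(1))
  heavy <- nchar(linker)

  band_ok <- heavy >= LINKER_BAND[1] & heavy <= LINKER_BAND[2]
  match_ok <- warhead_idx == poi_match[poi_idx]
  predicate <- switch(spec$active_rule,
                      linker_band = band_ok,
                      pocket_match = match_ok,
                      mixed = band_ok & match_ok)
  flip <- stats::runif(n) < spec$label_noise
  active <- xor(predicate, flip)
  if (!any(active) || all(active))
    stop("infeasible spec: planted rule yields a single class")

  # DC50/Dmax consistent with the planted label under the default cutoffs
  dc50 <- ifelse(active, stats::runif(n, 1, 99),
                 ifelse(stats::runif(n) < 0.5, stats::runif(n, 150, 5000),
                        stats::runif(n, 1, 99)))
  dmax <- ifelse(active, stats::runif(n, 81, 99.9),
                 ifelse(dc50 < 100, stats::runif(n, 10, 79),
                        stats::runif(n, 10, 99.9)))

  manifest <- data.frame(
    record_id = sprintf("R%04d", seq_len(n)),
    poi_name = pois[poi_idx], e3_name = e3s[e3_idx],
    poi_structure = poi_files[poi_idx],
    poi_ligand = pool[poi_match[poi_idx]],
    e3_structure = e3_files[e3_idx],
    e3_ligand = pool[((e3_idx) %% length(pool)) + 1L],
    warhead = pool[warhead_idx],
    linker_smiles = linker,
    dc50_nM = round(dc50, 3), dmax_pct = round(dmax, 2),
    label = ifelse(active, "active", "inactive"),
    stringsAsFactors = FALSE)

  manifest_path <- file.path(out_dir, "manifest.csv")
  write_manifest(manifest, manifest_path)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(rule = spec$active_rule, linker_band = LINKER_BAND,
         label_noise = spec$label_noise,
         record_id = manifest$record_id, predicate = predicate,
         flipped = flip, linker_heavy_atoms = heavy),
    truth_path, auto_unbox = TRUE)
  invisible(list(manifest = manifest, manifest_path = manifest_path,
                 structures_dir = out_dir, truth_path = truth_path))
}
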