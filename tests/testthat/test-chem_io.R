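test_that("Mol2 files are transcribed atom-for-atom with normalized bonds", {
  path <- write_tiny_mol2(tempfile(fileext = ".mol2"))
  mol <- read_structure(path, "mol2")
  expect_s3_class(mol, "molecule_record")
  expect_equal(nrow(mol$atoms), 3L)
  expect_equal(mol$atoms$element, c("C", "C", "N"))
  expect_equal(mol$bonds$i, c(1L, 2L))
  expect_equal(mol$bonds$j, c(2L, 3L))
  expect_equal(mol$bonds$label, c("single", "amide"))
})

test_that("degenerate and malformed structure files raise errors", {
  empty <- tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "void", " 0 0 0 0 0", "SMALL",
               "NO_CHARGES", "", "@<TRIPOS>ATOM", "@<TRIPOS>BOND"), empty)
  expect_error(read_structure(empty, "mol2"), "no atoms|failed to parse")

  badbond <- tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "bad", " 2 1 0 0 0", "SMALL",
               "NO_CHARGES", "", "@<TRIPOS>ATOM",
               "  1 C1 0.0 0.0 0.0 C.3 1 UNL1 0.0",
               "  2 C2 1.5 0.0 0.0 C.3 1 UNL1 0.0",
               "@<TRIPOS>BOND", "  1 1 2 du"), badbond)
  expect_error(read_structure(badbond, "mol2"), "du")

  expect_error(read_structure(tempfile(), "pdb"), "not found")
})

test_that("SMILES parsing perceives valence, aromaticity and amide bonds", {
  ald <- read_small_molecule("CC=O")
  expect_equal(nrow(ald$atoms), 3L)
  expect_setequal(ald$bonds$label, c("single", "double"))

  ace <- read_small_molecule("CC(=O)NC")
  cn <- ace$bonds[(ace$atoms$element[ace$bonds$i] == "N" &
                     ace$atoms$element[ace$bonds$j] == "C") |
                    (ace$atoms$element[ace$bonds$i] == "C" &
                       ace$atoms$element[ace$bonds$j] == "N"), ]
  expect_true("amide" %in% cn$label)

  benz <- read_small_molecule("c1ccccc1")
  expect_equal(nrow(benz$atoms), 6L)
  expect_equal(benz$bonds$label, rep("aromatic", 6L))

  expect_error(read_small_molecule("not((a(smiles"), "not\\(\\(a\\(smiles")
})

test_that("amide perception relabels C(=O)N read from bond tables", {
  atoms <- data.frame(element = c("C", "C", "O", "N"),
                      x = c(0, 1.5, 2.2, 2.1), y = c(0, 0, 1, -1.2),
                      z = 0, residue_name = "UNL", residue_id = 1L,
                      chain_id = "A", role = "ligand",
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = c(1L, 2L, 2L), j = c(2L, 3L, 4L),
                      label = c("single", "double", "single"),
                      stringsAsFactors = FALSE)
  mol <- perceive_amide(molecule_record("m", atoms, bonds))
  expect_equal(mol$bonds$label, c("single", "double", "amide"))
})

test_that("pocket selection uses the closed 5 A boundary at residue level", {
  lig <- data.frame(element = "C", x = 0, y = 0, z = 0,
                    residue_name = "LIG", residue_id = 99L, chain_id = "A",
                    role = "ligand", stringsAsFactors = FALSE)
  prot <- data.frame(
    element = c("C", "C", "C", "C", "C", "C", "C", "C"),
    x = c(4.9, 5.1, 3.0, 20, 20, 20, 20, 20),
    y = c(0, 0, 0, 1, 2, 3, 4, 5), z = 0,
    residue_name = "RES",
    residue_id = c(1L, 2L, 3L, 3L, 3L, 3L, 3L, 3L),
    chain_id = "A", role = "protein", stringsAsFactors = FALSE)
  sel <- extract_pocket(prot, lig, radius = 5.0)
  # residue 1 at 4.9 in, residue 2 at 5.1 out, residue 3 pulled in whole
  expect_setequal(sel$residues$residue_id, c(1L, 3L))
  expect_equal(sum(sel$atoms$residue_id == 3L), 6L)

  at_bound <- prot[2, , drop = FALSE]; at_bound$x <- 5.0
  sel2 <- extract_pocket(rbind(prot, at_bound), lig, radius = 5.0)
  expect_true(2L %in% sel2$residues$residue_id)   # closed boundary

  far <- prot[prot$residue_id > 1L & prot$x > 10, , drop = FALSE]
  expect_error(extract_pocket(far, lig, radius = 5.0), "empty pocket")
})

test_that("pocket extraction matches the brute-force all-pairs oracle", {
  for (seed in 1:100) {
    st <- random_structure(seed)
    got <- tryCatch(extract_pocket(st$protein, st$ligand, radius = 5.0),
                    error = function(e) NULL)
    want <- oracle_pocket_residues(st$protein, st$ligand, 5.0)
    if (is.null(got)) {
      expect_length(want, 0L)
    } else {
      expect_equal(sort(paste(got$residues$chain_id, got$residues$residue_id,
                              sep = "|")), want,
                   info = paste("seed", seed))
      expect_true(all(toupper(got$atoms$element) != "H"))
    }
  }
})

test_that("pocket selection grows monotonically with radius", {
  for (seed in 1:20) {
    st <- random_structure(seed)
    radii <- c(4, 6, 9, 14)
    sels <- lapply(radii, function(r)
      tryCatch(paste(extract_pocket(st$protein, st$ligand, r)$residues$chain_id,
                     extract_pocket(st$protein, st$ligand, r)$residues$residue_id),
               error = function(e) character(0)))
    for (k in seq_len(length(radii) - 1L))
      expect_true(all(sels[[k]] %in% sels[[k + 1L]]))
  }
})

test_that("Mol2 writing round-trips atoms, elements and bonds", {
  pk <- make_pocket(tempfile("pk"), seed = 9, n_residues = 5)
  mol <- read_structure(pk$mol2)
  out <- tempfile(fileext = ".mol2")
  write_mol2(mol, out)
  back <- read_structure(out)
  expect_equal(nrow(back$atoms), nrow(mol$atoms))
  expect_equal(back$atoms$element, mol$atoms$element)
  expect_equal(sort(table(back$bonds$label)), sort(table(mol$bonds$label)))
})
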