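# Shared fixtures and independent brute-force oracles used across the suite.

# --- oracles -------------------------------------------------------------

# all-pairs residue selection oracle for pocket extraction
oracle_pocket_residues <- function(protein_atoms, ligand_atoms, radius) {
  ph <- protein_atoms[toupper(protein_atoms$element) != "H", , drop = FALSE]
  lh <- ligand_atoms[toupper(ligand_atoms$element) != "H", , drop = FALSE]
  keys <- character(0)
  for (i in seq_len(nrow(ph))) for (j in seq_len(nrow(lh))) {
    d <- sqrt((ph$x[i] - lh$x[j])^2 + (ph$y[i] - lh$y[j])^2 +
                (ph$z[i] - lh$z[j])^2)
    if (d <= radius)
      keys <- c(keys, paste(ph$chain_id[i], ph$residue_id[i], sep = "|"))
  }
  sort(unique(keys))
}

# O(n^2) pairwise-concordance AUROC oracle (ties count half)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == "active"]
  neg <- scores[labels != "active"]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# independent character-frequency ranking oracle for the encoding table
oracle_char_ranking <- function(corpus, k = 39L) {
  chars <- unlist(strsplit(corpus, "", fixed = TRUE))
  counts <- sapply(unique(chars), function(ch) sum(chars == ch))
  cp <- vapply(names(counts), utf8ToInt, integer(1))
  names(counts)[order(-counts, cp)][seq_len(k)]
}

# direct double-loop ACC oracle
oracle_acc <- function(sequence) {
  zs <- protacnet:::Z_SCALES
  aa <- strsplit(sequence, "")[[1]]
  X <- zs[aa, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  n <- nrow(X)
  out <- numeric(0)
  for (lag in c(1, 2)) for (p in 1:3) for (q in 1:3) {
    s <- 0
    for (i in seq_len(n - lag)) s <- s + Xc[i, p] * Xc[i + lag, q]
    out <- c(out, s / (n - lag))
  }
  out
}

# --- fixtures ------------------------------------------------------------

# a tiny handcrafted Mol2: 3 atoms, bonds "1 2 1" and "2 3 am"
write_tiny_mol2 <- function(path) {
  writeLines(c(
    "@<TRIPOS>MOLECULE", "tiny", " 3 2 0 0 0", "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    "      1 C1   0.0000 0.0000 0.0000 C.3  1 UNL1 0.0",
    "      2 C2   1.5000 0.0000 0.0000 C.2  1 UNL1 0.0",
    "      3 N1   2.1000 1.2000 0.0000 N.am 1 UNL1 0.0",
    "@<TRIPOS>BOND",
    "     1    1    2 1",
    "     2    2    3 am"), path)
  path
}

# random protein/ligand atom tables for pocket property tests
random_structure <- function(seed, n_res = 6L, atoms_per_res = 3L,
                             n_lig = 4L) {
  set.seed(seed)
  n <- n_res * atoms_per_res
  data_prot <- data.frame(
    element = sample(c("C", "N", "O", "S", "H"), n, replace = TRUE,
                     prob = c(.5, .15, .15, .1, .1)),
    x = stats::runif(n, -10, 10), y = stats::runif(n, -10, 10),
    z = stats::runif(n, -10, 10),
    residue_name = "RES",
    residue_id = rep(seq_len(n_res), each = atoms_per_res),
    chain_id = "A", role = "protein", stringsAsFactors = FALSE)
  data_lig <- data.frame(
    element = sample(c("C", "N", "O"), n_lig, replace = TRUE),
    x = stats::runif(n_lig, -3, 3), y = stats::runif(n_lig, -3, 3),
    z = stats::runif(n_lig, -3, 3),
    residue_name = "LIG", residue_id = n_res + 1L, chain_id = "A",
    role = "ligand", stringsAsFactors = FALSE)
  list(protein = data_prot, ligand = data_lig)
}

# small shared model configuration that keeps unit tests fast
tiny_model_config <- function(...) {
  model_config(node_embed_dim = 8L, gcn1_dim = 12L, gcn2_dim = 8L,
               lstm_hidden = 8L, token_embed_dim = 8L, linker_fc_dim = 8L,
               mlp_hidden = 8L, max_len = 24L, ...)
}

random_ligand_graph <- function(seed, n = 8L) {
  set.seed(seed)
  codes <- sample(0:9, n, replace = TRUE)
  # random spanning tree plus a few extra edges -> connected, no dups
  edges <- data.frame(i = 2:n, j = vapply(2:n, function(k)
    sample.int(k - 1L, 1L), integer(1)),
    code = sample(1:5, n - 1L, replace = TRUE))
  structure(list(kind = "ligand", node_codes = as.integer(codes),
                 edges = edges, node_count = n),
            class = "molecular_graph")
}

# one shared synthetic mini-dataset (generated once per test run)
mini_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "protacnet-mini")
      cache <<- generate_dataset(
        synth_spec(n_records = 60L, seed = 42L, n_pois = 3L), dir)
    }
    cache
  }
})

mini_prep <- local({
  cache <- NULL
  function(cfg = tiny_model_config()) {
    if (is.null(cache)) {
      ds <- mini_dataset()
      cache <<- prepare_records(ds$manifest, ds$structures_dir, cfg = cfg)
    }
    cache
  }
})
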