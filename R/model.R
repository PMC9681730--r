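# The five-branch degradation-prediction network: two weight-shared pocket
# GCN branches, two weight-shared ligand GCN branches, a BiLSTM linker
# branch, and a two-layer MLP head.

BRANCHES <- c("poi_pocket", "warhead", "linker", "e3_ligand", "e3_pocket")

#' Network configuration
#'
#' Defaults follow the published layer table: 64-wide node embeddings, two
#' graph-convolution layers 128 then 64, max pooling, bond-type encoding on,
#' a bidirectional LSTM with 64 hidden units per direction, 64-wide linker
#' fully connected layer, and an MLP head 64 -> 2.
#'
#' @param node_embed_dim,gcn1_dim,gcn2_dim graph branch widths.
#' @param pooling node readout: `"max"` (default), `"mean"` or `"sum"`.
#' @param use_bond_encoding include the learned bond-type message term.
#' @param lstm_hidden,token_embed_dim,linker_fc_dim linker branch widths.
#' @param mlp_hidden,output_dim MLP head widths.
#' @param leaky_relu_slope negative slope of the Leaky ReLU activations.
#' @param active_branches character subset of
#'   poi_pocket, warhead, linker, e3_ligand, e3_pocket.
#' @param max_len fixed linker token-sequence length.
#' @param n_gcn_layers number of graph-convolution layers (1, 2 or 3); with
#'   1 the first layer maps straight to `gcn2_dim`, with 3 a 128-wide middle
#'   layer is repeated.
#' @param variant `"full"` (five branches), `"whole_graph"` or
#'   `"whole_smiles"` (three branches with the whole molecule as one input).
#' @return a `model_config` list.
#' @export
model_config <- function(node_embed_dim = 64L, gcn1_dim = 128L,
                         gcn2_dim = 64L,
                         pooling = c("max", "mean", "sum"),
                         use_bond_encoding = TRUE,
                         lstm_hidden = 64L, token_embed_dim = 64L,
                         linker_fc_dim = 64L, mlp_hidden = 64L,
                         output_dim = 2L, leaky_relu_slope = 0.01,
                         active_branches = BRANCHES, max_len = 100L,
                         n_gcn_layers = 2L,
                         variant = c("full", "whole_graph", "whole_smiles")) {
  pooling <- match.arg(pooling)
  variant <- match.arg(variant)
  stopifnot(all(c(node_embed_dim, gcn1_dim, gcn2_dim, lstm_hidden,
                  token_embed_dim, linker_fc_dim, mlp_hidden, output_dim,
                  max_len) > 0))
  if (variant == "full") {
    stopifnot(length(active_branches) >= 1L,
              all(active_branches %in% BRANCHES))
    active_branches <- BRANCHES[BRANCHES %in% active_branches]
  } else {
    active_branches <- c("poi_pocket",
                         if (variant == "whole_graph") "protac_graph"
                         else "protac_smiles", "e3_pocket")
  }
  structure(list(node_embed_dim = node_embed_dim, gcn1_dim = gcn1_dim,
                 gcn2_dim = gcn2_dim, pooling = pooling,
                 use_bond_encoding = use_bond_encoding,
                 lstm_hidden = lstm_hidden, token_embed_dim = token_embed_dim,
                 linker_fc_dim = linker_fc_dim, mlp_hidden = mlp_hidden,
                 output_dim = output_dim, leaky_relu_slope = leaky_relu_slope,
                 active_branches = active_branches, max_len = max_len,
                 n_gcn_layers = as.integer(n_gcn_layers), variant = variant),
            class = "model_config")
}

branch_output_dim <- function(cfg, branch) {
  if (branch %in% c("linker", "protac_smiles")) cfg$linker_fc_dim else cfg$gcn2_dim
}

#' Concatenated MLP input width for a configuration
#' @param cfg a `model_config`.
#' @return integer width (e.g. 320 with all five branches active).
#' @export
concat_width <- function(cfg) {
  as.integer(sum(vapply(cfg$active_branches,
                        function(b) branch_output_dim(cfg, b), numeric(1))))
}

#' Initialize model parameters
#'
#' Parameters are grouped per branch family with the two sharing constraints
#' built in: there is a single `pocket` parameter set referenced by both the
#' POI-pocket and E3-pocket branches, and a single `ligand` set referenced
#' by both the warhead and E3-ligand branches. Initialization is uniform
#' within +-1/sqrt(fan-in) and fully determined by `seed`.
#'
#' @param cfg a `model_config`.
#' @param seed integer RNG seed.
#' @return a `model_params` list with elements `pocket`, `ligand`,
#'   `linker` (as active), `mlp`, plus `cfg`.
#' @export
init_model <- function(cfg = model_config(), seed = 1L) {
  set.seed(seed)
  P <- list()
  ab <- cfg$active_branches
  if (any(ab %in% c("poi_pocket", "e3_pocket")))
    P$pocket <- init_gcn_params(5L, cfg)
  if (any(ab %in% c("warhead", "e3_ligand", "protac_graph")))
    P$ligand <- init_gcn_params(10L, cfg)
  if (any(ab %in% c("linker", "protac_smiles")))
    P$linker <- init_lstm_params(cfg)
  P$mlp <- init_mlp_params(concat_width(cfg), cfg)
  structure(c(P, list(cfg = cfg)), class = "model_params")
}

param_set_for <- function(branch) {
  switch(branch,
         poi_pocket = "pocket", e3_pocket = "pocket",
         warhead = "ligand", e3_ligand = "ligand", protac_graph = "ligand",
         linker = "linker", protac_smiles = "linker")
}

#' Checksum of a parameter set (testing/reporting aid)
#' @param params a `model_params` object or any nested parameter list.
#' @return a single numeric sum over all parameter values.
#' @export
param_checksum <- function(params) {
  sum_params(params[setdiff(names(params), "cfg")])
}

#' Run one graph branch
#'
#' Embeds node codes, applies the graph-convolution stack with
#' symmetric-normalized adjacency (self-loops included) and optional learned
#' bond-type messages, and pools node features to a single vector.
#' @param graph a `molecular_graph` or precomputed [graph_tensors()].
#' @param params the branch parameter set (e.g. `model$pocket`).
#' @param cfg a `model_config`.
#' @return numeric vector of length `gcn2_dim`.
#' @export
gcn_branch <- function(graph, params, cfg = model_config()) {
  gt <- if (inherits(graph, "molecular_graph")) graph_tensors(graph) else graph
  gcn_branch_forward(gt, params, cfg)$out
}

#' Run the linker branch
#'
#' Token embedding, bidirectional LSTM (final forward and backward hidden
#' states concatenated), fully connected layer with Leaky ReLU.
#' @param tokens a `token_sequence`.
#' @param params the linker parameter set (`model$linker`).
#' @param cfg a `model_config`.
#' @return numeric vector of length `linker_fc_dim`.
#' @export
linker_branch <- function(tokens, params, cfg = model_config()) {
  linker_branch_forward(tokens, params, cfg)$out
}

# inputs: named list keyed by branch; full caches kept for backprop
model_forward <- function(inputs, params, cfg) {
  caches <- list()
  outs <- list()
  for (br in cfg$active_branches) {
    x <- inputs[[br]]
    if (is.null(x)) stop("missing input for active branch '", br, "'")
    set <- param_set_for(br)
    if (br %in% c("linker", "protac_smiles")) {
      caches[[br]] <- linker_branch_forward(x, params[[set]], cfg)
    } else {
      gt <- if (inherits(x, "molecular_graph")) graph_tensors(x) else x
      caches[[br]] <- gcn_branch_forward(gt, params[[set]], cfg)
      caches[[br]]$gt <- gt
    }
    outs[[br]] <- caches[[br]]$out
  }
  xcat <- unlist(outs, use.names = FALSE)
  head <- mlp_forward(xcat, params$mlp, cfg)
  list(caches = caches, head = head, logits = head$logits)
}

model_backward <- function(dlogits, fwd, params, cfg, grads) {
  mb <- mlp_backward(dlogits, fwd$head, params$mlp, cfg, grads$mlp)
  grads$mlp <- mb$grad
  off <- 0L
  for (br in cfg$active_branches) {
    w <- branch_output_dim(cfg, br)
    dh <- mb$dx[(off + 1L):(off + w)]
    off <- off + w
    set <- param_set_for(br)
    if (br %in% c("linker", "protac_smiles")) {
      grads[[set]] <- linker_branch_backward(dh, fwd$caches[[br]],
                                             params[[set]], cfg, grads[[set]])
    } else {
      grads[[set]] <- gcn_branch_backward(dh, fwd$caches[[br]],
                                          fwd$caches[[br]]$gt,
                                          params[[set]], cfg, grads[[set]])
    }
  }
  grads
}

#' Predict degradation capacity for featurized inputs
#'
#' @param params a `model_params` object.
#' @param inputs named list with one entry per active branch: molecular
#'   graphs (or [graph_tensors()]) for the graph branches and a
#'   `token_sequence` for the linker branch.
#' @return list with `logits` (length 2, class order inactive/active),
#'   `prob_active` and `label` (`"active"` iff prob_active > 0.5; ties are
#'   inactive).
#' @export
predict_record <- function(params, inputs) {
  cfg <- params$cfg
  fwd <- model_forward(inputs, params, cfg)
  p <- softmax(fwd$logits)
  list(logits = fwd$logits, prob_active = p[2L],
       label = if (p[2L] > 0.5) "active" else "inactive")
}

#' Ablated model configuration
#'
#' The eight ablation settings: 1 none, 2 ligase pocket, 3 E3 ligand,
#' 4 POI pocket, 5 warhead, 6 linker, 7 ligase pocket + E3 ligand,
#' 8 POI pocket + warhead. The MLP input is resized accordingly and the
#' ablated model is retrained from scratch.
#' @param base a `model_config`.
#' @param ablated_item integer 1..8.
#' @return a `model_config` with the named branch(es) removed.
#' @export
ablated_config <- function(base = model_config(), ablated_item) {
  stopifnot(ablated_item %in% 1:8)
  removed <- switch(ablated_item,
    character(0),                      # 1 none
    "e3_pocket",                       # 2 ligase pocket
    "e3_ligand",                       # 3 E3 ligand
    "poi_pocket",                      # 4 POI pocket
    "warhead",                         # 5 warhead
    "linker",                          # 6 linker
    c("e3_pocket", "e3_ligand"),       # 7 ligase pocket + E3 ligand
    c("poi_pocket", "warhead"))        # 8 POI pocket + warhead
  cfg <- base
  cfg$active_branches <- setdiff(base$active_branches, removed)
  cfg
}

#' Forward pass of the whole-molecule variant architectures
#'
#' Three-branch variants that replace the warhead/linker/E3-ligand split by
#' a single whole-molecule branch: the molecule as one ligand graph
#' (`whole_graph`) or as one SMILES token sequence (`whole_smiles`). The
#' pocket branches keep their shared weights.
#' @param kind `"whole_graph"` or `"whole_smiles"`.
#' @param poi_pocket,e3_pocket pocket graphs.
#' @param protac whole-molecule graph (`whole_graph`) or `token_sequence`
#'   (`whole_smiles`).
#' @param params a `model_params` initialized with the matching variant
#'   config.
#' @return as [predict_record()].
#' @export
variant_forward <- function(kind = c("whole_graph", "whole_smiles"),
                            poi_pocket, e3_pocket, protac, params) {
  kind <- match.arg(kind)
  stopifnot(params$cfg$variant == kind)
  inputs <- list(poi_pocket = poi_pocket, e3_pocket = e3_pocket)
  inputs[[if (kind == "whole_graph") "protac_graph" else "protac_smiles"]] <-
    protac
  predict_record(params, inputs)
}

#' Save / load model parameters with sidecar metadata
#'
#' The checkpoint is an RDS file; a JSON sidecar records the configuration,
#' seed and data hashes for reproducibility.
#' @param params a `model_params`.
#' @param path checkpoint path (`.rds`).
#' @param meta named list merged into the sidecar JSON.
#' @return `path` (save) or a `model_params` (load).
#' @export
save_model <- function(params, path, meta = list()) {
  saveRDS(params, path)
  side <- c(list(config = unclass(params$cfg),
                 checksum = param_checksum(params)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
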