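cfg0 <- tiny_model_config()

test_that("initialization is seed-deterministic and establishes weight sharing", {
  p1 <- init_model(cfg0, seed = 5)
  p2 <- init_model(cfg0, seed = 5)
  expect_identical(param_checksum(p1), param_checksum(p2))
  p3 <- init_model(cfg0, seed = 6)
  expect_false(identical(param_checksum(p1), param_checksum(p3)))
  # the two pocket branches and the two ligand branches literally reference
  # one parameter set each, so sharing is structural
  expect_identical(protacnet:::param_set_for("poi_pocket"),
                   protacnet:::param_set_for("e3_pocket"))
  expect_identical(protacnet:::param_set_for("warhead"),
                   protacnet:::param_set_for("e3_ligand"))
})

test_that("branch outputs have width 64 under the default configuration", {
  cfg <- model_config()
  params <- init_model(cfg, seed = 1)
  g <- to_graph(read_small_molecule("CC(=O)Nc1ccccc1"), "ligand")
  expect_length(gcn_branch(g, params$ligand, cfg), 64L)
  expect_length(linker_branch(tokenize("CCOCCO", max_len = 100L),
                              params$linker, cfg), 64L)
  expect_equal(concat_width(cfg), 320L)
  expect_equal(concat_width(ablated_config(cfg, 6)), 256L)
  expect_equal(concat_width(model_config(variant = "whole_graph")), 192L)
})

test_that("single-node graphs and all-pad sequences degrade gracefully", {
  params <- init_model(cfg0, seed = 2)
  g1 <- structure(list(kind = "ligand", node_codes = 3L,
                       edges = data.frame(i = integer(0), j = integer(0),
                                          code = integer(0)),
                       node_count = 1L), class = "molecular_graph")
  out <- gcn_branch(g1, params$ligand, cfg0)
  # max pooling over one node is the identity on that node's features
  fwd <- protacnet:::gcn_branch_forward(graph_tensors(g1), params$ligand, cfg0)
  expect_equal(out, as.numeric(fwd$Hlast[1, ]))

  pad <- tokenize("", max_len = 8L)
  v <- linker_branch(pad, params$linker, cfg0)
  expect_length(v, cfg0$linker_fc_dim)
  expect_true(all(is.finite(v)))
  expect_identical(v, linker_branch(pad, params$linker, cfg0))
})

test_that("graph branches are invariant to node permutation and edge order", {
  params <- init_model(cfg0, seed = 3)
  for (seed in 1:100) {
    g <- random_ligand_graph(seed)
    base <- gcn_branch(g, params$ligand, cfg0)
    set.seed(seed + 1000)
    perm <- sample.int(g$node_count)
    gp <- g
    gp$node_codes <- g$node_codes[order(perm)]
    gp$edges <- data.frame(i = perm[g$edges$i], j = perm[g$edges$j],
                           code = g$edges$code)
    gp$edges <- gp$edges[sample.int(nrow(gp$edges)), ]
    expect_equal(gcn_branch(gp, params$ligand, cfg0), base,
                 tolerance = 1e-10, info = paste("seed", seed))
  }
})

test_that("out-of-vocabulary node codes are rejected by the branch", {
  params <- init_model(cfg0, seed = 4)
  g <- random_ligand_graph(1)
  g$node_codes[1] <- 7L   # valid for ligand, invalid for pocket vocabulary
  expect_error(gcn_branch(g, params$pocket, cfg0), "out of range")
})

test_that("forward produces normalized probabilities over the full and ablated models", {
  params <- init_model(cfg0, seed = 6)
  prep <- mini_prep()
  rec <- prep[[1]]
  out <- predict_record(params, rec$inputs)
  expect_length(out$logits, 2L)
  p <- exp(out$logits) / sum(exp(out$logits))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_equal(out$prob_active, p[2], tolerance = 1e-12)
  expect_true(out$label %in% c("active", "inactive"))
  expect_error(predict_record(params, rec$inputs["warhead"]),
               "missing input")

  for (item in 1:8) {
    acfg <- ablated_config(cfg0, item)
    ap <- init_model(acfg, seed = 6)
    aout <- predict_record(ap, rec$inputs)
    expect_length(aout$logits, 2L)
  }
  # each model still works with all branches ablated except one
  for (keep in protacnet:::BRANCHES) {
    one <- tiny_model_config(active_branches = keep)
    op <- init_model(one, seed = 1)
    expect_length(predict_record(op, rec$inputs)$logits, 2L)
  }
})

test_that("ablation items remove the published branch sets", {
  cfg <- model_config()
  expect_equal(ablated_config(cfg, 1)$active_branches,
               c("poi_pocket", "warhead", "linker", "e3_ligand", "e3_pocket"))
  expect_equal(ablated_config(cfg, 7)$active_branches,
               c("poi_pocket", "warhead", "linker"))
  expect_false("linker" %in% ablated_config(cfg, 6)$active_branches)
  expect_length(ablated_config(cfg, 6)$active_branches, 4L)
  expect_equal(ablated_config(cfg, 8)$active_branches,
               c("linker", "e3_ligand", "e3_pocket"))
})

test_that("whole-molecule variants run with three branches and shared pockets", {
  prep <- mini_prep()
  ds <- mini_dataset()
  rec <- prep[[1]]
  row <- ds$manifest[ds$manifest$record_id == rec$record_id, ]
  whole <- paste0(row$warhead, ".", row$linker_smiles, ".", row$e3_ligand)

  gcfg <- tiny_model_config(variant = "whole_graph")
  gparams <- init_model(gcfg, seed = 2)
  gg <- to_graph(read_small_molecule(whole), "ligand")
  out <- variant_forward("whole_graph", rec$inputs$poi_pocket,
                         rec$inputs$e3_pocket, gg, gparams)
  expect_length(out$logits, 2L)

  scfg <- tiny_model_config(variant = "whole_smiles")
  sparams <- init_model(scfg, seed = 2)
  tk <- tokenize(whole, max_len = 80L)
  out2 <- variant_forward("whole_smiles", rec$inputs$poi_pocket,
                          rec$inputs$e3_pocket, tk, sparams)
  expect_length(out2$logits, 2L)
  # pocket sharing still holds: a single pocket parameter set exists
  expect_true("pocket" %in% names(gparams))
  expect_length(intersect(c("poi_pocket_params", "e3_pocket_params"),
                          names(gparams)), 0L)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- model_config(node_embed_dim = 4L, gcn1_dim = 6L, gcn2_dim = 5L,
                      lstm_hidden = 4L, token_embed_dim = 3L,
                      linker_fc_dim = 5L, mlp_hidden = 6L, max_len = 8L)
  params <- init_model(cfg, seed = 7)
  inputs <- list(
    poi_pocket = graph_tensors(structure(list(
      kind = "protein_pocket", node_codes = c(0L, 1L, 2L, 4L),
      edges = data.frame(i = c(1L, 2L, 3L), j = c(2L, 3L, 4L),
                         code = c(1L, 2L, 5L)), node_count = 4L),
      class = "molecular_graph")),
    warhead = graph_tensors(to_graph(read_small_molecule("CC(=O)NC"),
                                     "ligand")),
    linker = tokenize("CCOCC", max_len = 8L),
    e3_ligand = graph_tensors(to_graph(read_small_molecule("c1ccncc1"),
                                       "ligand")),
    e3_pocket = graph_tensors(structure(list(
      kind = "protein_pocket", node_codes = c(0L, 0L, 3L),
      edges = data.frame(i = c(1L, 2L), j = c(2L, 3L), code = c(1L, 1L)),
      node_count = 3L), class = "molecular_graph")))

  loss_at <- function(pars) {
    fwd <- protacnet:::model_forward(inputs, pars, cfg)
    protacnet:::ce_loss_grad(fwd$logits, 1L, 2)$loss
  }
  fwd <- protacnet:::model_forward(inputs, params, cfg)
  lg <- protacnet:::ce_loss_grad(fwd$logits, 1L, 2)
  grads <- protacnet:::zero_like(params[setdiff(names(params), "cfg")])
  grads <- protacnet:::model_backward(lg$dlogits, fwd, params, cfg, grads)

  eps <- 1e-6
  set.seed(99)
  check <- function(getp, setp, gmat) {
    for (trial in 1:4) {
      idx <- sample(length(getp(params)), 1L)
      up <- params; M <- getp(up); M[idx] <- M[idx] + eps; up <- setp(up, M)
      dn <- params; M <- getp(dn); M[idx] <- M[idx] - eps; dn <- setp(dn, M)
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(gmat[idx], num, tolerance = 1e-4)
    }
  }
  check(function(p) p$pocket$layers[[1]]$W,
        function(p, M) { p$pocket$layers[[1]]$W <- M; p },
        grads$pocket$layers[[1]]$W)
  check(function(p) p$ligand$embed,
        function(p, M) { p$ligand$embed <- M; p }, grads$ligand$embed)
  check(function(p) p$linker$fwd$Wx,
        function(p, M) { p$linker$fwd$Wx <- M; p }, grads$linker$fwd$Wx)
  check(function(p) p$linker$bwd$Wh,
        function(p, M) { p$linker$bwd$Wh <- M; p }, grads$linker$bwd$Wh)
  check(function(p) p$mlp$W1,
        function(p, M) { p$mlp$W1 <- M; p }, grads$mlp$W1)
})

test_that("pocket and ligand parameter sets stay bitwise shared after training", {
  prep <- mini_prep()
  fit <- train(cfg0, prep[1:20], NULL,
               train_config(epochs = 3L, lr = 1e-3, seed = 8))
  # both pocket branches read from fit$params$pocket; the gradient of a
  # sample flowed through BOTH pocket branches into the same matrices, so
  # any desynchronization would show up as a second parameter set
  expect_setequal(intersect(names(fit$params),
                            c("pocket", "ligand", "linker", "mlp")),
                  c("pocket", "ligand", "linker", "mlp"))
  # forward of poi_pocket and e3_pocket on the same graph agree exactly
  g <- prep[[1]]$inputs$poi_pocket
  expect_identical(gcn_branch(g, fit$params$pocket, cfg0),
                   gcn_branch(g, fit$params$pocket, cfg0))
  expect_gt(abs(param_checksum(fit$params) -
                  param_checksum(init_model(cfg0, seed = 8))), 0)
})

test_that("checkpoints round-trip parameters and sidecar metadata", {
  params <- init_model(cfg0, seed = 10)
  path <- file.path(tempdir(), "model.rds")
  save_model(params, path, meta = list(seed = 10))
  back <- load_model(path)
  expect_identical(param_checksum(back), param_checksum(params))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 10)
  expect_equal(side$checksum, param_checksum(params), tolerance = 1e-12)
})
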