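# Training loop, evaluation metrics, ablation suite, leave-one-target-out
# protocol, repeated-run aggregation, and the SVM / RF baselines.

#' Training configuration
#'
#' Defaults are the published settings: batch size 1, 30 epochs, Adam with
#' learning rate 1e-4, beta1 0.9, beta2 0.999, cross-entropy loss. With a
#' batch size other than 1 the epoch count is chosen by validation loss
#' with the given patience (up to `max_epochs`).
#' @param batch_size samples per optimizer step.
#' @param epochs fixed epoch count used at batch size 1.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param loss_mode `"normal"` or `"weighted"` (active-class loss x2).
#' @param seed integer seed controlling initialization and shuffling.
#' @param patience early-stopping patience on validation loss.
#' @param max_epochs epoch cap when early stopping is in charge.
#' @param on_featurize_error `"abort"` or `"skip"` (skip the record with a
#'   message).
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 1L, epochs = 30L, lr = 1e-4,
                         beta1 = 0.9, beta2 = 0.999,
                         loss_mode = c("normal", "weighted"), seed = 1L,
                         patience = 5L, max_epochs = 300L,
                         on_featurize_error = c("abort", "skip")) {
  stopifnot(epochs > 0L, lr > 0, batch_size >= 1L)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, loss_mode = match.arg(loss_mode),
                 seed = as.integer(seed), patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 on_featurize_error = match.arg(on_featurize_error)),
            class = "train_config")
}

#' Featurize manifest records for the network
#'
#' Reads and caches every referenced structure once: POI and E3 pocket
#' graphs come from the structure files via [pocket_from_structure()],
#' warhead and E3-ligand graphs from SMILES or structure files, and the
#' linker SMILES is tokenized. Graph tensors (normalized adjacency, bond
#' aggregation) are precomputed so training touches no file I/O.
#'
#' @param records manifest data.frame (labeled or not).
#' @param structures_dir directory that relative structure paths resolve
#'   against.
#' @param table an `encoding_table` for the linker tokenizer.
#' @param cfg a `model_config` (pocket radius is 5 Angstrom; `max_len`
#'   bounds the token sequence).
#' @param radius pocket selection radius in Angstrom.
#' @param include_variant also build whole-molecule graph and SMILES inputs
#'   for the variant architectures.
#' @param on_error `"abort"` or `"skip"` failing records with a message.
#' @return list of prepared records, each with `inputs`, `label`,
#'   `poi_name`, `record_id`.
#' @export
prepare_records <- function(records, structures_dir = ".",
                            table = default_encoding_table(),
                            cfg = model_config(), radius = 5.0,
                            include_variant = FALSE,
                            on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  pocket_cache <- new.env(parent = emptyenv())
  ligand_cache <- new.env(parent = emptyenv())

  pocket_gt <- function(path) {
    full <- resolve_path(path, structures_dir)
    key <- full
    if (is.null(pocket_cache[[key]])) {
      mol <- read_structure(full)
      g <- to_graph(pocket_from_structure(mol, radius), "protein_pocket")
      pocket_cache[[key]] <- graph_tensors(g)
    }
    pocket_cache[[key]]
  }
  ligand_gt <- function(src) {
    if (is.null(ligand_cache[[src]])) {
      mol <- read_small_molecule(resolve_path(src, structures_dir))
      ligand_cache[[src]] <- graph_tensors(to_graph(mol, "ligand"))
    }
    ligand_cache[[src]]
  }

  out <- vector("list", nrow(records))
  for (k in seq_len(nrow(records))) {
    r <- records[k, ]
    prep <- tryCatch({
      inputs <- list(
        poi_pocket = pocket_gt(r$poi_structure),
        warhead = ligand_gt(r$warhead),
        linker = tokenize(r$linker_smiles, table, cfg$max_len),
        e3_ligand = ligand_gt(r$e3_ligand),
        e3_pocket = pocket_gt(r$e3_structure))
      if (include_variant) {
        whole <- default_protac_smiles(r)
        inputs$protac_graph <-
          graph_tensors(to_graph(read_small_molecule(whole), "ligand"))
        inputs$protac_smiles <- tokenize(whole, table, 3L * cfg$max_len)
      }
      list(inputs = inputs, label = r$label, poi_name = r$poi_name,
           record_id = r$record_id)
    }, error = function(e) {
      if (on_error == "abort")
        stop("featurization failed for record ", r$record_id, ": ",
             conditionMessage(e))
      message("skipping record ", r$record_id, ": ", conditionMessage(e))
      NULL
    })
    out[[k]] <- prep
  }
  out[!vapply(out, is.null, logical(1))]
}

resolve_path <- function(p, dir) {
  if (file.exists(p) || grepl("^/", p)) p
  else if (file.exists(file.path(dir, p))) file.path(dir, p)
  else p   # SMILES strings and absolute paths pass through
}

#' Train the degradation-prediction network
#'
#' Per-sample Adam updates at batch size 1 with the sample order reshuffled
#' every epoch under the seed; with larger batch sizes, gradients are
#' averaged per batch and the epoch count is chosen by validation loss with
#' early stopping. The weight-sharing constraints hold throughout because
#' the pocket branches (and the ligand branches) literally reference one
#' parameter set whose gradient accumulates over both uses.
#'
#' @param model_cfg a `model_config`.
#' @param train_prep prepared records from [prepare_records()] (labeled).
#' @param val_prep prepared validation records or `NULL`.
#' @param train_cfg a `train_config`.
#' @param verbose print per-epoch losses.
#' @return list with `params` (trained `model_params`), `loss_history`
#'   (mean training loss per epoch) and `val_loss_history`.
#' @export
train <- function(model_cfg = model_config(), train_prep, val_prep = NULL,
                  train_cfg = train_config(), verbose = FALSE) {
  stopifnot(length(train_prep) > 0L)
  labels <- vapply(train_prep, `[[`, character(1), "label")
  if (any(!labels %in% c("active", "inactive")))
    stop("all training records must carry an active/inactive label")
  y <- as.integer(labels == "active")
  wts <- class_loss_weights(train_cfg$loss_mode)

  params <- init_model(model_cfg, train_cfg$seed)
  opt <- adam_state(params[setdiff(names(params), "cfg")])
  n <- length(train_prep)
  fixed_epochs <- train_cfg$batch_size == 1L || is.null(val_prep)
  n_epochs <- if (fixed_epochs) train_cfg$epochs else train_cfg$max_epochs

  loss_hist <- numeric(0)
  val_hist <- numeric(0)
  best_val <- Inf; best_params <- NULL; bad <- 0L
  set.seed(train_cfg$seed + 1L)

  for (epoch in seq_len(n_epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    bi <- 0L
    grads <- NULL
    for (k in perm) {
      rec <- train_prep[[k]]
      fwd <- model_forward(rec$inputs, params, model_cfg)
      lg <- ce_loss_grad(fwd$logits, y[k],
                         wts[[if (y[k] == 1L) "active" else "inactive"]])
      epoch_loss <- epoch_loss + lg$loss
      if (is.null(grads))
        grads <- zero_like(params[setdiff(names(params), "cfg")])
      grads <- model_backward(lg$dlogits, fwd, params, model_cfg, grads)
      bi <- bi + 1L
      if (bi == train_cfg$batch_size) {
        if (train_cfg$batch_size > 1L)
          grads <- map2_params(grads, grads,
                               function(g, .) g / train_cfg$batch_size)
        st <- adam_step(params[setdiff(names(params), "cfg")], grads, opt,
                        train_cfg$lr, train_cfg$beta1, train_cfg$beta2)
        params[names(st$params)] <- st$params
        opt <- st$state
        grads <- NULL; bi <- 0L
      }
    }
    if (bi > 0L) {   # trailing partial batch
      grads <- map2_params(grads, grads, function(g, .) g / bi)
      st <- adam_step(params[setdiff(names(params), "cfg")], grads, opt,
                      train_cfg$lr, train_cfg$beta1, train_cfg$beta2)
      params[names(st$params)] <- st$params
      opt <- st$state
    }
    loss_hist <- c(loss_hist, epoch_loss / n)
    if (!is.null(val_prep)) {
      vl <- mean_loss(params, val_prep, wts)
      val_hist <- c(val_hist, vl)
      if (!fixed_epochs) {
        if (vl < best_val - 1e-9) {
          best_val <- vl; best_params <- params; bad <- 0L
        } else bad <- bad + 1L
        if (bad >= train_cfg$patience) {
          if (verbose) message("early stop at epoch ", epoch)
          params <- best_params
          break
        }
      }
    }
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f%s", epoch,
                      utils::tail(loss_hist, 1),
                      if (length(val_hist))
                        sprintf(", val loss %.4f", utils::tail(val_hist, 1))
                      else ""))
  }
  list(params = params, loss_history = loss_hist,
       val_loss_history = val_hist)
}

mean_loss <- function(params, prep, wts) {
  mean(vapply(prep, function(rec) {
    y <- as.integer(rec$label == "active")
    fwd <- model_forward(rec$inputs, params, params$cfg)
    ce_loss_grad(fwd$logits, y,
                 wts[[if (y == 1L) "active" else "inactive"]])$loss
  }, numeric(1)))
}

#' Predicted activity probabilities for prepared records
#' @param params a trained `model_params`.
#' @param prep prepared records.
#' @return numeric vector of active-class probabilities.
#' @export
predict_prepared <- function(params, prep) {
  vapply(prep, function(rec) predict_record(params, rec$inputs)$prob_active,
         numeric(1))
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation over the active-class scores; tied scores
#' contribute half a concordance.
#' @param scores numeric prediction scores.
#' @param labels character or 0/1 labels; `"active"`/1 is the positive
#'   class.
#' @return AUROC in `[0, 1]`, or `NA` with a warning when only one class is
#'   present.
#' @export
auroc <- function(scores, labels) {
  y <- if (is.numeric(labels)) labels == 1 else labels == "active"
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0L || nneg == 0L) {
    warning("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate predictions on a labeled record set
#'
#' Accuracy at the 0.5 threshold, AUROC, true positive rate TP/(TP+FN) and
#' precision TP/(TP+FP); rates are percentages.
#' @param params a trained `model_params`, or `NULL` when `scores` is given.
#' @param prep prepared labeled records.
#' @param scores optional precomputed scores (skips the forward passes).
#' @return an `eval_report` list: `accuracy`, `auroc`, `tpr`, `precision`,
#'   `n`, plus the raw `scores` and `labels`.
#' @export
evaluate <- function(params, prep, scores = NULL) {
  labels <- vapply(prep, `[[`, character(1), "label")
  if (is.null(scores)) scores <- predict_prepared(params, prep)
  pred_active <- scores > 0.5
  y <- labels == "active"
  tp <- sum(pred_active & y); fn <- sum(!pred_active & y)
  fp <- sum(pred_active & !y)
  structure(list(
    accuracy = 100 * mean(pred_active == y),
    auroc = auroc(scores, labels),
    tpr = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    n = length(prep), scores = scores, labels = labels),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  accuracy %.2f%%  AUROC %s  TPR %.2f%%  precision %.2f%%\n",
              x$n, x$accuracy,
              ifelse(is.na(x$auroc), "NA", sprintf("%.4f", x$auroc)),
              x$tpr, x$precision))
  invisible(x)
}

#' ROC curve points
#' @param scores,labels as in [auroc()].
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  y <- labels == "active"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               fpr = sum(pred & !y) / max(sum(!y), 1L),
               tpr = sum(pred & y) / max(sum(y), 1L))
  }))
}

#' Train and evaluate over repeated seeds
#'
#' Runs [train()] `repeats` times with derived seeds and aggregates each
#' metric as mean and sample standard deviation, the aggregation used for
#' repeated-training reports.
#' @param model_cfg,train_prep,test_prep,train_cfg as in [train()].
#' @param repeats number of repeated trainings (default 3).
#' @return list with `runs` (data.frame of per-run metrics) and `summary`
#'   (data.frame metric/mean/sd).
#' @export
repeated_runs <- function(model_cfg, train_prep, test_prep,
                          train_cfg = train_config(), repeats = 3L) {
  runs <- do.call(rbind, lapply(seq_len(repeats), function(rep) {
    tc <- train_cfg
    tc$seed <- train_cfg$seed + 1000L * rep
    fit <- train(model_cfg, train_prep, NULL, tc)
    ev <- evaluate(fit$params, test_prep)
    data.frame(run = rep, seed = tc$seed, accuracy = ev$accuracy,
               auroc = ev$auroc, tpr = ev$tpr, precision = ev$precision)
  }))
  summary <- data.frame(
    metric = c("accuracy", "auroc", "tpr", "precision"),
    mean = vapply(runs[, c("accuracy", "auroc", "tpr", "precision")],
                  mean, numeric(1)),
    sd = vapply(runs[, c("accuracy", "auroc", "tpr", "precision")],
                stats::sd, numeric(1)))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}

#' Run the eight-item ablation suite
#'
#' For each ablated item (1 none ... 8 POI pocket + warhead) the model is
#' reconfigured with [ablated_config()], retrained from scratch `repeats`
#' times, and evaluated on the test partition; metrics are reported as mean
#' and SD over the repeats.
#' @param train_prep,test_prep prepared labeled records.
#' @param items subset of 1..8.
#' @param repeats repeated trainings per item.
#' @param model_cfg,train_cfg base configurations.
#' @return data.frame with one row per item: accuracy/auroc mean and sd and
#'   the removed branches.
#' @export
run_ablation_suite <- function(train_prep, test_prep, items = 1:8,
                               repeats = 3L, model_cfg = model_config(),
                               train_cfg = train_config()) {
  do.call(rbind, lapply(items, function(item) {
    cfg <- ablated_config(model_cfg, item)
    tc <- train_cfg
    tc$seed <- train_cfg$seed + 17L * item
    rr <- repeated_runs(cfg, train_prep, test_prep, tc, repeats)
    data.frame(ablated_item = item,
               branches = paste(cfg$active_branches, collapse = "+"),
               accuracy_mean = rr$summary$mean[1],
               accuracy_sd = rr$summary$sd[1],
               auroc_mean = rr$summary$mean[2],
               auroc_sd = rr$summary$sd[2],
               repeats = repeats)
  }))
}

#' Leave-one-target-out evaluation
#'
#' Excludes every record of one POI from training, trains on the rest, and
#' evaluates separately on the held-out target's records and on a random
#' residual test split of the remaining data.
#' @param prep prepared labeled records (with `poi_name`).
#' @param target_name POI name to hold out.
#' @param model_cfg,train_cfg configurations.
#' @param residual_test_fraction fraction of the remaining records held
#'   back as the residual test set.
#' @return list with `held_out` and `residual` `eval_report`s and the
#'   trained `params`.
#' @export
leave_one_target_out <- function(prep, target_name,
                                 model_cfg = model_config(),
                                 train_cfg = train_config(),
                                 residual_test_fraction = 0.2) {
  pois <- vapply(prep, `[[`, character(1), "poi_name")
  held <- prep[pois == target_name]
  rest <- prep[pois != target_name]
  if (length(held) == 0L) stop("no records for target '", target_name, "'")
  if (length(rest) < 2L) stop("not enough residual records to train on")
  set.seed(train_cfg$seed)
  n_test <- max(1L, floor(residual_test_fraction * length(rest)))
  test_idx <- sample.int(length(rest), n_test)
  fit <- train(model_cfg, rest[-test_idx], NULL, train_cfg)
  list(held_out = evaluate(fit$params, held),
       residual = evaluate(fit$params, rest[test_idx]),
       params = fit$params)
}

#' Paired two-sided t-test between two runs of per-run metrics
#' @param a,b numeric vectors of matched per-run metric values.
#' @return the `htest` object from [stats::t.test()] (no multiplicity
#'   adjustment).
#' @export
compare_configurations <- function(a, b) {
  stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
}

# ---- classical baselines -----------------------------------------------

#' Train the SVM baseline
#'
#' Linear-kernel support vector machine with regularization parameter C = 1
#' (libsvm through e1071), with probability scores exposed for AUROC.
#' @param features numeric matrix (rows = records).
#' @param labels factor or character labels.
#' @return an object of class `svm_baseline`.
#' @export
train_svm <- function(features, labels) {
  y <- factor(labels, levels = c("inactive", "active"))
  fit <- e1071::svm(features, y, kernel = "linear", cost = 1,
                    probability = TRUE, scale = FALSE)
  structure(list(fit = fit), class = "svm_baseline")
}

#' @rdname train_svm
#' @param object a trained baseline.
#' @param newdata feature matrix to score.
#' @param ... unused.
#' @export
predict.svm_baseline <- function(object, newdata, ...) {
  p <- stats::predict(object$fit, newdata, probability = TRUE)
  attr(p, "probabilities")[, "active"]
}

#' Train the random-forest baseline
#'
#' 100 trees with maximum depth 5 (ranger), probability machine for AUROC.
#' @param features numeric matrix (rows = records).
#' @param labels factor or character labels.
#' @param seed integer RNG seed.
#' @return an object of class `rf_baseline`.
#' @export
train_rf <- function(features, labels, seed = 1L) {
  y <- factor(labels, levels = c("inactive", "active"))
  df <- data.frame(features, check.names = FALSE)
  fit <- ranger::ranger(x = df, y = y, num.trees = 100L, max.depth = 5L,
                        probability = TRUE, seed = seed)
  structure(list(fit = fit, cols = colnames(df)), class = "rf_baseline")
}

#' @rdname train_rf
#' @param object a trained baseline.
#' @param newdata feature matrix to score.
#' @param ... unused.
#' @export
predict.rf_baseline <- function(object, newdata, ...) {
  df <- data.frame(newdata, check.names = FALSE)
  stats::predict(object$fit, df)$predictions[, "active"]
}
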