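#' Training hyperparameters
#'
#' Defaults: 200 epochs, Adam with
#' learning rate 0.01 and weight decay 0.001, batch size 16, dropout 0.5.
#' All values are overridable for scaled-down runs.
#'
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to weight-matrix gradients.
#' @param batch_size scans per optimisation step.
#' @param seed seed fanned out to shuffling and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, learning_rate = 0.01,
                         weight_decay = 0.001, batch_size = 16L, seed = 1L) {
  stopifnot(is_count(epochs), learning_rate >= 0, weight_decay >= 0,
            is_count(batch_size), batch_size >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Subject-wise split for one trial
#'
#' Deterministic rotation over the sorted subject ids: in trial `t` the
#' test role goes to subject `t`, validation to the next subject in cyclic
#' order, and the remaining subjects train. Roles are disjoint within a
#' trial and labels are never consulted.
#'
#' @param subjects vector of subject ids (>= 3 distinct).
#' @param trial trial index, `1..length(unique(subjects))`.
#' @return list with integer vectors `train`, `validation`, `test`.
#' @export
split_scheme <- function(subjects, trial) {
  subj <- sort(unique(subjects))
  n <- length(subj)
  if (n < 3) stopf("need at least 3 subjects for a train/val/test split, got %d", n)
  if (trial < 1 || trial > n) stopf("trial must be in 1..%d", n)
  test <- subj[trial]
  val <- subj[trial %% n + 1]
  list(train = setdiff(subj, c(test, val)), validation = val, test = test)
}

#' Cross-entropy loss of class scores
#'
#' Scores are mapped to probabilities by softmax and the loss is
#' `-log q(true)` per sample (the cross-entropy `-sum_x p(x) log q(x)` with
#' one-hot `p`), averaged over the batch.
#'
#' @param scores numeric vector (one sample) or `N x K` matrix.
#' @param labels integer class labels in `1..K`.
#' @return mean loss (non-negative scalar).
#' @export
cross_entropy <- function(scores, labels) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1)
  if (any(labels < 1 | labels > ncol(scores)))
    stopf("label outside 1..%d", ncol(scores))
  softmax_ce_fwd(scores, as.integer(labels))
}

#' Jointly train the CNN streams and the GCN
#'
#' Single backward pass per batch: gradients flow from the cross-entropy
#' loss through the GCN into all eleven CNN streams, and Adam updates every
#' parameter. The adjacency must have been built from training subjects only
#' and stays frozen. Per-epoch training and validation losses are recorded
#' and the parameters with the lowest validation loss are kept.
#'
#' @param decoder a [build_decoder()].
#' @param scans list of normalised [volume_sequence()] (all subjects).
#' @param split a [split_scheme()] result.
#' @param Ahat normalised adjacency from [normalize_adjacency()].
#' @param config a [train_config()].
#' @param verbose print per-epoch losses?
#' @return list with `decoder` (best-on-validation parameters), `history`
#'   (data.frame epoch/train_loss/val_loss), `best_epoch`.
#' @export
train_decoder <- function(decoder, scans, split, Ahat,
                          config = train_config(), verbose = FALSE) {
  subjects <- vapply(scans, function(s) s$subject, integer(1))
  labels <- vapply(scans, function(s) s$label, integer(1))
  tr_idx <- which(subjects %in% split$train)
  va_idx <- which(subjects %in% split$validation)
  if (length(tr_idx) == 0 || length(va_idx) == 0)
    stopf("empty split role: %d train / %d validation scans",
          length(tr_idx), length(va_idx))
  x_tr <- stack_scans(scans[tr_idx])
  y_tr <- labels[tr_idx]
  x_va <- stack_scans(scans[va_idx])
  y_va <- labels[va_idx]

  state <- adam_init(decoder$net)
  set.seed(derive_seed(config$seed, 300L))
  step <- 0L
  best <- list(loss = Inf, net = decoder$net, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  nb <- length(tr_idx)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(nb)
    ep_loss <- 0
    for (start in seq(1, nb, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, nb)]
      xb <- x_tr[, , , , idx, drop = FALSE]
      fw <- decoder_forward(decoder, xb, Ahat, training = TRUE)
      decoder <- fw$decoder
      loss <- softmax_ce_fwd(fw$scores, y_tr[idx])
      ep_loss <- ep_loss + loss * length(idx)
      gs <- softmax_ce_bwd(fw$scores, y_tr[idx])
      grads <- decoder_backward(decoder, fw$cache, gs, Ahat)
      step <- step + 1L
      upd <- adam_step(decoder$net, grads, state, step,
                       lr = config$learning_rate,
                       weight_decay = config$weight_decay)
      decoder$net <- upd$p
      state <- upd$s
    }
    val_scores <- decoder_forward(decoder, x_va, Ahat, training = FALSE)$scores
    val_loss <- softmax_ce_fwd(val_scores, y_va)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / nb,
                                   val_loss = val_loss))
    if (val_loss < best$loss)
      best <- list(loss = val_loss, net = decoder$net, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / nb, val_loss))
  }
  decoder$net <- best$net
  list(decoder = decoder, history = hist, best_epoch = best$epoch)
}

#' One-vs-rest confusion counts
#'
#' Per-class TP/FP/FN/TN counts derived from the multi-class confusion
#' matrix; for every class the four counts sum to the number of samples, and
#' the TP counts sum to the number of correct predictions.
#'
#' @param predictions,truths integer labels in `1..n_classes`, equal length.
#' @param n_classes number of classes.
#' @return data.frame with columns class, TP, FP, FN, TN.
#' @export
confusion_counts <- function(predictions, truths, n_classes) {
  if (length(predictions) != length(truths) || length(truths) < 1)
    stopf("predictions and truths must have equal positive length")
  if (any(c(predictions, truths) < 1 | c(predictions, truths) > n_classes))
    stopf("label out of range 1..%d", n_classes)
  cm <- table(factor(predictions, levels = seq_len(n_classes)),
              factor(truths, levels = seq_len(n_classes)))
  n <- length(truths)
  tp <- diag(cm)
  fp <- rowSums(cm) - tp
  fn <- colSums(cm) - tp
  data.frame(class = seq_len(n_classes), TP = as.integer(tp),
             FP = as.integer(fp), FN = as.integer(fn),
             TN = as.integer(n - tp - fp - fn))
}

#' Evaluation metrics from confusion counts
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F-score
#' `(1+beta^2) P R / (beta^2 P + R)` with `beta = 1`, and one-vs-rest
#' accuracy `(TP+TN)/n`; macro (unweighted) averages over classes; total
#' accuracy `sum(TP)/n`. A zero denominator makes the metric undefined: it
#' is reported as 0 and flagged in the `undefined` column so averages remain
#' defined.
#'
#' @param counts a [confusion_counts()] data.frame.
#' @param beta F-score weight (default 1).
#' @return object of class `metrics_report`: `per_class` data.frame, `macro`
#'   named vector, `accuracy` scalar, `n`.
#' @export
compute_metrics <- function(counts, beta = 1) {
  n <- counts$TP[1] + counts$FP[1] + counts$FN[1] + counts$TN[1]
  safe_div <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  precision <- safe_div(counts$TP, counts$TP + counts$FP)
  recall <- safe_div(counts$TP, counts$TP + counts$FN)
  fden <- beta^2 * precision + recall
  fscore <- ifelse(fden > 0, (1 + beta^2) * precision * recall / ifelse(fden > 0, fden, 1), 0)
  class_acc <- (counts$TP + counts$TN) / n
  undefined <- (counts$TP + counts$FP == 0) | (counts$TP + counts$FN == 0)
  per_class <- data.frame(class = counts$class, precision = precision,
                          recall = recall, fscore = fscore,
                          accuracy = class_acc, undefined = undefined)
  structure(list(per_class = per_class,
                 macro = c(precision = mean(precision), recall = mean(recall),
                           fscore = mean(fscore)),
                 accuracy = sum(counts$TP) / n, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics over %d samples: total accuracy %.2f%%\n", x$n,
              100 * x$accuracy))
  cat(sprintf("macro: precision %.2f%%  recall %.2f%%  F-score %.2f%%\n",
              100 * x$macro["precision"], 100 * x$macro["recall"],
              100 * x$macro["fscore"]))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Evaluate a trained decoder on one split role
#'
#' @param decoder trained decoder.
#' @param scans full normalised scan list.
#' @param split a [split_scheme()] result.
#' @param Ahat the frozen normalised adjacency.
#' @param role `"test"` or `"validation"`.
#' @return a `metrics_report` with attribute `predictions`.
#' @export
evaluate_decoder <- function(decoder, scans, split, Ahat,
                             role = c("test", "validation")) {
  role <- match.arg(role)
  keep <- if (role == "test") split$test else split$validation
  subjects <- vapply(scans, function(s) s$subject, integer(1))
  idx <- which(subjects %in% keep)
  pred <- predict_decoder(decoder, scans[idx], Ahat)
  truth <- vapply(scans[idx], function(s) s$label, integer(1))
  rep <- compute_metrics(confusion_counts(pred$labels, truth,
                                          decoder$n_classes))
  attr(rep, "predictions") <- data.frame(scan = idx, truth = truth,
                                         predicted = pred$labels)
  rep
}

#' Run the full multi-trial decoding experiment
#'
#' For each trial: rotate the subject roles, normalise scans per subject,
#' build and freeze the functional-connectivity adjacency from the training
#' subjects only, train the joint model, and evaluate on the held-out test
#' subject. Reports per-trial metrics plus the mean over trials.
#'
#' @param dataset a [generate_dataset()] result (or compatible list with
#'   `template`, `scans`).
#' @param cnn,gcn,train configurations for the three model parts.
#' @param n_trials number of subject rotations (default
#'   `min(5, n_subjects)`).
#' @param omega within-group adjacency weight.
#' @param adjacency_type passed to [build_adjacency()].
#' @param seed experiment master seed (fans out to model init, shuffling,
#'   dropout).
#' @param verbose print progress?
#' @return object of class `experiment_record`: per-trial reports,
#'   adjacencies, loss histories, aggregate means, and the full
#'   configuration.
#' @export
run_experiment <- function(dataset, cnn = stream_config(),
                           gcn = gcn_config(), train = train_config(),
                           n_trials = NULL, omega = 3,
                           adjacency_type = "weighted_pearson",
                           seed = 1L, verbose = FALSE) {
  template <- dataset$template
  subjects <- sort(unique(vapply(dataset$scans, function(s) s$subject,
                                 integer(1))))
  n_subj <- length(subjects)
  n_trials <- n_trials %||% min(5L, n_subj)
  if (n_subj < 5)
    warning(sprintf("only %d subjects: running %d trial(s) instead of the full 5-trial protocol",
                    n_subj, n_trials))
  scans <- normalize_by_subject(dataset$scans)
  trials <- list()
  for (tr in seq_len(n_trials)) {
    split <- split_scheme(subjects, tr)
    train_scans <- scans[vapply(scans, function(s) s$subject, integer(1)) %in%
                           split$train]
    adj <- adjacency_from_scans(train_scans, template, omega = omega,
                                type = adjacency_type,
                                seed = derive_seed(seed, 400L, tr))
    Ahat <- normalize_adjacency(adj)
    decoder <- build_decoder(template, cnn = cnn, gcn = gcn,
                             seed = derive_seed(seed, 500L, tr))
    cfg <- train
    cfg$seed <- derive_seed(seed, 600L, tr)
    fit <- train_decoder(decoder, scans, split, Ahat, cfg, verbose = verbose)
    report <- evaluate_decoder(fit$decoder, scans, split, Ahat, "test")
    if (verbose)
      message(sprintf("trial %d: test accuracy %.2f%%", tr,
                      100 * report$accuracy))
    trials[[tr]] <- list(trial = tr, split = split, adjacency = adj,
                         history = fit$history, best_epoch = fit$best_epoch,
                         report = report)
  }
  acc <- vapply(trials, function(t) t$report$accuracy, numeric(1))
  macro <- rowMeans(vapply(trials, function(t) t$report$macro, numeric(3)))
  structure(list(trials = trials,
                 mean_accuracy = mean(acc),
                 mean_macro = macro,
                 config = list(cnn = cnn, gcn = gcn, train = train,
                               omega = omega,
                               adjacency_type = adjacency_type, seed = seed)),
            class = "experiment_record")
}

#' @export
print.experiment_record <- function(x, ...) {
  acc <- vapply(x$trials, function(t) t$report$accuracy, numeric(1))
  cat(sprintf("experiment: %d trial(s), mean test accuracy %.2f%%\n",
              length(x$trials), 100 * x$mean_accuracy))
  for (i in seq_along(acc))
    cat(sprintf("  trial %d (test subject %s): %.2f%%\n", i,
                x$trials[[i]]$split$test, 100 * acc[i]))
  invisible(x)
}

#' Serialise an experiment record to JSON
#'
#' Stores splits, adjacency matrices, loss histories, per-trial metrics and
#' the resolved configuration - enough metadata to regenerate the run.
#'
#' @param record an `experiment_record`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_experiment <- function(record, path) {
  out <- list(
    config = lapply(record$config, function(x)
      if (is.list(x)) unclass(x) else x),
    mean_accuracy = record$mean_accuracy,
    mean_macro = as.list(record$mean_macro),
    trials = lapply(record$trials, function(t) list(
      trial = t$trial, split = t$split,
      adjacency = unname(as.data.frame(t$adjacency$A)),
      best_epoch = t$best_epoch,
      history = t$history,
      accuracy = t$report$accuracy,
      macro = as.list(t$report$macro),
      per_class = t$report$per_class)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
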