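test_that("cross-entropy matches the one-hot definition", {
  # certain correct prediction: loss 0
  expect_equal(cross_entropy(c(100, 0, 0), 1), 0, tolerance = 1e-10)
  # q(true) = 0.5
  expect_equal(cross_entropy(c(0, 0), 1), 0.6931, tolerance = 1e-4)
  # definition oracle: -sum p log q with one-hot p, via an explicit loop
  set.seed(51)
  scores <- matrix(rnorm(6 * 4), 6, 4)
  y <- sample(4, 6, replace = TRUE)
  ref <- 0
  for (i in 1:6) {
    q <- exp(scores[i, ]) / sum(exp(scores[i, ]))
    p <- replace(rep(0, 4), y[i], 1)
    ref <- ref - sum(p * log(q))
  }
  expect_equal(cross_entropy(scores, y), ref / 6, tolerance = 1e-9)
  expect_error(cross_entropy(c(0, 0), 3), "label")
})

test_that("one-vs-rest confusion counts follow the confusion matrix", {
  # perfect balanced 10-class predictions
  truth <- rep(1:10, each = 10)
  cc <- confusion_counts(truth, truth, 10)
  expect_true(all(cc$TP == 10 & cc$FP == 0 & cc$FN == 0 & cc$TN == 90))
  # everything predicted as class 1 on two balanced classes
  cc2 <- confusion_counts(rep(1, 20), rep(1:2, each = 10), 2)
  expect_identical(cc2[1, -1], data.frame(TP = 10L, FP = 10L, FN = 0L, TN = 0L),
                   ignore_attr = TRUE)
  expect_identical(cc2[2, -1], data.frame(TP = 0L, FP = 0L, FN = 10L, TN = 10L),
                   ignore_attr = TRUE)
  # invariants on random label vectors, against a brute-force loop
  set.seed(52)
  for (r in 1:10) {
    k <- sample(3:8, 1); n <- sample(20:60, 1)
    pred <- sample(k, n, replace = TRUE)
    tru <- sample(k, n, replace = TRUE)
    cc <- confusion_counts(pred, tru, k)
    expect_true(all(cc$TP + cc$FP + cc$FN + cc$TN == n))
    expect_identical(sum(cc$TP), sum(pred == tru))
    for (cl in seq_len(k)) {
      expect_identical(cc$TP[cl], sum(pred == cl & tru == cl))
      expect_identical(cc$FP[cl], sum(pred == cl & tru != cl))
      expect_identical(cc$FN[cl], sum(pred != cl & tru == cl))
    }
  }
  expect_error(confusion_counts(c(1, 5), c(1, 2), 4), "out of range")
})

test_that("metrics reproduce the printed formulas", {
  cc <- data.frame(class = 1L, TP = 9L, FP = 1L, FN = 1L, TN = 89L)
  m <- compute_metrics(cc)
  expect_equal(m$per_class$precision, 0.90)
  expect_equal(m$per_class$recall, 0.90)
  expect_equal(m$per_class$fscore, 0.90)
  expect_equal(m$per_class$accuracy, 0.98)
  # perfect classifier
  mp <- compute_metrics(confusion_counts(rep(1:5, 4), rep(1:5, 4), 5))
  expect_true(all(mp$per_class$precision == 1 & mp$per_class$recall == 1 &
                    mp$per_class$fscore == 1))
  expect_equal(mp$accuracy, 1)
  # precision = recall implies F = precision at beta = 1
  set.seed(53)
  for (r in 1:20) {
    tp <- sample(1:20, 1); e <- sample(0:10, 1)
    m1 <- compute_metrics(data.frame(class = 1L, TP = tp, FP = e, FN = e,
                                     TN = 100L))
    expect_equal(m1$per_class$fscore, m1$per_class$precision, tolerance = 1e-12)
  }
  # F lies between precision and recall
  mr <- compute_metrics(data.frame(class = 1L, TP = 8L, FP = 4L, FN = 1L,
                                   TN = 80L))
  expect_true(mr$per_class$fscore >= min(mr$per_class$precision,
                                         mr$per_class$recall) &&
                mr$per_class$fscore <= max(mr$per_class$precision,
                                           mr$per_class$recall))
  # undefined precision (never predicted) reported as 0 and flagged
  mu <- compute_metrics(confusion_counts(rep(1, 10), rep(1:2, 5), 2))
  expect_equal(mu$per_class$precision[2], 0)
  expect_true(mu$per_class$undefined[2])
  expect_false(mu$per_class$undefined[1])
})

test_that("metric formulas agree with an independent implementation", {
  # independent route: per-class metrics enumerated directly from the label
  # vectors, never through confusion_counts
  set.seed(54)
  for (r in 1:50) {
    k <- sample(2:10, 1); n <- sample(10:50, 1)
    pred <- sample(k, n, replace = TRUE)
    tru <- sample(k, n, replace = TRUE)
    m <- compute_metrics(confusion_counts(pred, tru, k))
    for (cl in seq_len(k)) {
      tp <- sum(pred == cl & tru == cl)
      prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
      rec <- if (sum(tru == cl) > 0) tp / sum(tru == cl) else 0
      f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      expect_identical(m$per_class$precision[cl], prec)
      expect_identical(m$per_class$recall[cl], rec)
      expect_equal(m$per_class$fscore[cl], f, tolerance = 1e-12)
    }
    expect_identical(m$accuracy, mean(pred == tru))
  }
})

test_that("subject splits rotate deterministically and stay disjoint", {
  for (tr in 1:5) {
    sp <- split_scheme(1:5, tr)
    expect_length(sp$train, 3)
    expect_length(intersect(sp$train, c(sp$validation, sp$test)), 0)
    expect_false(sp$validation == sp$test)
    expect_setequal(c(sp$train, sp$validation, sp$test), 1:5)
  }
  # each subject serves as test exactly once over the five trials
  tests <- vapply(1:5, function(t) split_scheme(1:5, t)$test, integer(1))
  expect_setequal(tests, 1:5)
  expect_error(split_scheme(1:2, 1), "at least 3 subjects")
  expect_error(split_scheme(1:5, 6), "trial")
})

test_that("training is deterministic, sensitive to the seed, and inert at lr 0", {
  ds <- desk_dataset(n_subjects = 3, reps = 2, seed = 61)
  scans <- normalize_by_subject(ds$scans)
  subjects <- vapply(scans, function(s) s$subject, integer(1))
  split <- split_scheme(subjects, 1)
  Ahat <- normalize_adjacency(
    adjacency_from_scans(scans[subjects %in% split$train], ds$template))
  dec <- build_decoder(ds$template, cnn = stream_config("small"),
                       gcn = gcn_config(), seed = 7)
  cfg <- train_config(epochs = 2, seed = 3)
  f1 <- train_decoder(dec, scans, split, Ahat, cfg)
  f2 <- train_decoder(dec, scans, split, Ahat, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$decoder$net, f2$decoder$net)
  f3 <- train_decoder(dec, scans, split, Ahat, train_config(epochs = 2, seed = 4))
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
  # learning rate 0 leaves every parameter where it started
  f0 <- train_decoder(dec, scans, split, Ahat,
                      train_config(epochs = 1, learning_rate = 0,
                                   weight_decay = 0, seed = 3))
  expect_equal(f0$decoder$net$streams[[1]]$layers$C1$params$W,
               dec$net$streams[[1]]$layers$C1$params$W, tolerance = 1e-12)
  expect_equal(f0$decoder$net$gcn$head$params$W, dec$net$gcn$head$params$W,
               tolerance = 1e-12)
  # optimisation sanity: loss falls over a short run
  expect_lt(f1$history$train_loss[2], f1$history$train_loss[1])
  empty_split <- list(train = 8:9, validation = 7L, test = 1L)
  expect_error(train_decoder(dec, scans, empty_split, Ahat, cfg),
               "empty split")
})

test_that("a shared-weights decoder runs with a single stream", {
  tpl <- desk_template(1)
  dec <- build_decoder(tpl, cnn = stream_config("small"), gcn = gcn_config(),
                       seed = 2, shared_weights = TRUE)
  expect_length(dec$net$streams, 1)
  x5 <- array(rnorm(prod(desk_grid()) * 3 * 2), c(desk_grid(), 3, 2))
  A <- normalize_adjacency(build_adjacency(NULL, type = "random", seed = 1))
  fw <- gcndecode:::decoder_forward(dec, x5, A, training = TRUE)
  expect_identical(dim(fw$scores), c(2L, 10L))
  gs <- gcndecode:::softmax_ce_bwd(fw$scores, c(1L, 2L))
  grads <- gcndecode:::decoder_backward(fw$decoder, fw$cache, gs, A)
  expect_length(grads$streams, 1)
  expect_true(all(is.finite(grads$streams[[1]]$layers$C1$params$W)))
})

test_that("experiments keep subject roles apart and serialise losslessly", {
  ds <- desk_dataset(n_subjects = 3, reps = 2, seed = 62)
  expect_warning(
    rec <- run_experiment(ds, cnn = stream_config("small"),
                          gcn = gcn_config(),
                          train = train_config(epochs = 2, seed = 1),
                          n_trials = 1, seed = 9),
    "3 subjects")
  trial <- rec$trials[[1]]
  expect_length(intersect(trial$split$train,
                          c(trial$split$validation, trial$split$test)), 0)
  # no leakage: the frozen adjacency equals one recomputed from training
  # subjects only, and differs from one that includes the test subject
  scans <- normalize_by_subject(ds$scans)
  subjects <- vapply(scans, function(s) s$subject, integer(1))
  ref <- adjacency_from_scans(scans[subjects %in% trial$split$train],
                              ds$template, omega = 3)
  leaked <- adjacency_from_scans(scans, ds$template, omega = 3)
  expect_equal(trial$adjacency$A, ref$A, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(trial$adjacency$A, leaked$A)))
  # record round-trips through JSON
  path <- withr::local_tempfile(fileext = ".json")
  write_experiment(rec, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$mean_accuracy, rec$mean_accuracy, tolerance = 1e-12)
  expect_equal(back$trials$accuracy[1], trial$report$accuracy,
               tolerance = 1e-12)
  expect_equal(unname(as.matrix(back$trials$adjacency[[1]])),
               unname(trial$adjacency$A), tolerance = 1e-9)
})
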