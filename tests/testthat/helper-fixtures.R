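# Shared fixtures: all synthetic, generated at test time.

# desk-scale grid compatible with the "small" stream preset
desk_grid <- function() c(12L, 12L, 10L)

desk_template <- function(seed = 1L) generate_template(seed, grid = desk_grid())

desk_dataset <- function(n_subjects = 3L, reps = 2L, effect_size = 2,
                         seed = 1L, n_classes = 10L) {
  tpl <- desk_template(seed)
  cfg <- generator_config(n_subjects = n_subjects,
                          scans_per_class_per_subject = reps,
                          n_classes = n_classes, effect_size = effect_size,
                          grid = desk_grid(), seed = seed)
  generate_dataset(cfg, tpl)
}

# a deliberately tiny stream architecture for gradient and shape tests
tiny_grid <- function() c(6L, 6L, 5L)

tiny_stream_config <- function(width = 2L) {
  layers <- list(C1 = gcndecode:::conv_layer(c(3, 3, 2), 2),
                 S1 = gcndecode:::pool_layer(c(2, 2, 2), c(2, 2, 2)),
                 C2 = gcndecode:::conv_layer(c(2, 2, 2), width))
  stream_config(layers = layers, feature_width = width)
}

# random binary template on the tiny grid (ROIs may overlap; HVC kept valid)
tiny_template <- function(seed = 42L) {
  grid <- tiny_grid()
  set.seed(seed)
  masks <- lapply(roi_names(), function(n) array(rbinom(prod(grid), 1, 0.4), grid))
  names(masks) <- roi_names()
  for (n in roi_names()) if (sum(masks[[n]]) == 0) masks[[n]][1] <- 1
  masks$HVC <- pmin(masks$LOC + masks$FFA + masks$PPA, 1)
  roi_template(masks)
}

# nearest-centroid classifier on ROI-mean time-course features (33 numbers
# per scan): the simple baseline the synthetic data must make solvable
roi_mean_features <- function(scans, template) {
  t(vapply(scans, function(s)
    unlist(lapply(roi_names(), function(r)
      roi_mean_timecourse(s, r, template))),
    numeric(3 * length(roi_names()))))
}

nearest_centroid_accuracy <- function(dataset) {
  scans <- normalize_by_subject(dataset$scans)
  subjects <- vapply(scans, function(s) s$subject, integer(1))
  labels <- vapply(scans, function(s) s$label, integer(1))
  feats <- roi_mean_features(scans, dataset$template)
  tr <- subjects == 1
  te <- !tr
  classes <- sort(unique(labels))
  centroids <- t(vapply(classes, function(cl)
    colMeans(feats[tr & labels == cl, , drop = FALSE]),
    numeric(ncol(feats))))
  pred <- apply(feats[te, , drop = FALSE], 1, function(f)
    classes[which.min(colSums((t(centroids) - f)^2))])
  mean(pred == labels[te])
}
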