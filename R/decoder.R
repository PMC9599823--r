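#' Build the joint ROI-CNN + GCN decoder
#'
#' One CNN stream per ROI (independent weights by default; optionally one
#' shared stream), feeding the stacked feature matrix into the residual GCN
#' classifier. With `use_gcn = FALSE` the GCN is removed and the flattened
#' feature matrix goes straight to a fully connected head (the no-GCN
#' ablation); all other parts are unchanged.
#'
#' @param template an [roi_template()] (fixes grid and masks).
#' @param cnn a [stream_config()].
#' @param gcn a [gcn_config()].
#' @param seed RNG seed fanned out to every stream and the GCN.
#' @param shared_weights share one stream across the 11 ROIs?
#' @param use_gcn include the GCN (default) or the ablation head?
#' @return object of class `decoder`.
#' @export
build_decoder <- function(template, cnn = stream_config(),
                          gcn = gcn_config(), seed = 1L,
                          shared_weights = FALSE, use_gcn = TRUE) {
  nr <- length(roi_names())
  grid <- as.integer(template$grid)
  n_streams <- if (shared_weights) 1L else nr
  streams <- lapply(seq_len(n_streams), function(i)
    build_stream(cnn, input_extents = grid, in_channels = 3L,
                 seed = derive_seed(seed, 100L, i)))
  width <- cnn$feature_width
  net <- list(streams = streams)
  if (use_gcn) {
    net$gcn <- build_gcn(gcn, n_rois = nr, in_width = width,
                         seed = derive_seed(seed, 200L))
  } else {
    hin <- nr * width
    set.seed(derive_seed(seed, 201L))
    net$head <- list(params = list(W = init_uniform(c(hin, gcn$n_classes), hin),
                                   b = rep(0, gcn$n_classes)))
  }
  structure(list(net = net, masks = template$masks, grid = grid,
                 n_rois = nr, feature_width = width,
                 n_classes = gcn$n_classes, use_gcn = use_gcn,
                 shared_weights = shared_weights, seed = as.integer(seed),
                 cnn_config = cnn, gcn_config = gcn),
            class = "decoder")
}

#' @export
print.decoder <- function(x, ...) {
  cat(sprintf("decoder: %d ROI streams (%s, width %d)%s -> %s -> %d classes\n",
              x$n_rois, x$cnn_config$preset, x$feature_width,
              if (x$shared_weights) " [shared weights]" else "",
              if (x$use_gcn)
                sprintf("GCN (%d blocks, residual %s)",
                        x$gcn_config$n_blocks, x$gcn_config$residual_type)
              else "dense head (no GCN)",
              x$n_classes))
  invisible(x)
}

# forward a batch x5 (X, Y, Z, 3, N) through masking, streams and classifier
decoder_forward <- function(decoder, x5, Ahat, training = FALSE) {
  n <- dim(x5)[5]
  nr <- decoder$n_rois
  w <- decoder$feature_width
  F3 <- array(0, dim = c(nr, w, n))
  scaches <- vector("list", nr)
  for (r in seq_len(nr)) {
    xm <- x5 * as.vector(decoder$masks[[roi_names()[r]]])
    si <- if (decoder$shared_weights) 1L else r
    fw <- stream_forward(decoder$net$streams[[si]], xm, training = training)
    if (training) decoder$net$streams[[si]] <- fw$stream
    F3[r, , ] <- t(fw$out)
    scaches[[r]] <- fw
  }
  if (decoder$use_gcn) {
    gf <- gcn_forward(decoder$net$gcn, F3, Ahat, training = training)
    if (training) decoder$net$gcn <- gf$gcn
    scores <- gf$scores
    gcache <- gf$cache
  } else {
    flat <- t(matrix(F3, nrow = nr * w, ncol = n))
    scores <- dense_fwd(flat, decoder$net$head$params$W,
                        decoder$net$head$params$b)
    gcache <- list(flat = flat, n = n)
  }
  list(scores = scores, decoder = decoder,
       cache = if (training) list(streams = scaches, gcn = gcache, F3 = F3))
}

decoder_backward <- function(decoder, cache, gscores, Ahat) {
  nr <- decoder$n_rois
  w <- decoder$feature_width
  n <- nrow(gscores)
  grads <- list(streams = vector("list", length(decoder$net$streams)))
  if (decoder$use_gcn) {
    gb <- gcn_backward(decoder$net$gcn, cache$gcn, gscores, Ahat)
    grads$gcn <- gb$grads
    gF3 <- gb$gF3
  } else {
    db <- dense_bwd(cache$gcn$flat, decoder$net$head$params$W, gscores)
    grads$head <- list(params = list(W = db$gW, b = db$gb))
    gF3 <- array(t(db$gx), dim = c(nr, w, n))
  }
  for (r in seq_len(nr)) {
    gout <- t(matrix(gF3[r, , ], nrow = w)) # N x width
    si <- if (decoder$shared_weights) 1L else r
    sb <- stream_backward(decoder$net$streams[[si]], cache$streams[[r]], gout)
    grads$streams[[si]] <- grads_add(grads$streams[[si]], sb$grads)
  }
  grads
}

#' Predict stimulus classes for a batch of scans
#'
#' Runs the decoder in inference mode (batch-norm running statistics, no
#' dropout) and takes the arg-max score per scan; ties break toward the
#' lowest class index.
#'
#' @param decoder a trained [build_decoder()].
#' @param scans list of [volume_sequence()] (already normalised per subject).
#' @param Ahat normalised adjacency used at training time.
#' @param batch_size scans per forward batch.
#' @return list with `labels` (integer vector) and `scores`
#'   (`n_scans x n_classes` matrix).
#' @export
predict_decoder <- function(decoder, scans, Ahat, batch_size = 16L) {
  n <- length(scans)
  scores <- matrix(0, n, decoder$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x5 <- stack_scans(scans[idx])
    scores[idx, ] <- decoder_forward(decoder, x5, Ahat, training = FALSE)$scores
  }
  list(labels = apply(scores, 1, which.max), scores = scores)
}

# stack a list of volume sequences into one (X, Y, Z, 3, N) array
stack_scans <- function(scans) {
  d <- dim(scans[[1]]$data)
  x5 <- array(0, dim = c(d, length(scans)))
  for (i in seq_along(scans)) x5[, , , , i] <- scans[[i]]$data
  x5
}
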