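#' Output extent of a valid convolution or pooling axis
#'
#' `floor((I + 2P - D*(K - 1) - 1) / S) + 1`, the standard output-size rule
#' for a convolution/pooling axis. The architecture uses no padding and no
#' dilation throughout, so `P = 0`, `D = 1`.
#'
#' @param I input extent (positive integer).
#' @param K kernel extent.
#' @param S stride.
#' @param P padding (default 0).
#' @param D dilation (default 1).
#' @param layer optional layer name for error messages.
#' @return integer output extent (>= 1), or an error if the layer is
#'   infeasible for this input.
#' @export
output_size <- function(I, K, S, P = 0, D = 1, layer = NULL) {
  out <- floor((I + 2 * P - D * (K - 1) - 1) / S) + 1
  bad <- out < 1
  if (any(bad))
    stopf("architecture infeasible%s: input extent %s collapses below 1 (K=%s, S=%s)",
          if (is.null(layer)) "" else paste0(" at layer ", layer),
          paste(I[bad], collapse = ","), paste(K, collapse = ","),
          paste(S, collapse = ","))
  as.integer(out)
}

conv_layer <- function(kernel, out_channels) {
  list(kind = "conv", kernel = as.integer(kernel), stride = c(1L, 1L, 1L),
       out_channels = as.integer(out_channels))
}

pool_layer <- function(kernel = c(3L, 3L, 3L), stride = c(2L, 2L, 2L)) {
  list(kind = "pool", kernel = as.integer(kernel), stride = as.integer(stride))
}

#' Configure a per-ROI 3D CNN stream
#'
#' `preset = "default9"` is the default nine-layer architecture for
#' 64 x 64 x 50 inputs: six convolutions (C1..C6) interleaved with three max
#' poolings (S1..S3), kernels 5 x 5 x 3 for C1-C5 and 3 x 3 x 3 for C6
#' (extents given in grid x/y/z order; the 3-long kernel axis runs along the
#' 50-slice z axis), convolution stride 1, pooling kernel 3 with stride 2,
#' output channels 16, 16, 32, 64, 64 and `feature_width`. Each convolution
#' is followed by batch normalisation and ReLU. The layer schedule collapses
#' the grid to 1 x 1 x 1, so the flattened output is the stream's feature
#' vector.
#'
#' `preset = "small"` is a compact desk-scale variant for 12 x 12 x 10 grids
#' (two 3 x 3 x 3 convolutions, two 2 x 2 x 2 poolings) that also collapses
#' to 1 x 1 x 1. Custom architectures (e.g. depth sweeps) can be given via
#' `layers`.
#'
#' @param preset `"default9"` or `"small"`.
#' @param feature_width output channels of the final convolution (the length
#'   of the per-ROI feature vector); 2-12 supported, default 8.
#' @param layers optional explicit layer list overriding the preset (built
#'   from internal `conv_layer()` / `pool_layer()` specs).
#' @return object of class `stream_config`.
#' @export
stream_config <- function(preset = c("default9", "small"), feature_width = 8L,
                          layers = NULL) {
  preset <- match.arg(preset)
  stopifnot(is_count(feature_width), feature_width >= 2, feature_width <= 12)
  if (is.null(layers)) {
    layers <- if (preset == "default9") {
      list(C1 = conv_layer(c(5, 5, 3), 16),
           C2 = conv_layer(c(5, 5, 3), 16),
           S1 = pool_layer(),
           C3 = conv_layer(c(5, 5, 3), 32),
           C4 = conv_layer(c(5, 5, 3), 64),
           S2 = pool_layer(),
           C5 = conv_layer(c(5, 5, 3), 64),
           C6 = conv_layer(c(3, 3, 3), feature_width),
           S3 = pool_layer())
    } else {
      list(C1 = conv_layer(c(3, 3, 3), 8),
           S1 = pool_layer(c(2, 2, 2), c(2, 2, 2)),
           C2 = conv_layer(c(3, 3, 3), feature_width),
           S2 = pool_layer(c(2, 2, 2), c(2, 2, 2)))
    }
  } else {
    last_conv <- max(which(vapply(layers, `[[`, "", "kind") == "conv"))
    layers[[last_conv]]$out_channels <- as.integer(feature_width)
    if (is.null(names(layers)))
      names(layers) <- paste0("L", seq_along(layers))
  }
  structure(list(preset = preset, feature_width = as.integer(feature_width),
                 layers = layers),
            class = "stream_config")
}

#' Per-layer spatial extents of a stream
#'
#' Iterates [output_size()] over the configured layer schedule, axis by axis,
#' and errors if any axis would collapse below one voxel. For the default
#' nine-layer configuration on a `(64, 64, 50)` grid the z axis evolves
#' 50, 48, 46, 22, 20, 18, 8, 6, 4, 1 and each 64 axis evolves
#' 64, 60, 56, 27, 23, 19, 9, 5, 3, 1, so the final grid is 1 x 1 x 1.
#'
#' @param config a [stream_config()].
#' @param input_extents spatial grid `(X, Y, Z)`, default `c(64, 64, 50)`.
#' @return integer matrix, one row per stage (including the input) with
#'   columns X, Y, Z and `channels`.
#' @export
shape_chain <- function(config, input_extents = c(64L, 64L, 50L)) {
  ext <- as.integer(input_extents)
  ch <- 3L
  rows <- list(input = c(ext, ch))
  for (nm in names(config$layers)) {
    l <- config$layers[[nm]]
    ext <- vapply(1:3, function(a)
      output_size(ext[a], l$kernel[a], l$stride[a], layer = nm), integer(1))
    if (l$kind == "conv") ch <- l$out_channels
    rows[[nm]] <- c(ext, ch)
  }
  out <- do.call(rbind, rows)
  colnames(out) <- c("X", "Y", "Z", "channels")
  out
}

#' Build a trainable per-ROI CNN stream
#'
#' Instantiates the configured layers with seeded He-uniform weights (bound
#' `sqrt(6 / fan_in)`), zero biases, and unit-gamma/zero-beta batch
#' normalisation. The stream maps a 3-channel volume batch to an
#' `N x feature_width` matrix by flattening the final 1 x 1 x 1 activation.
#'
#' @param config a [stream_config()].
#' @param input_extents spatial grid the stream will see.
#' @param in_channels input channels (3 time frames).
#' @param seed RNG seed for initialisation.
#' @return object of class `cnn_stream`.
#' @export
build_stream <- function(config, input_extents = c(64L, 64L, 50L),
                         in_channels = 3L, seed = 1L) {
  chain <- shape_chain(config, input_extents) # errors early if infeasible
  set.seed(seed)
  cin <- as.integer(in_channels)
  layers <- list()
  for (nm in names(config$layers)) {
    l <- config$layers[[nm]]
    if (l$kind == "conv") {
      fan_in <- cin * prod(l$kernel)
      l$params <- list(
        W = init_uniform(c(l$kernel, cin, l$out_channels), fan_in),
        b = rep(0, l$out_channels),
        gamma = rep(1, l$out_channels),
        beta = rep(0, l$out_channels))
      l$stats <- list(run_mean = rep(0, l$out_channels),
                      run_var = rep(1, l$out_channels))
      cin <- l$out_channels
    }
    layers[[nm]] <- l
  }
  structure(list(config = config, in_channels = as.integer(in_channels),
                 input_extents = as.integer(input_extents),
                 feature_width = config$feature_width,
                 chain = chain, layers = layers),
            class = "cnn_stream")
}

# forward pass over a 5D batch (X, Y, Z, C, N); caches are kept only when
# training (they hold per-layer inputs for backward)
stream_forward <- function(stream, x5, training = FALSE) {
  n <- dim(x5)[5]
  caches <- list()
  shapes <- list(input = dim(x5)[1:4])
  a <- x5
  for (nm in names(stream$layers)) {
    l <- stream$layers[[nm]]
    if (l$kind == "conv") {
      cf <- conv_fwd(a, l$params$W, l$params$b, l$stride, cache_col = training)
      z <- cf$y
      bnr <- bn5_fwd(z, c(l$params[c("gamma", "beta")], l$stats), training)
      if (training) {
        stream$layers[[nm]]$stats$run_mean <- bnr$bn$run_mean
        stream$layers[[nm]]$stats$run_var <- bnr$bn$run_var
      }
      mask <- bnr$y > 0
      out <- bnr$y * mask
      if (training)
        caches[[nm]] <- list(x = a, xcol = cf$xcol, z = z,
                             mu = bnr$mu, ivar = bnr$ivar, relu_mask = mask)
      a <- out
    } else {
      pr <- pool3d_fwd_cpp(a, l$kernel, l$stride)
      if (training) caches[[nm]] <- list(idx = pr$idx, xdim = dim(a))
      a <- pr$y
    }
    shapes[[nm]] <- dim(a)[1:4]
  }
  w <- dim(a)[4] * prod(dim(a)[1:3])
  out <- t(matrix(a, nrow = w, ncol = n)) # N x feature_width
  list(out = out, stream = stream, caches = caches, shapes = shapes,
       out_dim = dim(a))
}

# backward from d(loss)/d(features) (N x width); returns grads mirroring the
# stream structure plus optionally the input gradient
stream_backward <- function(stream, fwd, gout, want_gx = FALSE) {
  g <- t(gout)
  dim(g) <- fwd$out_dim
  grads <- list()
  lnames <- names(stream$layers)
  for (k in rev(seq_along(lnames))) {
    nm <- lnames[k]
    l <- stream$layers[[nm]]
    cc <- fwd$caches[[nm]]
    if (l$kind == "conv") {
      g <- g * cc$relu_mask
      bnb <- bn5_bwd(g, cc$z, cc$mu, cc$ivar, l$params$gamma)
      gz <- bnb$dx
      need_gx <- want_gx || k > 1
      cb <- conv_bwd(cc$x, l$params$W, gz, l$stride, want_gx = need_gx,
                     xcol = cc$xcol)
      grads[[nm]] <- list(params = list(W = cb$gw, b = cb$gb,
                                        gamma = bnb$dgamma, beta = bnb$dbeta))
      g <- if (need_gx) cb$gx else NULL
    } else {
      g <- pool3d_bwd_cpp(cc$idx, g, cc$xdim)
      grads[nm] <- list(NULL)
    }
  }
  list(grads = list(layers = grads), gx = if (want_gx) g)
}

#' Extract the per-ROI feature matrix of one scan
#'
#' Row `r` is the output of stream `r` applied to the scan masked down to ROI
#' `r`; rows are stacked in the canonical ROI order, giving the 11 x 8
#' feature matrix (for the default width) consumed by the GCN.
#'
#' @param streams list of [build_stream()] models, one per ROI in canonical
#'   order (or a single stream to share across all ROIs).
#' @param scan a [volume_sequence()].
#' @param template an [roi_template()].
#' @return numeric matrix `n_rois x feature_width` with ROI row names.
#' @export
extract_feature_matrix <- function(streams, scan, template) {
  if (inherits(streams, "cnn_stream")) streams <- list(streams)
  nr <- length(roi_names())
  if (!length(streams) %in% c(1L, nr))
    stopf("need 1 shared stream or %d streams, got %d", nr, length(streams))
  width <- streams[[1]]$feature_width
  out <- matrix(0, nr, width, dimnames = list(roi_names(), NULL))
  for (r in seq_len(nr)) {
    masked <- apply_mask(scan, roi_names()[r], template)
    x5 <- masked$data
    dim(x5) <- c(dim(x5), 1L)
    s <- if (length(streams) == 1L) streams[[1]] else streams[[r]]
    out[r, ] <- stream_forward(s, x5, training = FALSE)$out[1, ]
  }
  out
}
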