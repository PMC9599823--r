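#' Bare graph-convolution primitive
#'
#' One spectral graph-convolution step on a single node-feature matrix:
#' `sigma(Ahat %*% H %*% W)` with `sigma = ReLU` (optionally disabled). This
#' is the propagation rule the residual blocks are built around; within a
#' block, batch normalisation and the residual addition are interposed before
#' the activation.
#'
#' @param H node features (`n_nodes x w_in`).
#' @param Ahat normalised adjacency (`n_nodes x n_nodes`), see
#'   [normalize_adjacency()].
#' @param W weight matrix (`w_in x w_out`).
#' @param activation apply ReLU? (default `TRUE`).
#' @return node features `n_nodes x w_out`.
#' @export
gcn_layer <- function(H, Ahat, W, activation = TRUE) {
  if (ncol(Ahat) != nrow(H)) stopf("Ahat is %dx%d but H has %d rows",
                                   nrow(Ahat), ncol(Ahat), nrow(H))
  if (nrow(W) != ncol(H)) stopf("H has %d columns but W has %d rows",
                                ncol(H), nrow(W))
  out <- Ahat %*% H %*% W
  if (activation) out <- relu_fwd(out)
  out
}

#' Configure the residual GCN classifier
#'
#' The network is `n_blocks` convolution blocks, each block applying in order
#' dropout, graph convolution, batch normalisation, and ReLU, with a residual
#' connection of the selected type; the final node features are flattened and
#' classified by one fully connected layer. Residual wirings (`H_in` is the
#' block input, `Z = BN(Ahat %*% dropout(H_in) %*% W)`):
#'
#' * type `"B"` (default): `ReLU(Z + H_in)` - pre-activation addition;
#' * type `"A"`: `ReLU(Z) + H_in` - post-activation addition;
#' * type `"C"`: `ReLU(Z + H_in %*% Wproj)` - addition through a trainable
#'   projection;
#' * `"none"`: `ReLU(Z)` - no skip (the no-residual-connection ablation).
#'
#' @param n_blocks number of blocks (default 5).
#' @param residual_type `"A"`, `"B"`, `"C"` or `"none"`.
#' @param width hidden feature width, constant across blocks (default 8, so
#'   identity skips are always dimension-valid).
#' @param dropout dropout rate at each block input (default 0.5).
#' @param n_classes output classes (default 10).
#' @return object of class `gcn_config`.
#' @export
gcn_config <- function(n_blocks = 5L, residual_type = c("B", "A", "C", "none"),
                       width = 8L, dropout = 0.5, n_classes = 10L) {
  residual_type <- match.arg(residual_type)
  stopifnot(is_count(n_blocks), n_blocks >= 1, is_count(width), width >= 1,
            dropout >= 0, dropout < 1, is_count(n_classes), n_classes >= 2)
  structure(list(n_blocks = as.integer(n_blocks),
                 residual_type = residual_type,
                 width = as.integer(width), dropout = dropout,
                 n_classes = as.integer(n_classes)),
            class = "gcn_config")
}

#' Build the residual GCN classifier
#'
#' @param config a [gcn_config()].
#' @param n_rois number of graph nodes (default 11).
#' @param in_width width of the incoming feature matrix (default
#'   `config$width`). Identity skips (types A and B) require
#'   `in_width == width`; type C projects.
#' @param seed RNG seed for initialisation.
#' @return object of class `gcn_model`.
#' @export
build_gcn <- function(config, n_rois = 11L, in_width = config$width,
                      seed = 1L) {
  if (in_width != config$width && config$residual_type %in% c("A", "B"))
    stopf("residual type %s needs matching widths (in %d vs block %d); use type C",
          config$residual_type, in_width, config$width)
  set.seed(seed)
  blocks <- list()
  win <- as.integer(in_width)
  for (b in seq_len(config$n_blocks)) {
    params <- list(W = init_uniform(c(win, config$width), win))
    if (config$residual_type == "C")
      params$Wproj <- init_uniform(c(win, config$width), win)
    params$gamma <- rep(1, config$width)
    params$beta <- rep(0, config$width)
    blocks[[b]] <- list(params = params,
                        stats = list(run_mean = rep(0, config$width),
                                     run_var = rep(1, config$width)),
                        in_width = win)
    win <- config$width
  }
  head_in <- as.integer(n_rois * config$width)
  head <- list(params = list(W = init_uniform(c(head_in, config$n_classes), head_in),
                             b = rep(0, config$n_classes)))
  structure(list(config = config, n_rois = as.integer(n_rois),
                 in_width = as.integer(in_width),
                 blocks = blocks, head = head),
            class = "gcn_model")
}

# apply Ahat to a stacked node-feature matrix (R*N x w, node index fastest)
ahat_apply <- function(Hmat, Ahat, n_rois, n, width) {
  h3 <- mat_to_t3(Hmat, n_rois, n, width)
  dim(h3) <- c(n_rois, width * n)
  out <- Ahat %*% h3
  dim(out) <- c(n_rois, width, n)
  t3_to_mat(out)
}

# forward over a feature batch F3 (n_rois, width, N); returns class scores
gcn_forward <- function(gcn, F3, Ahat, training = FALSE) {
  cfg <- gcn$config
  nr <- gcn$n_rois
  n <- dim(F3)[3]
  H <- t3_to_mat(F3)
  caches <- list()
  for (b in seq_along(gcn$blocks)) {
    blk <- gcn$blocks[[b]]
    win <- blk$in_width
    dr <- dropout_fwd(H, cfg$dropout, training)
    Z1 <- ahat_apply(dr$y, Ahat, nr, n, win)
    Z2 <- Z1 %*% blk$params$W
    bnr <- bn_fwd(Z2, c(blk$params[c("gamma", "beta")], blk$stats), training)
    if (training) {
      gcn$blocks[[b]]$stats$run_mean <- bnr$bn$run_mean
      gcn$blocks[[b]]$stats$run_var <- bnr$bn$run_var
    }
    pre <- switch(cfg$residual_type,
                  B = bnr$y + H,
                  C = bnr$y + H %*% blk$params$Wproj,
                  bnr$y) # A and none: activation sees Z only
    act <- relu_fwd(pre)
    out <- if (cfg$residual_type == "A") act + H else act
    if (training)
      caches[[b]] <- list(H = H, mask = dr$mask, Z1 = Z1, bn = bnr$cache,
                          relu_mask = pre > 0, win = win)
    H <- out
  }
  # flatten node-major per sample, then the fully connected head
  h3 <- mat_to_t3(H, nr, n, cfg$width)
  flat <- t(matrix(h3, nrow = nr * cfg$width, ncol = n))
  scores <- dense_fwd(flat, gcn$head$params$W, gcn$head$params$b)
  list(scores = scores, gcn = gcn,
       cache = if (training) list(blocks = caches, flat = flat, n = n))
}

gcn_backward <- function(gcn, cache, gscores, Ahat) {
  cfg <- gcn$config
  nr <- gcn$n_rois
  n <- cache$n
  db <- dense_bwd(cache$flat, gcn$head$params$W, gscores)
  grads <- list(blocks = vector("list", length(gcn$blocks)),
                head = list(params = list(W = db$gW, b = db$gb)))
  gflat <- db$gx # N x (nr*width)
  g3 <- array(t(gflat), dim = c(nr, cfg$width, n))
  gH <- t3_to_mat(g3)
  for (b in rev(seq_along(gcn$blocks))) {
    blk <- gcn$blocks[[b]]
    cc <- cache$blocks[[b]]
    gH_in <- matrix(0, nrow(cc$H), ncol(cc$H))
    if (cfg$residual_type == "A") {
      gH_in <- gH_in + gH # skip path
      gact <- gH
    } else {
      gact <- gH
    }
    gpre <- gact * cc$relu_mask
    if (cfg$residual_type == "B") gH_in <- gH_in + gpre
    gbn_out <- gpre
    if (cfg$residual_type == "C") {
      grads$blocks[[b]]$params$Wproj <- crossprod(cc$H, gpre)
      gH_in <- gH_in + gpre %*% t(blk$params$Wproj)
    }
    bnb <- bn_bwd(gbn_out, cc$bn)
    gZ2 <- bnb$dx
    gW <- crossprod(cc$Z1, gZ2)
    gZ1 <- gZ2 %*% t(blk$params$W)
    gdrop <- ahat_apply(gZ1, t(Ahat), nr, n, cc$win)
    gH_in <- gH_in + dropout_bwd(gdrop, cc$mask)
    grads$blocks[[b]]$params$W <- gW
    grads$blocks[[b]]$params$gamma <- bnb$dgamma
    grads$blocks[[b]]$params$beta <- bnb$dbeta
    gH <- gH_in
  }
  gF3 <- mat_to_t3(gH, nr, n, gcn$in_width)
  list(grads = grads, gF3 = gF3)
}
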