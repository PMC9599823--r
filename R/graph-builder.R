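#' Pearson correlation between two ROI signals
#'
#' Standard sample Pearson r. Constant inputs have no defined correlation;
#' by default this is an error, but callers building adjacencies from short
#' degenerate signals may ask for 0 instead (with a warning).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param on_constant `"error"` (default) or `"zero"`.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y, on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  if (length(x) != length(y) || length(x) < 2)
    stopf("pearson needs two equal-length vectors of length >= 2")
  if (sd(x) == 0 || sd(y) == 0) {
    if (on_constant == "zero") {
      warning("constant signal: substituting correlation 0")
      return(0)
    }
    stopf("degenerate signal: constant input has no defined correlation")
  }
  cor(x, y)
}

#' Build the group-weighted functional-connectivity adjacency
#'
#' Entry `a_ij = w_ij * P(r_i, r_j)` where `P` is the Pearson correlation
#' between the ROI signals and the weight is `omega` when both ROIs belong to
#' the same group (low-level vs medium/high-level visual regions), 1 across
#' groups, and 0 on the diagonal. By default `|P|` is used so that the
#' symmetric normalisation is always real-valued; set `signed = TRUE` to keep
#' the sign. `type = "plain_pearson"` drops the group weighting
#' (equivalently `omega = 1`); `type = "random"` draws a seeded random
#' symmetric matrix as an ablation control.
#'
#' @param roi_signals matrix with one row per ROI in canonical order (11 x L,
#'   L >= 2), or a list of 11 numeric vectors.
#' @param groups named group map as from [roi_groups()].
#' @param omega within-group weight (default 3).
#' @param signed keep the sign of the correlation? (default `FALSE`).
#' @param type adjacency flavour, see above.
#' @param on_constant passed to [pearson()].
#' @param seed seed for `type = "random"`.
#' @return object of class `adjacency_matrix`: fields `A` (11 x 11), `omega`,
#'   `groups`, `type`, `signed`.
#' @export
build_adjacency <- function(roi_signals, groups = roi_groups(), omega = 3,
                            signed = FALSE,
                            type = c("weighted_pearson", "plain_pearson", "random"),
                            on_constant = "error", seed = 1L) {
  type <- match.arg(type)
  if (is.list(roi_signals)) roi_signals <- do.call(rbind, roi_signals)
  nr <- length(groups)
  if (type != "random" && nrow(roi_signals) != nr)
    stopf("expected %d ROI signals, got %d", nr, nrow(roi_signals))
  A <- matrix(0, nr, nr, dimnames = list(names(groups), names(groups)))
  if (type == "random") {
    set.seed(seed)
    u <- matrix(runif(nr * nr), nr, nr)
    A <- (u + t(u)) / 2
    diag(A) <- 0
  } else {
    for (i in seq_len(nr - 1)) {
      for (j in (i + 1):nr) {
        p <- pearson(roi_signals[i, ], roi_signals[j, ], on_constant = on_constant)
        if (!signed) p <- abs(p)
        w <- if (type == "plain_pearson") 1
             else if (groups[i] == groups[j]) omega else 1
        A[i, j] <- A[j, i] <- w * p
      }
    }
  }
  structure(list(A = A, omega = omega, groups = groups, type = type,
                 signed = signed),
            class = "adjacency_matrix")
}

#' Symmetric normalisation of an adjacency matrix
#'
#' Computes `Ahat = Dtilde^(-1/2) (A + I) Dtilde^(-1/2)` with
#' `Dtilde_ii = sum_j (A + I)_ij`, the propagation operator of the graph
#' convolution. With non-negative `A` every eigenvalue of `Ahat` lies in
#' `[-1, 1]`; a non-positive generalised degree (possible with signed
#' correlations) has no real square root and is an error.
#'
#' @param A an `adjacency_matrix` or a plain square numeric matrix.
#' @return the normalised matrix (plain matrix, symmetric).
#' @export
normalize_adjacency <- function(A) {
  if (inherits(A, "adjacency_matrix")) A <- A$A
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  At <- A + diag(nrow(A))
  dd <- rowSums(At)
  if (any(dd <= 0))
    stopf("non-normalizable adjacency: generalized degree <= 0 at node(s) %s",
          paste(which(dd <= 0), collapse = ", "))
  s <- 1 / sqrt(dd)
  out <- At * outer(s, s)
  (out + t(out)) / 2 # enforce exact symmetry against rounding
}

#' Adjacency from a set of training scans
#'
#' Computes each ROI's mean time course (3 points per scan) on every supplied
#' scan, concatenates them in scan order into one signal per ROI, and calls
#' [build_adjacency()]. Pass training-subject scans only: the graph is built
#' once from the training set and then frozen for training and inference.
#'
#' @param scans list of [volume_sequence()] (training scans only).
#' @param template an [roi_template()].
#' @param ... passed to [build_adjacency()].
#' @return an `adjacency_matrix`.
#' @export
adjacency_from_scans <- function(scans, template, ...) {
  sig <- vapply(roi_names(), function(nm)
    unlist(lapply(scans, roi_mean_timecourse, roi = nm, template = template)),
    numeric(3 * length(scans)))
  build_adjacency(t(sig), ...)
}

#' Write / read an adjacency matrix as CSV
#'
#' 11 x 11 matrix with ROI names as header row and column.
#'
#' @param adj an `adjacency_matrix` or plain matrix.
#' @param path CSV path.
#' @return `write_adjacency()`: invisibly, `path`; `read_adjacency()`: matrix.
#' @export
write_adjacency <- function(adj, path) {
  A <- if (inherits(adj, "adjacency_matrix")) adj$A else adj
  write.csv(A, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
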