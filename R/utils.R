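`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes integer identifiers (for instance subject, class and repetition
#' indices) into a master seed with a Lehmer-style multiplicative hash so that
#' every generated object gets its own stable RNG stream. All arithmetic stays
#' exact in doubles and the result fits a 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param ... integer identifiers to mix in.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (i in ids) h <- (h * 69069 + i + 1) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# reshape an (R, w, N) node-feature array to an (R*N, w) matrix whose rows are
# node-within-sample (node index fastest) ...
t3_to_mat <- function(h3) {
  d <- dim(h3)
  m <- aperm(h3, c(1L, 3L, 2L))
  dim(m) <- c(d[1] * d[3], d[2])
  m
}

# ... and back
mat_to_t3 <- function(m, n_nodes, n_samples, width) {
  dim(m) <- c(n_nodes, n_samples, width)
  aperm(m, c(1L, 3L, 2L))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x) && x >= 0
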