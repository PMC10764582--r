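# Internal helpers: deterministic seed substreams, PSD-aware multivariate
# normal draws, and a light logging shim.

# 31-bit string hash (polynomial rolling hash); used to derive independent
# seed substreams from a master seed plus a tag, so that enabling or
# disabling one randomized stage never perturbs another's stream.
.hash31 <- function(x) {
  x <- as.character(x)
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Derive a child seed (< 2^31) from a master seed and a character tag.
substream_seed <- function(seed, tag) {
  seed <- as.integer(seed) %% 2147483647L
  as.integer((as.double(seed) * 48271 + .hash31(tag)) %% 2147483647)
}

# Multivariate normal draws via pivoted Cholesky so that PSD (rank-deficient
# or exactly zero) covariance matrices are handled without error.
.rmvnorm_psd <- function(n, mean, sigma) {
  p <- length(mean)
  stopifnot(nrow(sigma) == p, ncol(sigma) == p)
  if (all(sigma == 0)) {
    return(matrix(rep(mean, each = n), nrow = n,
                  dimnames = list(NULL, names(mean))))
  }
  sigma <- (sigma + t(sigma)) / 2
  ch <- suppressWarnings(chol(sigma, pivot = TRUE))
  r <- attr(ch, "rank")
  piv <- attr(ch, "pivot")
  if (r < p) {
    ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8 * max(abs(diag(sigma)), 1)) {
      stop("covariance matrix is not positive semi-definite; ",
           "consider a nearest-PSD repair before sampling", call. = FALSE)
    }
    ch[seq(r + 1, p), ] <- 0
  }
  z <- matrix(stats::rnorm(n * p), nrow = n)
  out <- z %*% ch[, order(piv), drop = FALSE]
  out <- sweep(out, 2, mean, "+")
  colnames(out) <- names(mean)
  out
}

# Minimal level-aware logger. Verbosity is a package option:
# options(mird.verbose = TRUE) narrates pipeline stages with counts.
mird_log <- function(..., verbose = getOption("mird.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[mird] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
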