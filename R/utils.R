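# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible integer seed from a master seed and a string key
#'
#' Used so that per-source-node random streams do not depend on iteration
#' order. The result is always in [1, 2^31 - 2].
#'
#' @param master integer master seed.
#' @param key character key naming the stream.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(master, key) {
  h <- 0
  for (cc in utf8ToInt(as.character(key))) {
    h <- (h * 31 + cc) %% 2147483647
  }
  as.integer((as.numeric(master) * 1000003 + h) %% 2147483629 + 1)
}

# Trapezoid rule on an ascending grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Smallest-eigenvalue eigenvectors of many symmetric 2x2 matrices at once.
# a, b, c are vectors of the entries [[a, b], [b, c]]. Returns a list with
# components v1, v2 (unnormalised eigenvector coordinates) and lmin.
eig2_smallest <- function(a, b, c) {
  tr <- a + c
  disc <- sqrt(pmax((a - c)^2 + 4 * b^2, 0))
  lmin <- (tr - disc) / 2
  # (A - lmin I) v = 0 -> v is orthogonal to the larger row of (A - lmin I)
  r1 <- abs(a - lmin) + abs(b)
  r2 <- abs(b) + abs(c - lmin)
  use1 <- r1 >= r2
  v1 <- ifelse(use1, -b, -(c - lmin))
  v2 <- ifelse(use1, a - lmin, b)
  nrm <- sqrt(v1^2 + v2^2)
  zero <- nrm < .Machine$double.eps
  # degenerate (isotropic) case: direction undetermined, fix to (1, 0)
  v1[zero] <- 1
  v2[zero] <- 0
  nrm[zero] <- 1
  list(v1 = v1 / nrm, v2 = v2 / nrm, lmin = lmin)
}
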