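#' Multiplicative zero replacement
#'
#' Replaces zeros in a raw composition by a small proportion `epsilon` and
#' rescales the nonzero parts so the result is a strictly positive composition
#' summing to one. This is the standard multiplicative replacement: ratios
#' among nonzero parts are preserved exactly.
#'
#' @param x Numeric vector of nonnegative parts, or a matrix with compositions
#'   in columns (features x samples).
#' @param epsilon Proportion assigned to each zero part (default `1e-6`).
#' @return Object of the same shape with strictly positive entries; each
#'   composition sums to 1.
#' @examples
#' zero_replace(c(0.5, 0.5, 0))
#' @export
zero_replace <- function(x, epsilon = 1e-6) {
  if (is.matrix(x)) {
    out <- apply(x, 2, zero_replace, epsilon = epsilon)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (any(x < 0)) stop("composition has negative parts")
  s <- sum(x)
  if (s <= 0) stop("all-zero composition cannot be zero-replaced")
  x <- x / s
  nz <- x > 0
  n0 <- sum(!nz)
  if (n0 == 0L) return(x)
  if (epsilon * n0 >= 1) {
    stop("epsilon * number_of_zeros >= 1; replacement would exhaust the simplex")
  }
  x[!nz] <- epsilon
  x[nz] <- x[nz] * (1 - n0 * epsilon)
  x
}

#' Centered log-ratio transform
#'
#' `clr(x)_i = log(x_i / g(x))` with `g(x)` the geometric mean of the sample,
#' so coordinates sum to zero. Scale-invariant: multiplying a composition by a
#' positive constant leaves the clr unchanged.
#'
#' @param x Strictly positive numeric vector, or matrix with samples in columns.
#' @return clr coordinates, same shape as input.
#' @export
clr <- function(x) {
  if (is.matrix(x)) {
    if (any(x <= 0)) stop("clr requires strictly positive parts")
    lx <- log(x)
    return(sweep(lx, 2, colMeans(lx)))
  }
  if (any(x <= 0)) stop("clr requires strictly positive parts")
  lx <- log(x)
  lx - mean(lx)
}

#' Additive log-ratio transform
#'
#' `alr(x)_i = log(x_i / x_ref)` for all parts except the reference, which is
#' omitted. The choice of reference is arbitrary; downstream summaries are
#' converted to clr coordinates so results do not depend on it.
#'
#' @param x Strictly positive vector, or matrix with samples in columns.
#' @param ref Index of the reference part (default: last part).
#' @return Vector of length D-1 (or (D-1) x N matrix) of log ratios.
#' @export
alr <- function(x, ref = NULL) {
  D <- if (is.matrix(x)) nrow(x) else length(x)
  if (is.null(ref)) ref <- D
  if (ref < 1 || ref > D) stop("alr reference index out of range")
  if (any(x <= 0)) stop("alr requires strictly positive parts")
  if (is.matrix(x)) {
    lx <- log(x)
    out <- sweep(lx[-ref, , drop = FALSE], 2, lx[ref, ])
    return(out)
  }
  lx <- log(x)
  lx[-ref] - lx[ref]
}

#' Inverse additive log-ratio (softmax) transform
#'
#' Re-inserts a zero at the reference slot, exponentiates and closes to sum 1.
#' Output is always a strictly positive composition.
#'
#' @param y alr coordinates: vector of length D-1 or (D-1) x N matrix.
#' @param ref Reference slot index in the reconstructed composition
#'   (default: last).
#' @return Composition of D parts (vector or D x N matrix) summing to 1.
#' @export
alr_inv <- function(y, ref = NULL) {
  if (is.matrix(y)) {
    D <- nrow(y) + 1L
    if (is.null(ref)) ref <- D
    full <- matrix(0, D, ncol(y))
    full[-ref, ] <- y
    e <- exp(sweep(full, 2, apply(full, 2, max)))  # guard overflow
    out <- sweep(e, 2, colSums(e), "/")
    colnames(out) <- colnames(y)
    return(out)
  }
  D <- length(y) + 1L
  if (is.null(ref)) ref <- D
  full <- numeric(D)
  full[-ref] <- y
  e <- exp(full - max(full))
  e / sum(e)
}

#' Convert alr-coordinate coefficients to clr coordinates
#'
#' A coefficient matrix estimated in an alr system (rows = D-1 log-ratio
#' coordinates) is mapped to the clr system by inserting a zero row at the
#' reference slot and centering each column to mean zero (left-multiplying by
#' `I - J/D`). Applied per posterior draw, this makes coefficient summaries
#' independent of the alr reference.
#'
#' @param M (D-1) x Q numeric matrix of coefficients in alr coordinates.
#' @param ref Reference slot index (default: last of the D rows).
#' @return D x Q matrix in clr coordinates; every column sums to zero.
#' @export
alr_to_clr_coeffs <- function(M, ref = NULL) {
  if (!is.matrix(M)) M <- matrix(M, ncol = 1)
  if (any(!is.finite(M))) stop("coefficient matrix has non-finite entries")
  D <- nrow(M) + 1L
  if (is.null(ref)) ref <- D
  full <- matrix(0, D, ncol(M))
  full[-ref, ] <- M
  out <- sweep(full, 2, colMeans(full))
  colnames(out) <- colnames(M)
  out
}
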