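## Spherical-spline current source density (surface Laplacian). The scalp
## potential is interpolated with a spherical spline (Perrin-style): solve
## (G + lambda I) c + c0 = v subject to sum(c) = 0, then apply the Laplacian
## kernel, CSD = H c. The kernels are Legendre series
##   g(x) = 1/(4 pi) sum_n (2n+1) / (n (n+1))^m            P_n(x)
##   h(x) = 1/(4 pi) sum_n (2n+1) / (n (n+1))^(m-1)        P_n(x)
## evaluated at x = cos(angle between electrodes). The head radius scale is
## left at 1 (unitless CSD): only relative power matters downstream.

## Legendre polynomials P_1..P_nmax evaluated at a matrix x, returned as a
## list; three-term recurrence
.legendreSeries <- function(x, nmax, coefG, coefH) {
  Pm2 <- array(1, dim(x))      # P_0
  Pm1 <- x                     # P_1
  G <- coefG[1] * Pm1
  H <- coefH[1] * Pm1
  for (n in 2:nmax) {
    Pn <- ((2 * n - 1) * x * Pm1 - (n - 1) * Pm2) / n
    G <- G + coefG[n] * Pn
    H <- H + coefH[n] * Pn
    Pm2 <- Pm1
    Pm1 <- Pn
  }
  list(G = G / (4 * pi), H = H / (4 * pi))
}

#' Build a spherical-spline basis for CSD estimation
#'
#' Precomputes the spline matrices and the linear CSD transform for a fixed
#' electrode set. Defaults (m = 4, lambda = 1e-5, 50 series terms) are
#' conventional spherical-spline settings.
#'
#' @param montage montage data.frame restricted to the channels the basis is
#'   for (at least 8, unique positions).
#' @param m spline stiffness order (integer >= 2).
#' @param lambda ridge regularizer added to G before solving.
#' @param nTerms number of Legendre series terms (>= 20).
#' @return a \linkS4class{SplineBasis}.
#' @examples
#' basis <- buildSplineBasis(defaultMontage()[1:12, ])
#' basis
#' @export
buildSplineBasis <- function(montage, m = 4, lambda = 1e-5, nTerms = 50) {
  if (m < 2) stop("spline order m must be >= 2")
  if (nTerms < 20) stop("nTerms must be >= 20")
  if (nrow(montage) < 8)
    stop("at least 8 channels are required to build a spline basis")
  xyz <- montagePositions(montage)
  cosang <- pmin(pmax(tcrossprod(xyz), -1), 1)  # keep matrix attributes
  offdiag <- cosang[upper.tri(cosang)]
  if (any(offdiag > 1 - 1e-10)) {
    idx <- which(cosang > 1 - 1e-10 & upper.tri(cosang), arr.ind = TRUE)
    stop("duplicate electrode positions: ",
         paste(montage$label[idx[1, 1]], montage$label[idx[1, 2]],
               sep = " / "))
  }
  n <- seq_len(nTerms)
  coefG <- (2 * n + 1) / (n * (n + 1))^m
  coefH <- (2 * n + 1) / (n * (n + 1))^(m - 1)
  gh <- .legendreSeries(cosang, nTerms, coefG, coefH)
  if (!all(is.finite(gh$G)) || !all(is.finite(gh$H)))
    stop("spline matrices are not finite")
  nc <- nrow(montage)
  ## augmented system enforcing the mean constraint sum(c) = 0
  A <- rbind(cbind(gh$G + lambda * diag(nc), rep(1, nc)),
             c(rep(1, nc), 0))
  Ainv <- solve(A)
  transform <- gh$H %*% Ainv[seq_len(nc), seq_len(nc)]
  new("SplineBasis", G = gh$G, H = gh$H, m = m, lambda = lambda,
      nTerms = nTerms, labels = montage$label, transform = transform)
}

#' Evaluate the spline kernels g and h at given cosine angles
#'
#' Exposed mainly for verification: the series can be checked directly, e.g.
#' g(1) equals the analytic series sum.
#'
#' @param x cosine of the inter-electrode angle(s), in [-1, 1].
#' @param m spline order.
#' @param nTerms series length.
#' @return list with numeric \code{g} and \code{h} of the same shape as x.
#' @export
splineKernels <- function(x, m = 4, nTerms = 50) {
  n <- seq_len(nTerms)
  coefG <- (2 * n + 1) / (n * (n + 1))^m
  coefH <- (2 * n + 1) / (n * (n + 1))^(m - 1)
  gh <- .legendreSeries(as.matrix(x), nTerms, coefG, coefH)
  list(g = gh$G[, , drop = TRUE] , h = gh$H[, , drop = TRUE])
}

#' Apply the CSD transform
#'
#' Transforms scalp potentials to current source density. The operation is
#' linear and reference-free: adding a constant to all input channels leaves
#' the output unchanged, and a constant field maps to exactly zero.
#'
#' @param x an \linkS4class{EpochSet}, \linkS4class{Recording}, or a
#'   channels x samples matrix.
#' @param basis a \linkS4class{SplineBasis} whose channel set matches
#'   \code{x} exactly (same order).
#' @return object of the same class with CSD values (unitless; microvolts per
#'   squared head radius up to scale).
#' @export
setGeneric("csdTransform", function(x, basis) standardGeneric("csdTransform"))

.checkCsdChannels <- function(labels, basis) {
  if (!identical(as.character(labels), as.character(basis@labels)))
    stop("channel set/order of the data does not match the spline basis; ",
         "use selectChannels() first")
}

#' @rdname csdTransform
setMethod("csdTransform", "matrix", function(x, basis) {
  if (nrow(x) != nrow(basis@transform))
    stop("channel count does not match the spline basis")
  if (!all(is.finite(x))) stop("non-finite values in input data")
  basis@transform %*% x
})

#' @rdname csdTransform
setMethod("csdTransform", "Recording", function(x, basis) {
  .checkCsdChannels(x@labels, basis)
  if (!all(is.finite(x@data))) stop("non-finite values in input data")
  newRecording(basis@transform %*% x@data, x@sfreq, x@labels, x@events)
})

#' @rdname csdTransform
setMethod("csdTransform", "EpochSet", function(x, basis) {
  .checkCsdChannels(x@labels, basis)
  d <- dim(x@data)
  if (!all(is.finite(x@data))) stop("non-finite values in input data")
  ## channels x (trials * time) multiply, then back
  m <- aperm(x@data, c(2, 1, 3))
  dim(m) <- c(d[2], d[1] * d[3])
  m <- basis@transform %*% m
  dim(m) <- c(d[2], d[1], d[3])
  new("EpochSet", data = aperm(m, c(2, 1, 3)), times = x@times,
      sfreq = x@sfreq, labels = x@labels, trials = x@trials)
})
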