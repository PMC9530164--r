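#' Connectivity matched to omnivorous assembly
#'
#' Expected connectivity of an omnivorous food web of richness `N` assembled
#' with a 1:2 producer ratio and a second-resource probability of 1/2,
#' assuming no extinctions: `p(N) = (N^2 + 21 N - 28) / (9 N (N - 1))`.
#' The formula exceeds 1 for very small `N` (it equals 1 at `N = 2`), so the
#' value is clipped to `[0, 1]`.
#'
#' @param N species richness (matrix dimension), integer > 1.
#' @return connectivity in `[0, 1]`.
#' @export
connectivity <- function(N) {
  if (any(N <= 1)) stop("connectivity is defined for N > 1")
  p <- (N^2 + 21 * N - 28) / (9 * N * (N - 1))
  pmin(pmax(p, 0), 1)
}

#' Specification of a random community-matrix ensemble
#'
#' The null model against which evolved spectra are compared: `N x N`
#' matrices with diagonal fixed at `d` (self-regulation, default -1) and
#' off-diagonal entries standard normal with probability `connectivity`
#' (matched to omnivorous assembly by default), zero otherwise.
#'
#' @param size matrix dimension `N >= 2`.
#' @param samples number of matrices in the ensemble.
#' @param diagonal common diagonal value `d`.
#' @param p connectivity; defaults to [connectivity()] of `size`.
#' @param seed RNG seed used by [ensemble_spectrum()].
#' @return list of class `random_ensemble_spec`.
#' @export
random_ensemble_spec <- function(size, samples = 1e4, diagonal = -1,
                                 p = connectivity(size), seed = 1L) {
  if (size < 2) stop("`size` must be at least 2")
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (samples < 1) stop("`samples` must be positive")
  structure(list(size = as.integer(size), samples = as.integer(samples),
                 diagonal = diagonal, p = p, seed = as.integer(seed)),
            class = "random_ensemble_spec")
}

#' Draw one matrix from the random ensemble
#'
#' @param spec a [random_ensemble_spec()].
#' @return a `size` x `size` numeric matrix.
#' @export
sample_random_matrix <- function(spec) {
  n <- spec$size
  m <- matrix(0, n, n)
  off <- which(row(m) != col(m))
  on <- stats::runif(length(off)) < spec$p
  m[off[on]] <- stats::rnorm(sum(on))
  diag(m) <- spec$diagonal
  m
}

#' Pooled eigenvalue spectrum of a random ensemble
#'
#' Draws `spec$samples` matrices and pools all their eigenvalues under the
#' richness key `size`.  The trace identity guarantees that each sample's
#' eigenvalues sum to `size * diagonal` exactly (up to round-off).
#'
#' @param spec a [random_ensemble_spec()].
#' @return a `spectrum_set` with the single richness key `spec$size`.
#' @export
ensemble_spectrum <- function(spec) {
  set.seed(spec$seed)
  n <- spec$size
  vals <- vector("list", spec$samples)
  for (s in seq_len(spec$samples))
    vals[[s]] <- eigen(sample_random_matrix(spec), only.values = TRUE)$values
  out <- list(unlist(vals))
  names(out) <- as.character(n)
  structure(out, class = "spectrum_set")
}
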