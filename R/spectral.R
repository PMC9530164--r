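#' Two-species consumer--resource system
#'
#' The only feasible two-species web is one producer plus one consumer.
#' Its community matrix is small enough to diagonalise by hand, which makes
#' it the natural laboratory for understanding where purely real eigenvalues
#' come from.  `gamma = alpha2 / (1 - alpha1/k)` acts as the inverse
#' intrinsic fitness of the pair: feasibility requires the consumption rate
#' `beta_eta` to exceed `gamma`.
#'
#' @param alpha1 producer decay rate (must satisfy `alpha1 < k`).
#' @param alpha2 consumer decay rate.
#' @param beta_eta consumption rate, the product of efficiency and link
#'   strength.
#' @param k producer growth rate.
#' @return list of class `two_species_system` with fields `alpha1`,
#'   `alpha2`, `beta_eta`, `k`, `gamma`, `feasible`.
#' @export
two_species_system <- function(alpha1, alpha2, beta_eta, k = 1) {
  if (alpha1 >= k) stop("producer cannot persist: alpha1 must be < k")
  if (alpha2 <= 0 || beta_eta <= 0) stop("rates must be positive")
  gamma <- alpha2 / (1 - alpha1 / k)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, beta_eta = beta_eta,
                 k = k, gamma = gamma, feasible = beta_eta > gamma),
            class = "two_species_system")
}

#' Closed-form eigenvalues of the two-species community matrix
#'
#' At the feasible fixed point `S1* = alpha2 / beta_eta`,
#' `S2* = (k (1 - S1*) - alpha1) / eta`, the community matrix is
#' `[[-k S1*, -eta S1*], [beta_eta S2*, 0]]`, giving
#' `lambda = (-k S1* +- sqrt(k^2 S1*^2 - 4 beta_eta eta S1* S2*)) / 2`.
#' The product `eta S2*` equals `k (1 - S1*) - alpha1`, so the eigenvalues
#' depend on the link only through `beta_eta` and the result holds for any
#' split of the consumption rate into efficiency and strength.
#'
#' @param sys a feasible [two_species_system()].
#' @return complex vector `c(lambda_plus, lambda_minus)` (descending real
#'   part).
#' @export
two_species_eigenvalues <- function(sys) {
  if (!sys$feasible)
    stop("system is infeasible (beta_eta <= gamma); no coexistence point")
  s1 <- sys$alpha2 / sys$beta_eta
  eta_s2 <- sys$k * (1 - s1) - sys$alpha1     # = eta * S2*
  tr <- -sys$k * s1
  det <- sys$beta_eta * s1 * eta_s2
  disc <- as.complex(tr^2 - 4 * det)
  lam <- (tr + c(1, -1) * sqrt(disc)) / 2
  lam[order(-Re(lam))]
}

#' Purely-real criterion for the two-species spectrum
#'
#' Both eigenvalues of the two-species community matrix are purely real iff
#' `beta_eta <= (gamma + sqrt(gamma^2 + k gamma)) / 2`: consumption moderate
#' relative to the pair's intrinsic fitness puts the system in an
#' over-damped regime, while heavier exploitation produces a complex
#' conjugate pair and oscillatory relaxation.
#'
#' @param sys a feasible [two_species_system()].
#' @return logical.
#' @export
purely_real_condition <- function(sys) {
  if (!sys$feasible) stop("system is infeasible")
  sys$beta_eta <= (sys$gamma + sqrt(sys$gamma^2 + sys$k * sys$gamma)) / 2
}

#' Fraction of purely real eigenvalues
#'
#' @param eigenvalues complex vector (non-empty).
#' @param tol absolute tolerance on the imaginary part below which an
#'   eigenvalue counts as purely real (default 1e-9).
#' @return fraction in `[0, 1]`.
#' @export
purely_real_fraction <- function(eigenvalues, tol = 1e-9) {
  if (length(eigenvalues) == 0L) stop("need at least one eigenvalue")
  mean(abs(Im(eigenvalues)) < tol)
}

#' Scale eigenvalue real parts so the support starts at -1
#'
#' Divides the real parts by the magnitude of the most negative one, the
#' normalisation used to compare the functional form of real-part
#' distributions across web structures and richnesses.  Idempotent: scaling
#' a scaled set changes nothing.
#'
#' @param eigenvalues complex or numeric vector with at least one negative
#'   real part.
#' @return numeric vector of scaled real parts (minimum is -1).
#' @export
scale_real_parts <- function(eigenvalues) {
  x <- Re(eigenvalues)
  m <- min(x)
  if (m >= 0) stop("scaling requires at least one negative real part")
  x / abs(m)
}

#' Real-part distribution of a spectrum, scaled to start at -1
#'
#' @param eigenvalues complex vector (non-empty, some negative real part).
#' @param bins number of equal-width bins.
#' @return data frame with `bin_left`, `bin_right`, `mass` (sums to 1);
#'   attribute `breaks` carries the bin edges.
#' @export
real_part_distribution <- function(eigenvalues, bins = 100L) {
  x <- scale_real_parts(eigenvalues)
  hi <- max(x, 0)
  breaks <- seq(-1, hi, length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  out <- data.frame(bin_left = breaks[-length(breaks)],
                    bin_right = breaks[-1], mass = cnt / sum(cnt))
  attr(out, "breaks") <- breaks
  out
}

#' Two-dimensional histogram of a spectrum in the complex plane
#'
#' @param eigenvalues complex vector (non-empty).
#' @param re_bins,im_bins number of bins along each axis.
#' @return list with `counts` (`re_bins` x `im_bins` matrix), `re_breaks`,
#'   `im_breaks`.
#' @export
complex_plane_histogram <- function(eigenvalues, re_bins = 100L,
                                    im_bins = 100L) {
  if (length(eigenvalues) == 0L) stop("need at least one eigenvalue")
  re <- Re(eigenvalues); im <- Im(eigenvalues)
  pad <- function(r) if (diff(r) == 0) r + c(-5e-13, 5e-13) else r
  re_breaks <- seq(pad(range(re))[1], pad(range(re))[2],
                   length.out = re_bins + 1L)
  im_breaks <- seq(pad(range(im))[1], pad(range(im))[2],
                   length.out = im_bins + 1L)
  ri <- findInterval(re, re_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ii <- findInterval(im, im_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, re_bins, im_bins)
  for (j in seq_along(ri))
    counts[ri[j], ii[j]] <- counts[ri[j], ii[j]] + 1L
  list(counts = counts, re_breaks = re_breaks, im_breaks = im_breaks)
}

#' Pool recorded spectra by species richness
#'
#' Collects the eigenvalues recorded during one or more assembly runs (or
#' random ensembles) into a single map from richness to eigenvalues, the
#' shape used for richness-resolved spectral statistics across modes and
#' efficiencies.
#'
#' @param ... `evolution_history` objects, `spectrum_set`s, or data frames
#'   with columns `richness`, `re`, `im`.
#' @param min_richness drop eigenvalues of webs below this richness.
#' @return An object of class `spectrum_set`: list of complex vectors named
#'   by richness.
#' @export
pool_spectra <- function(..., min_richness = 2L) {
  inputs <- list(...)
  frames <- lapply(inputs, function(x) {
    if (inherits(x, "evolution_history")) return(x$eigenvalues)
    if (inherits(x, "spectrum_set")) {
      return(data.frame(
        richness = rep(as.integer(names(x)), lengths(x)),
        re = Re(unlist(x, use.names = FALSE)),
        im = Im(unlist(x, use.names = FALSE))))
    }
    stopifnot(is.data.frame(x), all(c("richness", "re", "im") %in% names(x)))
    x
  })
  df <- do.call(rbind, lapply(frames, function(f)
    f[f$richness >= min_richness, c("richness", "re", "im")]))
  sets <- lapply(split(df, df$richness),
                 function(g) complex(real = g$re, imaginary = g$im))
  structure(sets, class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set>\n")
  for (nm in names(x))
    cat(sprintf("  richness %s: %d eigenvalues\n", nm, length(x[[nm]])))
  invisible(x)
}
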