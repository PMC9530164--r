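#' Construct a food web
#'
#' A `food_web` is the full state of a consumer--resource community under
#' generalised Lotka--Volterra (GLV) dynamics with a single implicit basic
#' nutrient source.  Primary producers draw on the nutrient through a shared
#' logistic term (growth rate `k`, carrying capacity 1); consumers feed on
#' other species through Holling type-I links of strength `eta[consumer,
#' resource]`, converting consumed biomass with a single web-wide efficiency
#' `beta`.
#'
#' Biomasses are normalised to the carrying capacity of the nutrient source.
#' The nutrient itself is not a dynamical variable: its depletion is encoded
#' by the logistic term shared by all producers.
#'
#' @param alpha numeric vector of per-species decay rates (must be > 0).
#' @param is_producer logical vector flagging primary producers.
#' @param eta square numeric matrix of interaction strengths;
#'   `eta[k, m] > 0` iff consumer `k` eats resource `m`.  Producer rows must
#'   be zero (producers consume only the nutrient) and the diagonal must be
#'   zero (no cannibalism).
#' @param beta consumption efficiency shared by every link, in (0, 1].
#' @param k producer growth rate (shared; the unit of time is `1/k`).
#' @param biomass numeric vector of current biomass densities (>= 0).
#' @param id optional integer vector of stable species identifiers, used to
#'   track individuals across invasions and extinctions.
#'
#' @return An object of class `food_web`: a list with elements `alpha`,
#'   `is_producer`, `eta`, `beta`, `k`, `biomass`, `id`.
#' @export
food_web <- function(alpha, is_producer, eta, beta, k = 1,
                     biomass = NULL, id = NULL) {
  n <- length(alpha)
  if (n == 0L) {
    eta <- matrix(numeric(0), 0L, 0L)
    is_producer <- logical(0)
  }
  if (!is.matrix(eta) || nrow(eta) != n || ncol(eta) != n)
    stop("`eta` must be an n x n matrix matching length(alpha)")
  if (length(is_producer) != n)
    stop("`is_producer` must match length(alpha)")
  if (any(alpha <= 0)) stop("decay rates `alpha` must be positive")
  if (length(beta) != 1L || beta <= 0 || beta > 1)
    stop("`beta` must be a single value in (0, 1]")
  if (k <= 0) stop("producer growth rate `k` must be positive")
  if (any(eta < 0)) stop("interaction strengths must be non-negative")
  if (n > 0L && any(diag(eta) != 0)) stop("no self-loops: diag(eta) must be 0")
  if (any(eta[is_producer, ] > 0))
    stop("producers consume only the nutrient: producer rows of eta must be 0")
  if (is.null(biomass)) biomass <- numeric(n)
  if (length(biomass) != n || any(biomass < 0))
    stop("`biomass` must be a non-negative vector of length n")
  if (is.null(id)) id <- seq_len(n)
  structure(
    list(alpha = as.numeric(alpha), is_producer = as.logical(is_producer),
         eta = eta, beta = as.numeric(beta), k = as.numeric(k),
         biomass = as.numeric(biomass), id = as.integer(id)),
    class = "food_web"
  )
}

#' @export
print.food_web <- function(x, ...) {
  n <- length(x$alpha)
  cat(sprintf("<food_web> %d species (%d producers), beta = %g, k = %g\n",
              n, sum(x$is_producer), x$beta, x$k))
  if (n > 0) {
    nres <- rowSums(x$eta > 0)
    cat(sprintf("  links: %d, multi-resource consumers: %d\n",
                sum(x$eta > 0), sum(!x$is_producer & nres > 1)))
  }
  invisible(x)
}

#' Number of species in a web
#' @param web a `food_web`.
#' @return integer species richness (the nutrient source is not counted).
#' @export
richness <- function(web) length(web$alpha)

#' Per-capita growth rates of all species
#'
#' Evaluates the right-hand side of the GLV equations divided by biomass:
#' producers obey `k (1 - sum of producer biomass) - alpha_i - predation`,
#' consumers obey `beta * (consumption gain) - alpha_k - predation`.
#' The full time derivative is `biomass * per_capita_growth()`.
#'
#' @param web a `food_web`.
#' @param biomass biomass vector at which to evaluate (defaults to the web's
#'   current state).
#' @return numeric vector of per-capita growth rates.
#' @export
per_capita_growth <- function(web, biomass = web$biomass) {
  n <- length(web$alpha)
  if (length(biomass) != n) stop("biomass length must equal species count")
  if (n == 0L) return(numeric(0))
  predation <- as.numeric(crossprod(web$eta, biomass))   # sum_p eta[p, i] S_p
  gain <- web$beta * as.numeric(web$eta %*% biomass)     # 0 for producers
  f <- gain - web$alpha - predation
  f[web$is_producer] <- f[web$is_producer] +
    web$k * (1 - sum(biomass[web$is_producer]))
  f
}

#' Linear system whose solution is the analytic steady state
#'
#' The GLV per-capita growth rates are affine in the biomasses, so setting
#' them to zero yields a linear system `R %*% S = K`.  The sign convention:
#' producer row `i` has `R[i, j] = k` for every producer `j`,
#' `R[i, p] = eta[p, i]` for every consumer `p`, and `K[i] = k - alpha[i]`;
#' consumer row `kk` has `R[kk, j] = beta * eta[kk, j] - eta[j, kk]` and
#' `K[kk] = alpha[kk]`.
#'
#' @param web a `food_web` with at least one species.
#' @return list with the interaction matrix `R` and rate vector `K`.
#' @export
glv_linear_system <- function(web) {
  n <- length(web$alpha)
  if (n < 1L) stop("web must contain at least one species")
  pr <- web$is_producer
  R <- web$beta * web$eta - t(web$eta)   # correct rows for consumers
  if (any(pr)) {
    R[pr, ] <- t(web$eta)[pr, , drop = FALSE]  # eta[p, i] for consumers p
    R[pr, pr] <- web$k
  }
  K <- ifelse(pr, web$k - web$alpha, web$alpha)
  list(R = R, K = as.numeric(K))
}

#' Analytic steady state of a food web
#'
#' Solves `R %*% S = K` (see [glv_linear_system()]).  The web is *feasible*
#' iff every steady-state entry exceeds `feasibility_tol`.  A near-singular
#' interaction matrix (reciprocal condition number below 1e-12) means no
#' unique steady state exists; the result is then flagged `singular` and
#' infeasible, and callers fall back on numerical relaxation.
#'
#' @param web a `food_web` with at least one species.
#' @param feasibility_tol positive threshold a steady-state biomass must
#'   exceed to count as present (default 1e-14).
#' @return An object of class `steady_state`: list with `populations`,
#'   `feasible`, `residual` (max absolute per-capita growth at the steady
#'   state over present species), `singular`.
#' @export
steady_state <- function(web, feasibility_tol = 1e-14) {
  n <- length(web$alpha)
  sys <- glv_linear_system(web)
  rc <- if (n == 1L) abs(sys$R[1, 1]) else rcond(sys$R)
  if (!is.finite(rc) || rc < 1e-12) {
    return(structure(list(populations = rep(NA_real_, n), feasible = FALSE,
                          residual = NA_real_, singular = TRUE),
                     class = "steady_state"))
  }
  s <- solve(sys$R, sys$K)
  feasible <- all(s > feasibility_tol)
  alive <- s > feasibility_tol
  residual <- if (any(alive))
    max(abs(per_capita_growth(web, s)[alive])) else 0
  structure(list(populations = as.numeric(s), feasible = feasible,
                 residual = residual, singular = FALSE),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> feasible: %s%s\n",
              x$feasible, if (x$singular) " (singular system)" else ""))
  if (!x$singular)
    cat("  S* =", format(x$populations, digits = 6), "\n")
  invisible(x)
}

#' Community matrix (Jacobian at a fixed point)
#'
#' The community matrix `C[i, j] = d(dS_i/dt)/dS_j` evaluated at the steady
#' state.  For GLV dynamics `C = diag(S*) %*% J + diag(f(S*))` where `J` is
#' the constant gradient of the per-capita growth rates; at an exact fixed
#' point the second term vanishes, and it is dropped here (the steady state
#' solver guarantees `|f(S*)| < 1e-8` for feasible webs).
#'
#' @param web a `food_web`.
#' @param fixed_point a feasible [steady_state()] for `web` (computed if
#'   missing).
#' @return An object of class `community_matrix`: list with the matrix
#'   `entries` and its complex `eigenvalues`.
#' @export
community_matrix <- function(web, fixed_point = steady_state(web)) {
  if (!isTRUE(fixed_point$feasible))
    stop("community matrix requires a feasible fixed point")
  J <- growth_gradient(web)
  C <- fixed_point$populations * J       # row scaling by S*
  structure(list(entries = C,
                 eigenvalues = as.complex(eigen(C, only.values = TRUE)$values)),
            class = "community_matrix")
}

# Gradient of per-capita growth w.r.t. biomasses (constant for GLV).
growth_gradient <- function(web) {
  pr <- web$is_producer
  J <- web$beta * web$eta - t(web$eta)
  if (any(pr)) {
    J[pr, ] <- -t(web$eta)[pr, , drop = FALSE]
    J[pr, pr] <- -web$k
  }
  J
}

#' Eigenvalue spectrum of a community matrix
#'
#' @param cm a `community_matrix`, or a plain square matrix.
#' @return complex vector of all eigenvalues (conjugate-closed).
#' @export
spectrum <- function(cm) {
  if (inherits(cm, "community_matrix")) return(cm$eigenvalues)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stop("need a square matrix")
  as.complex(eigen(cm, only.values = TRUE)$values)
}

#' Linear stability verdict from eigenvalues
#'
#' A fixed point is linearly stable iff every community-matrix eigenvalue
#' has negative real part.  Marginal eigenvalues occur exactly (two-species
#' webs pinned at the feasibility boundary have a zero eigenvalue), so the
#' verdict uses an absolute tolerance: unstable iff `max(Re) > tol`.
#'
#' @param eigenvalues complex vector (non-empty).
#' @param tol absolute tolerance on the real part (default 1e-10).
#' @return logical.
#' @export
is_stable <- function(eigenvalues, tol = 1e-10) {
  if (length(eigenvalues) == 0L) stop("need at least one eigenvalue")
  max(Re(eigenvalues)) <= tol
}

#' Trophic levels
#'
#' Producers sit at level 1; a consumer's level is one plus the mean of its
#' resources' levels (equal weight per resource link).  Levels are obtained
#' by solving the induced linear system, so chains of any depth and shared
#' resources are handled exactly.
#'
#' @param web a `food_web` in which every consumer has at least one resource.
#' @return numeric vector of trophic levels.
#' @export
trophic_levels <- function(web) {
  n <- length(web$alpha)
  if (n == 0L) return(numeric(0))
  pr <- web$is_producer
  nres <- rowSums(web$eta > 0)
  if (any(!pr & nres == 0))
    stop("every consumer must have at least one resource")
  A <- diag(n)
  cons <- which(!pr)
  for (kk in cons) {
    res <- which(web$eta[kk, ] > 0)
    A[kk, res] <- A[kk, res] - 1 / length(res)
  }
  as.numeric(solve(A, rep(1, n)))
}

#' Serialize a food web to JSON
#'
#' Writes a snapshot with web-level `beta`/`k`, a `species` array (id, alpha,
#' k for producers, producer flag, biomass, trophic level) and a `links`
#' array (consumer_id, resource_id, eta).  Floats are written at full
#' precision, so a write/read round trip is lossless.
#'
#' @param web a `food_web`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_web_json <- function(web, path) {
  n <- length(web$alpha)
  lv <- if (n > 0 && all(web$is_producer | rowSums(web$eta > 0) > 0))
    trophic_levels(web) else rep(NA_real_, n)
  species <- lapply(seq_len(n), function(i) {
    s <- list(id = web$id[i], alpha = web$alpha[i],
              is_producer = web$is_producer[i],
              biomass = web$biomass[i], trophic_level = lv[i])
    if (web$is_producer[i]) s$k <- web$k
    s
  })
  idx <- which(web$eta > 0, arr.ind = TRUE)
  links <- lapply(seq_len(nrow(idx)), function(r) {
    list(consumer_id = web$id[idx[r, 1]], resource_id = web$id[idx[r, 2]],
         eta = web$eta[idx[r, 1], idx[r, 2]])
  })
  doc <- list(beta = web$beta, k = web$k, species = species, links = links)
  # I(17): 17 significant digits guarantee an exact double round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a food web from a JSON snapshot
#'
#' @param path file written by [write_web_json()].
#' @return a `food_web`.
#' @export
read_web_json <- function(path) {
  doc <- jsonlite::read_json(path)
  sp <- doc$species
  n <- length(sp)
  id <- vapply(sp, function(s) as.integer(s$id), integer(1))
  alpha <- vapply(sp, function(s) as.numeric(s$alpha), numeric(1))
  is_producer <- vapply(sp, function(s) isTRUE(s$is_producer), logical(1))
  biomass <- vapply(sp, function(s) as.numeric(s$biomass), numeric(1))
  eta <- matrix(0, n, n)
  for (ln in doc$links) {
    ci <- match(as.integer(ln$consumer_id), id)
    ri <- match(as.integer(ln$resource_id), id)
    eta[ci, ri] <- as.numeric(ln$eta)
  }
  food_web(alpha = alpha, is_producer = is_producer, eta = eta,
           beta = as.numeric(doc$beta), k = as.numeric(doc$k),
           biomass = biomass, id = id)
}

#' Build the minimal producer--consumer web
#'
#' Convenience constructor for the two-species motif used throughout the
#' closed-form spectral analysis: one producer (decay `alpha1`) and one
#' consumer (decay `alpha2`) joined by a single link of strength `eta`.
#'
#' @param alpha1,alpha2 producer and consumer decay rates.
#' @param beta consumption efficiency.
#' @param eta link strength.
#' @param k producer growth rate.
#' @param biomass optional length-2 biomass vector (producer, consumer).
#' @return a `food_web` with species 1 = producer, species 2 = consumer.
#' @export
two_species_web <- function(alpha1, alpha2, beta, eta, k = 1,
                            biomass = NULL) {
  em <- matrix(c(0, eta, 0, 0), 2, 2)  # consumer (row 2) eats producer
  food_web(alpha = c(alpha1, alpha2), is_producer = c(TRUE, FALSE),
           eta = em, beta = beta, k = k, biomass = biomass)
}
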