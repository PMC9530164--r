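#' Integrate a food web until an event or a time limit
#'
#' Integrates the GLV equations with an adaptive Dormand--Prince RK5(4)
#' scheme (relative tolerance 1e-9, absolute 1e-14 by default), stopping at
#' the first time any biomass falls to the extinction threshold (the crossing
#' time is localised by bisection inside the offending step, so the state is
#' returned *at* the event, not past it), at convergence to a supplied
#' steady-state target, or at `t_limit`.
#'
#' @param web a `food_web`.
#' @param initial starting biomasses (defaults to the web's state); all
#'   entries must exceed the extinction threshold.
#' @param t_limit maximum integration time, in units of `1/k`.
#' @param target optional steady-state vector; if given, integration also
#'   stops once `|S_i - target_i| / target_i < conv_tol` for every species.
#' @param conv_tol relative convergence tolerance used with `target`.
#' @param extinction_threshold biomass at or below which a species is extinct
#'   (default 1e-12).
#' @param rtol,atol integrator tolerances.
#' @return list with `biomass` (terminal state), `time`, `event` (one of
#'   `"none"`, `"extinction"`, `"converged"`, `"stalled"`), and
#'   `extinct` (integer indices of species at or below the threshold).
#' @export
integrate_glv <- function(web, initial = web$biomass, t_limit,
                          target = NULL, conv_tol = 1e-6,
                          extinction_threshold = 1e-12,
                          rtol = 1e-9, atol = 1e-14) {
  n <- length(web$alpha)
  if (n == 0L)
    return(list(biomass = numeric(0), time = 0, event = "none",
                extinct = integer(0)))
  if (length(initial) != n) stop("initial biomass length mismatch")
  if (any(initial <= 0)) stop("initial biomasses must be positive")
  if (t_limit <= 0) stop("t_limit must be positive")
  tgt <- if (is.null(target)) numeric(0) else as.numeric(target)
  res <- .cpp_integrate_glv(as.numeric(initial), web$alpha, web$eta,
                            as.integer(web$is_producer), web$beta, web$k,
                            t_limit, extinction_threshold, tgt,
                            if (is.null(target)) -1 else conv_tol,
                            rtol, atol)
  list(biomass = as.numeric(res$y), time = res$t,
       event = c("none", "extinction", "converged", "stalled")[res$status + 1L],
       extinct = as.integer(res$extinct) + 1L)
}

#' Remove species from a web
#'
#' Deletes the given species and every link incident to them.  Consumers
#' that lose their last resource are *not* removed here: they decay at rate
#' `-alpha` in subsequent dynamics and go extinct on their own, which is how
#' cascading extinctions propagate.
#'
#' @param web a `food_web`.
#' @param ids species identifiers (`web$id` values) to remove.
#' @return the reduced `food_web`.
#' @export
remove_species <- function(web, ids) {
  if (length(ids) == 0L) return(web)
  drop <- match(ids, web$id)
  if (anyNA(drop)) stop("unknown species id(s): ",
                        paste(ids[is.na(drop)], collapse = ", "))
  keep <- setdiff(seq_along(web$id), drop)
  food_web(alpha = web$alpha[keep], is_producer = web$is_producer[keep],
           eta = web$eta[keep, keep, drop = FALSE], beta = web$beta,
           k = web$k, biomass = web$biomass[keep], id = web$id[keep])
}

#' Relax a food web to a feasible state
#'
#' Implements the full post-invasion settling protocol:
#'
#' * If the analytic steady state is feasible and linearly stable, integrate
#'   until all species are within relative deviation 1e-6 of it; if that is
#'   not met by `t = 1e4/k` the criterion is softened to 1e-2 (and stays
#'   softened); if still unmet at `t = 1e5/k` the web is declared
#'   non-convergent and, being linearly stable, its biomasses are *set* to
#'   the steady state.
#' * If feasible but unstable, integrate until `t = 1e5/k` or an extinction.
#' * If infeasible (some analytic biomass non-positive, or no unique steady
#'   state), integrate until extinctions restore feasibility.
#'
#' Whenever any biomass reaches the extinction threshold, every species at or
#' below it is removed simultaneously, steady state and eigenvalues are
#' recomputed for the survivors, and the clock restarts.  A safety cap on
#' extinction--restart cycles guards against pathological cycling.
#'
#' @param web a `food_web` whose biomasses are set (residents at their
#'   previous state, any invader at its introduction density).
#' @param extinction_threshold biomass at or below which a species is
#'   extinct (default 1e-12).
#' @param feasibility_tol steady-state feasibility threshold (default 1e-14).
#' @param stability_tol absolute tolerance on eigenvalue real parts.
#' @param conv_tol,conv_tol_soft strict and softened relative convergence
#'   criteria.
#' @param t_soften,t_max times at which the criterion softens and at which
#'   integration is abandoned.
#' @param max_cycles cap on extinction--restart cycles (default 50).
#' @param rtol,atol integrator tolerances.
#' @return An object of class `relaxation`: list with `web` (survivors, with
#'   settled biomasses), `extinct_ids` (in order of removal), `converged`,
#'   `non_convergent`, `elapsed_time` (time spent in the final integration
#'   leg), and `cycles`.
#' @export
relax <- function(web,
                  extinction_threshold = 1e-12,
                  feasibility_tol = 1e-14,
                  stability_tol = 1e-10,
                  conv_tol = 1e-6, conv_tol_soft = 1e-2,
                  t_soften = 1e4, t_max = 1e5,
                  max_cycles = 50L,
                  rtol = 1e-9, atol = 1e-14) {
  stopifnot(extinction_threshold > feasibility_tol)
  extinct_ids <- integer(0)
  cycles <- 0L
  softened <- FALSE
  elapsed <- 0
  converged <- FALSE
  non_convergent <- FALSE

  kill <- function(w, idx) {
    extinct_ids <<- c(extinct_ids, w$id[idx])
    cycles <<- cycles + 1L
    remove_species(w, w$id[idx])
  }

  repeat {
    n <- length(web$alpha)
    if (n == 0L) { converged <- TRUE; break }
    if (cycles > max_cycles) { non_convergent <- TRUE; break }

    # species already at/below threshold (e.g. handed in that way)
    below <- which(web$biomass <= extinction_threshold & web$biomass > 0)
    if (length(below) > 0) { web <- kill(web, below); next }

    ss <- steady_state(web, feasibility_tol)
    if (ss$feasible) {
      eig <- spectrum(community_matrix(web, ss))
      if (is_stable(eig, stability_tol)) {
        tol_now <- if (softened) conv_tol_soft else conv_tol
        leg <- integrate_glv(web, web$biomass,
                             t_limit = if (softened) t_max else t_soften,
                             target = ss$populations, conv_tol = tol_now,
                             extinction_threshold = extinction_threshold,
                             rtol = rtol, atol = atol)
        elapsed <- leg$time
        if (leg$event == "extinction") {
          web$biomass <- pmax(leg$biomass, 0)
          web <- kill(web, leg$extinct)
          softened <- FALSE
          next
        }
        if (leg$event == "converged") {
          web$biomass <- leg$biomass
          converged <- TRUE
          break
        }
        if (!softened) {      # t_soften reached under the strict criterion
          web$biomass <- leg$biomass
          softened <- TRUE
          next
        }
        # linearly stable but unconverged at t_max (or stalled): assume slow
        # convergence and pin to the analytic steady state
        non_convergent <- TRUE
        web$biomass <- ss$populations
        break
      }
      # feasible but unstable: integrate to t_max or an extinction
      leg <- integrate_glv(web, web$biomass, t_limit = t_max,
                           extinction_threshold = extinction_threshold,
                           rtol = rtol, atol = atol)
      elapsed <- leg$time
      if (leg$event == "extinction") {
        web$biomass <- pmax(leg$biomass, 0)
        web <- kill(web, leg$extinct)
        softened <- FALSE
        next
      }
      non_convergent <- TRUE
      web$biomass <- leg$biomass
      break
    }

    # infeasible (or singular): integrate until extinctions restore
    # feasibility
    leg <- integrate_glv(web, web$biomass, t_limit = t_max,
                         extinction_threshold = extinction_threshold,
                         rtol = rtol, atol = atol)
    elapsed <- leg$time
    if (leg$event == "extinction") {
      web$biomass <- pmax(leg$biomass, 0)
      web <- kill(web, leg$extinct)
      softened <- FALSE
      next
    }
    # an infeasible web that never sheds a species within t_max
    non_convergent <- TRUE
    web$biomass <- leg$biomass
    break
  }

  structure(list(web = web, extinct_ids = extinct_ids,
                 converged = converged, non_convergent = non_convergent,
                 elapsed_time = elapsed, cycles = cycles),
            class = "relaxation")
}

#' @export
print.relaxation <- function(x, ...) {
  cat(sprintf(
    "<relaxation> %d survivors, %d extinctions, converged: %s%s\n",
    length(x$web$alpha), length(x$extinct_ids), x$converged,
    if (x$non_convergent) " (non-convergent)" else ""))
  invisible(x)
}
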