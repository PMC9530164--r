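#' Assembly configuration
#'
#' Collects every tunable of an evolutionary assembly run.  Defaults follow
#' the standard parameterisation: decay rates uniform on (0.05, 0.5),
#' interaction strengths uniform on (0.01, 1), producer growth rate `k = 1`
#' (which fixes the time unit), invaders introduced at biomass 1e-10, and a
#' 1:2 invasion ratio of primary producers to other species (one producer
#' invader per two consumer invaders, probability 1/3).
#'
#' The three assembly modes differ only in how consumers acquire resources:
#' `"treelike"` consumers get exactly one resource; `"omnivorous"` consumers
#' get a second, distinct resource with probability 1/2, always accepted;
#' `"non_omnivorous"` consumers propose a second resource with probability
#' 0.75 (1.5 times the omnivorous rate, compensating the rejections) but the
#' proposal is accepted only if both resources sit at the same trophic level.
#'
#' @param mode one of `"treelike"`, `"non_omnivorous"`, `"omnivorous"`.
#' @param beta consumption efficiency in (0, 1]; canonical values are
#'   0.25, 0.5, 0.75, 0.9, 1.
#' @param attempts number of invasion attempts.
#' @param seed RNG seed for the run.
#' @param producer_fraction probability an invader is a primary producer.
#'   The default 1/3 reads the 1:2 producer-to-species invasion ratio as one
#'   producer per two non-producer invaders; it reproduces the reported
#'   per-mode invasion success rates, while the alternative reading (1/2) is
#'   one flag away.
#' @param second_resource_prob probability of proposing a second resource;
#'   defaults to 0 (treelike), 0.75 (non_omnivorous) or 0.5 (omnivorous).
#' @param alpha_range,eta_range uniform sampling ranges for decay rates and
#'   interaction strengths.
#' @param k producer growth rate.
#' @param invader_biomass introduction biomass density.
#' @param record_every_attempt record a spectrum after every attempt instead
#'   of only when the surviving composition changed.
#' @param extinction_threshold,feasibility_tol,stability_tol thresholds; the
#'   extinction threshold must exceed the feasibility threshold.
#' @param level_tol tolerance for the equal-trophic-level acceptance test in
#'   non-omnivorous mode.
#' @param rtol,atol integrator tolerances.
#' @return a validated list of class `assembly_config`.
#' @export
assembly_config <- function(mode = c("treelike", "non_omnivorous",
                                     "omnivorous"),
                            beta = 0.75, attempts = 1e5, seed = 1L,
                            producer_fraction = 1/3,
                            second_resource_prob = NULL,
                            alpha_range = c(0.05, 0.5),
                            eta_range = c(0.01, 1),
                            k = 1, invader_biomass = 1e-10,
                            record_every_attempt = FALSE,
                            extinction_threshold = 1e-12,
                            feasibility_tol = 1e-14,
                            stability_tol = 1e-10,
                            level_tol = 1e-9,
                            rtol = 1e-9, atol = 1e-14) {
  mode <- match.arg(mode)
  if (is.null(second_resource_prob))
    second_resource_prob <- switch(mode, treelike = 0,
                                   non_omnivorous = 0.75, omnivorous = 0.5)
  if (beta <= 0 || beta > 1) stop("`beta` must lie in (0, 1]")
  if (attempts < 1) stop("`attempts` must be a positive integer")
  if (producer_fraction < 0 || producer_fraction > 1)
    stop("`producer_fraction` must lie in [0, 1]")
  if (second_resource_prob < 0 || second_resource_prob > 1)
    stop("`second_resource_prob` must lie in [0, 1]")
  if (mode == "treelike" && second_resource_prob != 0)
    stop("treelike mode forbids second resources")
  if (length(alpha_range) != 2 || alpha_range[1] <= 0 || diff(alpha_range) <= 0)
    stop("`alpha_range` must be positive and increasing")
  if (length(eta_range) != 2 || eta_range[1] <= 0 || diff(eta_range) <= 0)
    stop("`eta_range` must be positive and increasing")
  if (alpha_range[2] >= k)
    stop("producer decay rates must stay below the growth rate k")
  if (extinction_threshold <= feasibility_tol)
    stop("extinction threshold must exceed the feasibility threshold")
  if (invader_biomass <= extinction_threshold)
    stop("invader biomass must exceed the extinction threshold")
  structure(list(mode = mode, beta = beta, attempts = as.integer(attempts),
                 seed = as.integer(seed),
                 producer_fraction = producer_fraction,
                 second_resource_prob = second_resource_prob,
                 alpha_range = alpha_range, eta_range = eta_range, k = k,
                 invader_biomass = invader_biomass,
                 record_every_attempt = record_every_attempt,
                 extinction_threshold = extinction_threshold,
                 feasibility_tol = feasibility_tol,
                 stability_tol = stability_tol, level_tol = level_tol,
                 rtol = rtol, atol = atol),
            class = "assembly_config")
}

#' Draw a random invader
#'
#' Producers (probability `producer_fraction`) feed on the nutrient only.
#' Consumers take their first resource uniformly from the resident species;
#' depending on the assembly mode a second, distinct resident may be added
#' (see [assembly_config()]).  Each link strength is drawn independently
#' from `U(eta_range)`, the decay rate from `U(alpha_range)`.
#'
#' @param config an `assembly_config`.
#' @param web the resident `food_web` (non-empty for consumer invaders).
#' @param levels resident trophic levels, required for non-omnivorous
#'   acceptance (computed from `web` if `NULL`).
#' @return list with `alpha`, `is_producer`, `resources` (integer positions
#'   in `web`), `eta` (link strengths, parallel to `resources`).
#' @export
draw_invader <- function(config, web, levels = NULL) {
  n <- length(web$alpha)
  is_prod <- n == 0L || stats::runif(1) < config$producer_fraction
  alpha <- stats::runif(1, config$alpha_range[1], config$alpha_range[2])
  if (is_prod)
    return(list(alpha = alpha, is_producer = TRUE,
                resources = integer(0), eta = numeric(0)))
  first <- sample.int(n, 1L)
  resources <- first
  etas <- stats::runif(1, config$eta_range[1], config$eta_range[2])
  if (config$second_resource_prob > 0 && n >= 2L &&
      stats::runif(1) < config$second_resource_prob) {
    rest <- setdiff(seq_len(n), first)
    second <- rest[sample.int(length(rest), 1L)]
    accept <- TRUE
    if (config$mode == "non_omnivorous") {
      if (is.null(levels)) levels <- trophic_levels(web)
      accept <- abs(levels[first] - levels[second]) < config$level_tol
    }
    if (accept) {
      resources <- c(resources, second)
      etas <- c(etas, stats::runif(1, config$eta_range[1],
                                   config$eta_range[2]))
    }
  }
  list(alpha = alpha, is_producer = FALSE, resources = resources, eta = etas)
}

#' Append an invader to a web
#'
#' @param web a `food_web`.
#' @param invader an invader description from [draw_invader()].
#' @param id identifier for the new species.
#' @param biomass introduction biomass density.
#' @return the enlarged `food_web` (invader is the last species).
#' @export
add_species <- function(web, invader, id, biomass = 1e-10) {
  n <- length(web$alpha)
  eta <- rbind(cbind(web$eta, 0), 0)
  if (length(invader$resources) > 0)
    eta[n + 1L, invader$resources] <- invader$eta
  food_web(alpha = c(web$alpha, invader$alpha),
           is_producer = c(web$is_producer, invader$is_producer),
           eta = eta, beta = web$beta, k = web$k,
           biomass = c(web$biomass, biomass), id = c(web$id, as.integer(id)))
}

#' One invasion attempt
#'
#' Appends the invader at its introduction biomass and relaxes the enlarged
#' web (see [relax()]).  The attempt is a *success* if the invader is among
#' the survivors.
#'
#' @param web a relaxed, feasible `food_web`.
#' @param invader invader description from [draw_invader()].
#' @param config an `assembly_config`.
#' @param id identifier to assign to the invader.
#' @return list with `web` (post-relaxation survivors), `success`,
#'   `extinct_resident_ids`, `invader_id`, and the full `relaxation`.
#' @export
attempt_invasion <- function(web, invader, config, id) {
  enlarged <- add_species(web, invader, id,
                          biomass = config$invader_biomass)
  r <- relax(enlarged,
             extinction_threshold = config$extinction_threshold,
             feasibility_tol = config$feasibility_tol,
             stability_tol = config$stability_tol,
             rtol = config$rtol, atol = config$atol)
  list(web = r$web,
       success = id %in% r$web$id,
       extinct_resident_ids = setdiff(r$extinct_ids, id),
       invader_id = as.integer(id),
       relaxation = r)
}

#' Evolve a food web by sequential invasion
#'
#' Starts from the minimal web (the implicit nutrient source plus one
#' randomly parameterised primary producer at its steady state) and applies
#' `config$attempts` invasion attempts, each followed by relaxation with
#' possible extinctions.  All bookkeeping needed for the downstream spectral
#' and evolutionary statistics is accumulated.
#'
#' A spectrum is recorded whenever the post-relaxation web is feasible and
#' its species composition differs from the previously recorded web (every
#' attempt instead if `record_every_attempt`).
#'
#' @param config an [assembly_config()].
#' @param progress print a progress line every 1000 attempts.
#' @return An object of class `evolution_history`: list with
#'   `records` (one row per attempt: `attempt`, `invader_is_producer`,
#'   `success`, `extinct_count`, `richness_before`, `richness_after`,
#'   `web_changed`, `non_convergent`, `min_producer_alpha`),
#'   `eigenvalues` (`attempt`, `richness`, `re`, `im`; one row per
#'   eigenvalue of each recorded web), `recorded_webs` (`attempt`,
#'   `richness`, `treelike`, `max_re`), `residence` (`id`, `arrival`,
#'   `departure`, `censored`), `final_web`, `config`.
#' @export
evolve <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "assembly_config"))
  set.seed(config$seed)
  n_att <- config$attempts

  # seed web: one producer at its steady state (k - alpha) / k
  alpha0 <- stats::runif(1, config$alpha_range[1], config$alpha_range[2])
  web <- food_web(alpha = alpha0, is_producer = TRUE,
                  eta = matrix(0, 1, 1), beta = config$beta, k = config$k,
                  biomass = (config$k - alpha0) / config$k, id = 1L)
  next_id <- 2L

  rec_inv_prod <- logical(n_att); rec_success <- logical(n_att)
  rec_extinct <- integer(n_att); rec_rich_before <- integer(n_att)
  rec_rich_after <- integer(n_att); rec_changed <- logical(n_att)
  rec_nonconv <- logical(n_att); rec_minalpha <- numeric(n_att)

  eig_attempt <- list(); eig_rich <- list(); eig_val <- list()
  recw_attempt <- integer(0); recw_rich <- integer(0)
  recw_tree <- logical(0); recw_maxre <- numeric(0)
  last_key <- ""

  arrival <- c(0L); departure <- c(NA_integer_)  # indexed by species id
  established <- c(TRUE)

  for (i in seq_len(n_att)) {
    levels <- if (config$mode == "non_omnivorous") trophic_levels(web)
              else NULL
    inv <- draw_invader(config, web, levels)
    out <- attempt_invasion(web, inv, config, next_id)

    arrival[next_id] <- i; departure[next_id] <- NA_integer_
    established[next_id] <- out$success
    gone <- out$relaxation$extinct_ids
    if (length(gone) > 0) departure[gone] <- i

    rec_inv_prod[i] <- inv$is_producer
    rec_success[i] <- out$success
    rec_extinct[i] <- length(out$extinct_resident_ids)
    rec_rich_before[i] <- length(web$alpha)
    rec_rich_after[i] <- length(out$web$alpha)
    rec_changed[i] <- out$success || rec_extinct[i] > 0L
    rec_nonconv[i] <- out$relaxation$non_convergent
    web <- out$web
    next_id <- next_id + 1L
    rec_minalpha[i] <- if (any(web$is_producer))
      min(web$alpha[web$is_producer]) else NA_real_

    key <- paste(web$id, collapse = ",")
    want <- if (config$record_every_attempt) TRUE else key != last_key
    if (want && length(web$alpha) > 0L) {
      ss <- steady_state(web, config$feasibility_tol)
      if (ss$feasible) {
        ev <- spectrum(community_matrix(web, ss))
        j <- length(eig_attempt) + 1L
        eig_attempt[[j]] <- rep.int(i, length(ev))
        eig_rich[[j]] <- rep.int(length(ev), length(ev))
        eig_val[[j]] <- ev
        recw_attempt <- c(recw_attempt, i)
        recw_rich <- c(recw_rich, length(web$alpha))
        recw_tree <- c(recw_tree,
                       !any(rowSums(web$eta > 0) > 1L))
        recw_maxre <- c(recw_maxre, max(Re(ev)))
        last_key <- key
      }
    }
    if (progress && i %% 1000L == 0L)
      message(sprintf("attempt %d/%d: richness %d", i, n_att,
                      length(web$alpha)))
  }

  ev_all <- if (length(eig_val)) unlist(eig_val) else complex(0)
  eig <- data.frame(attempt = unlist(eig_attempt, use.names = FALSE) %||%
                      integer(0),
                    richness = unlist(eig_rich, use.names = FALSE) %||%
                      integer(0),
                    re = Re(ev_all), im = Im(ev_all))
  alive <- web$id
  ids <- which(established[seq_len(next_id - 1L)])  # species that settled in
  residence <- data.frame(id = ids, arrival = arrival[ids],
                          departure = departure[ids],
                          censored = ids %in% alive)

  structure(list(
    records = data.frame(attempt = seq_len(n_att),
                         invader_is_producer = rec_inv_prod,
                         success = rec_success, extinct_count = rec_extinct,
                         richness_before = rec_rich_before,
                         richness_after = rec_rich_after,
                         web_changed = rec_changed,
                         non_convergent = rec_nonconv,
                         min_producer_alpha = rec_minalpha),
    eigenvalues = eig,
    recorded_webs = data.frame(attempt = recw_attempt, richness = recw_rich,
                               treelike = recw_tree, max_re = recw_maxre),
    residence = residence,
    final_web = web,
    config = config), class = "evolution_history")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.evolution_history <- function(x, ...) {
  cat(sprintf(
    "<evolution_history> %s, beta = %g: %d attempts, success rate %.1f%%, final richness %d\n",
    x$config$mode, x$config$beta, nrow(x$records),
    100 * success_rate(x), length(x$final_web$alpha)))
  invisible(x)
}

#' Invasion success rate
#'
#' @param history an `evolution_history`.
#' @return fraction of attempts in which the invader survived relaxation.
#' @export
success_rate <- function(history) {
  mean(history$records$success)
}

#' Evolutionary summary metrics
#'
#' @param history an `evolution_history`.
#' @return list with
#'   `richness_histogram` (named numeric, post-relaxation richness of every
#'   attempt, normalised to unit mass),
#'   `residence_times` (data frame of per-species residence intervals in
#'   attempt units, with a `censored` flag for species alive at run end),
#'   `extinction_sizes` (resident extinctions per attempt divided by the
#'   pre-invasion richness, for attempts with at least one extinction),
#'   `treelike_fraction` (fraction of recorded feasible webs without any
#'   multi-resource consumer).
#' @export
evolution_metrics <- function(history) {
  rec <- history$records
  h <- table(rec$richness_after)
  richness_histogram <- as.numeric(h) / sum(h)
  names(richness_histogram) <- names(h)
  res <- history$residence
  res$time <- ifelse(res$censored, nrow(rec) - res$arrival,
                     res$departure - res$arrival)
  ext <- rec$extinct_count > 0
  list(richness_histogram = richness_histogram,
       residence_times = res[, c("id", "arrival", "departure", "censored",
                                 "time")],
       extinction_sizes = rec$extinct_count[ext] / rec$richness_before[ext],
       treelike_fraction = if (nrow(history$recorded_webs))
         mean(history$recorded_webs$treelike) else NA_real_)
}
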