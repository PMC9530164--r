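# Shared fixtures: all webs are generated in code.

# The worked 2-species example used throughout: producer (alpha 0.1),
# consumer (alpha 0.2), beta = 1, eta = 0.5, k = 1; S* = (0.4, 1.0).
example_pair <- function() two_species_web(0.1, 0.2, beta = 1, eta = 0.5)

# Draw a random *feasible* two-species web with the standard parameter
# ranges: alpha ~ U(0.05, 0.5), eta ~ U(0.01, 1), beta from the canonical
# set, k = 1.  Rejection sampling on the feasibility condition beta*eta >
# gamma.
draw_feasible_pair <- function(betas = c(0.25, 0.5, 0.75, 0.9, 1)) {
  repeat {
    a1 <- runif(1, 0.05, 0.5); a2 <- runif(1, 0.05, 0.5)
    eta <- runif(1, 0.01, 1); beta <- sample(betas, 1)
    gamma <- a2 / (1 - a1)
    if (beta * eta > gamma)
      return(list(alpha1 = a1, alpha2 = a2, beta = beta, eta = eta,
                  gamma = gamma))
  }
}

# Central-difference Jacobian of the full derivative biomass * f(biomass),
# the independent oracle for the analytic community matrix.
numerical_jacobian <- function(web, s, h = 1e-7) {
  n <- length(s)
  dot <- function(x) x * per_capita_growth(web, x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hp <- h * max(1, abs(s[j]))
    up <- s; up[j] <- up[j] + hp
    dn <- s; dn[j] <- dn[j] - hp
    J[, j] <- (dot(up) - dot(dn)) / (2 * hp)
  }
  J
}

# Assemble a random feasible web of moderate richness by running a short
# seeded evolution; returns the final web (always relaxed and feasible).
assemble_web <- function(seed, mode = "omnivorous", attempts = 60,
                         beta = 0.75) {
  cfg <- assembly_config(mode = mode, beta = beta, attempts = attempts,
                         seed = seed)
  evolve(cfg)$final_web
}
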