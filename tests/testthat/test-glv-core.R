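test_that("per-capita growth matches closed-form cases", {
  # single producer at its logistic equilibrium 1 - alpha/k
  p <- food_web(0.2, TRUE, matrix(0, 1, 1), beta = 1)
  expect_equal(per_capita_growth(p, 0.8), 0)

  # empty-interaction limit: producers give k - alpha, consumers -alpha
  w <- example_pair()
  expect_equal(per_capita_growth(w, c(0, 0)), c(1 - 0.1, -0.2))

  # hand-solved 2-species equilibrium
  expect_equal(per_capita_growth(w, c(0.4, 1.0)), c(0, 0))

  expect_error(per_capita_growth(w, c(1, 2, 3)), "length")
})

test_that("linear system reproduces the steady state", {
  p <- food_web(0.2, TRUE, matrix(0, 1, 1), beta = 1)
  sys <- glv_linear_system(p)
  expect_equal(solve(sys$R, sys$K), 0.8)

  w <- example_pair()
  sys <- glv_linear_system(w)
  expect_equal(solve(sys$R, sys$K), c(0.4, 1.0))

  # R S = K is exactly the zero of the per-capita growth: check at a random
  # state that R s - K equals the interaction part of f with flipped signs
  set.seed(1)
  for (i in 1:20) {
    web <- assemble_web(i, attempts = 30)
    if (richness(web) < 2) next
    sys <- glv_linear_system(web)
    s <- runif(richness(web), 0.05, 1)
    f <- per_capita_growth(web, s)
    pr <- web$is_producer
    lhs <- as.numeric(sys$R %*% s - sys$K)
    expect_equal(lhs[pr], -f[pr], tolerance = 1e-12)
    expect_equal(lhs[!pr], f[!pr], tolerance = 1e-12)
  }
})

test_that("steady state solves, flags feasibility, and bounds the residual", {
  p <- food_web(0.2, TRUE, matrix(0, 1, 1), beta = 1)
  ss <- steady_state(p)
  expect_equal(ss$populations, 0.8)
  expect_true(ss$feasible)
  expect_lt(ss$residual, 1e-8)

  ss <- steady_state(example_pair())
  expect_equal(ss$populations, c(0.4, 1.0))
  expect_true(ss$feasible)

  # consumption too weak to sustain the consumer: S1* = alpha2/(beta eta)
  # exceeds what the producer equation allows, so S2* < 0 -> infeasible
  weak <- two_species_web(0.1, 0.2, beta = 1, eta = 0.1)
  ss <- steady_state(weak)
  expect_false(ss$feasible)
  expect_equal(ss$populations[1], 2.0)
  expect_lt(ss$populations[2], 0)

  # consumer whose only "resource" row is all zero makes R singular
  orphan <- food_web(alpha = c(0.2, 0.3), is_producer = c(TRUE, FALSE),
                     eta = matrix(0, 2, 2), beta = 1)
  ss <- steady_state(orphan)
  expect_true(ss$singular)
  expect_false(ss$feasible)
})

test_that("community matrix matches hand differentiation and the numeric oracle", {
  w <- example_pair()
  cm <- community_matrix(w)
  expect_equal(cm$entries, matrix(c(-0.4, 0.5, -0.2, 0), 2, 2))

  p <- food_web(0.2, TRUE, matrix(0, 1, 1), beta = 1)
  expect_equal(community_matrix(p)$entries, matrix(-0.8, 1, 1))

  expect_error(community_matrix(two_species_web(0.1, 0.2, 1, 0.1)),
               "feasible")

  # analytic vs central-difference Jacobian on randomly assembled webs
  set.seed(99)
  checked <- 0
  for (i in 1:120) {
    web <- assemble_web(i, mode = sample(c("treelike", "omnivorous"), 1),
                        attempts = sample(20:80, 1))
    n <- richness(web)
    if (n < 2 || n > 8) next
    ss <- steady_state(web)
    if (!ss$feasible) next
    C <- community_matrix(web, ss)$entries
    J <- numerical_jacobian(web, ss$populations)
    expect_lt(max(abs(C - J)) / max(1, max(abs(C))), 1e-6)
    checked <- checked + 1
  }
  expect_gte(checked, 100)
})

test_that("spectrum and stability verdicts behave", {
  C <- matrix(c(-0.4, 0.5, -0.2, 0), 2, 2)
  ev <- spectrum(C)
  expect_equal(sort(Re(ev)), c(-0.2, -0.2))
  expect_equal(sort(Im(ev)), c(-1, 1) * sqrt(0.1 - 0.04), tolerance = 1e-10)
  expect_equal(spectrum(matrix(-0.8, 1, 1)), -0.8 + 0i)
  expect_equal(sort(Re(spectrum(diag(c(-1, -2))))), c(-2, -1))

  expect_true(is_stable(ev))
  expect_true(is_stable(0 + 0i))          # marginal case counts as stable
  expect_false(is_stable(c(0.1, -1)))
  expect_error(is_stable(complex(0)), "eigenvalue")

  # conjugate closure on assembled webs
  for (i in 1:10) {
    web <- assemble_web(i + 300, attempts = 40)
    ss <- steady_state(web)
    if (!ss$feasible || richness(web) < 2) next
    ev <- spectrum(community_matrix(web, ss))
    expect_equal(sort(Im(ev)), sort(-Im(ev)), tolerance = 1e-12)
  }
})

test_that("trophic levels solve the equal-weight linear system", {
  p <- food_web(0.2, TRUE, matrix(0, 1, 1), beta = 1)
  expect_equal(trophic_levels(p), 1)
  expect_equal(trophic_levels(example_pair()), c(1, 2))

  # consumer eating a level-1 and a level-2 resource -> 1 + mean(1, 2)
  eta <- matrix(0, 4, 4)
  eta[2, 1] <- 0.3          # consumer 2 eats producer 1
  eta[3, 1] <- 0.2          # consumer 3 eats producer 1
  eta[4, 1] <- 0.1; eta[4, 2] <- 0.4   # omnivore 4 eats levels 1 and 2
  w <- food_web(alpha = rep(0.2, 4),
                is_producer = c(TRUE, FALSE, FALSE, FALSE),
                eta = eta, beta = 0.75)
  expect_equal(trophic_levels(w), c(1, 2, 2, 2.5))

  orphan <- food_web(alpha = c(0.2, 0.3), is_producer = c(TRUE, FALSE),
                     eta = matrix(0, 2, 2), beta = 1)
  expect_error(trophic_levels(orphan), "resource")
})

test_that("energy asymmetry: consumer gain is below resource loss for beta < 1", {
  set.seed(7)
  for (i in 1:20) {
    web <- assemble_web(i + 100, beta = 0.75, attempts = 40)
    links <- which(web$eta > 0)
    if (length(links) == 0) next
    expect_true(all(web$beta * web$eta[links] < web$eta[links]))
  }
})

test_that("JSON snapshot round trip is lossless", {
  set.seed(11)
  web <- assemble_web(5, attempts = 60)
  path <- withr::local_tempfile(fileext = ".json")
  write_web_json(web, path)
  back <- read_web_json(path)
  expect_identical(back$alpha, web$alpha)
  expect_identical(back$biomass, web$biomass)
  expect_identical(back$eta, web$eta)
  expect_identical(back$is_producer, web$is_producer)
  expect_identical(back$id, web$id)
  expect_identical(back$beta, web$beta)
})

test_that("food_web constructor enforces structural invariants", {
  expect_error(food_web(0.2, TRUE, matrix(1, 1, 1), beta = 1), "self-loops")
  eta <- matrix(c(0, 0, 0.5, 0), 2, 2)  # producer row 1 consumes species 2
  expect_error(food_web(c(0.2, 0.3), c(TRUE, FALSE), eta, beta = 1),
               "producer")
  expect_error(food_web(c(-0.1, 0.3), c(TRUE, FALSE), matrix(0, 2, 2),
                        beta = 1), "positive")
  expect_error(food_web(0.2, TRUE, matrix(0, 1, 1), beta = 1.5), "beta")
})
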