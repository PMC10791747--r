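test_that("vectorized growth equations match the loop-based evaluator", {
  set.seed(2024)
  for (s in 1:25) {
    net <- make_test_net(S = sample(2:7, 1), seed = s,
                         omega_c = runif(1, 0, 0.1),
                         omega_m = runif(1, 0, 0.3),
                         omega_p = runif(1, 0, 0.3))
    st <- random_state(net, seed = s + 100)
    expect_lt(max(abs(unname(rhs(st, net)) -
                      naive_rhs(st, net, net$params))), 1e-10)
  }
})

test_that("compiled and R derivative evaluations are identical", {
  net <- make_test_net(S = 9, seed = 2)
  st <- random_state(net, seed = 3)
  rr <- params_r <- triguild:::params_r_vectors(net, net$params)
  cc <- triguild:::rhs_guilds_cpp(st$P, st$M, st$H, rr$rP, rr$rM, rr$rH,
                                  net$beta_P, net$beta_M, net$beta_H,
                                  net$gamma, net$tau, net$Theta_MP,
                                  net$Theta_HP, net$params$h, net$params$eps)
  expect_equal(unname(rhs(st, net)), drop(cc), tolerance = 1e-14)
})

test_that("an isolated plant at its carrying capacity has zero growth", {
  com <- niche_community(1, 1, 1, pos_P = 0.5, pos_M = 0.1, pos_H = 0.9)
  p <- model_params(omega_c = 0.1, omega_m = 0.1, omega_p = 0.1)
  mats <- assemble_matrices(com, p, matrix(0, 1, 1), matrix(0, 1, 1))
  st <- community_state(P = 1, M = 1e-12, H = 1e-12)
  expect_equal(unname(rhs(st, mats))[1], 0, tolerance = 1e-12)
})

test_that("with h = 0 a single plant-pollinator pair is bilinear", {
  com <- niche_community(1, 1, 1, pos_P = 0.5, pos_M = 0.5, pos_H = 0.9)
  p <- model_params(omega_c = 0, omega_m = 0.2, omega_p = 0, h = 0)
  mats <- assemble_matrices(com, p, matrix(1, 1, 1), matrix(0, 1, 1))
  st <- community_state(P = 0.7, M = 0.4, H = 0)
  d <- unname(rhs(st, mats))
  gamma <- 0.2  # perfect overlap
  expect_equal(d[1], 0.7 * (1 - 0.7 + gamma * 0.4), tolerance = 1e-12)
  expect_equal(d[2], 0.4 * (1 - 0.4 + gamma * 0.7), tolerance = 1e-12)
  expect_equal(d[3], 0)
})

test_that("rhs rejects non-finite states", {
  net <- make_test_net(S = 3, seed = 1)
  st <- random_state(net)
  st$P[1] <- NaN
  expect_error(rhs(st, net), "non-finite")
})

test_that("a lone plant converges to its carrying capacity", {
  com <- niche_community(1, 1, 1, pos_P = 0.5, pos_M = 0.1, pos_H = 0.9)
  p <- model_params(omega_c = 0.1, omega_m = 0, omega_p = 0)
  mats <- assemble_matrices(com, p, matrix(0, 1, 1), matrix(0, 1, 1))
  eq <- integrate_to_equilibrium(community_state(0.2, 1, 1), mats)
  expect_true(eq$converged)
  expect_equal(eq$state$P, 1, tolerance = 1e-6)
})

test_that("exact zero biomass is absorbing", {
  net <- make_test_net(S = 4, seed = 6)
  st <- community_state(c(0, rep(1, 3)), rep(1, 4), rep(1, 4))
  eq <- integrate_to_equilibrium(st, net)
  expect_identical(eq$state$P[1], 0)
})

test_that("two symmetric competitors converge to r/(1+b)", {
  b <- niche_overlap_coefficient(0.4, 0.6, 0.1) * 0.5
  com <- niche_community(2, 1, 1, pos_P = c(0.4, 0.6), pos_M = 0.1,
                         pos_H = 0.9)
  p <- model_params(omega_c = 0.5, omega_m = 0, omega_p = 0)
  mats <- assemble_matrices(com, p, matrix(0, 1, 2), matrix(0, 1, 2))
  eq <- integrate_to_equilibrium(community_state(c(0.3, 1.2), 1, 1), mats)
  expect_equal(eq$state$P, rep(1 / (1 + b), 2), tolerance = 1e-6)
})

test_that("the two integration methods agree at equilibrium", {
  net <- make_test_net(S = 6, seed = 12, omega_m = 0.2, omega_p = 0.15)
  eq1 <- integrate_to_equilibrium(NULL, net, method = "dp45")
  eq2 <- integrate_to_equilibrium(NULL, net, method = "lsoda")
  expect_true(eq1$converged && eq2$converged)
  expect_equal(c(eq1$state$P, eq1$state$M, eq1$state$H),
               c(eq2$state$P, eq2$state$M, eq2$state$H), tolerance = 1e-6)
})

test_that("integration never takes biomass below the floor", {
  net <- make_test_net(S = 8, seed = 3, omega_c = 0.1, omega_m = 0.3,
                       omega_p = 0.3)
  eq <- integrate_to_equilibrium(NULL, net, floor = 1e-9)
  expect_true(all(c(eq$state$P, eq$state$M, eq$state$H) >= 1e-9))
})

test_that("the one-species logistic Jacobian at capacity is [-r]", {
  com <- niche_community(1, 1, 1, pos_P = 0.5, pos_M = 0.1, pos_H = 0.9)
  p <- model_params(omega_c = 0, omega_m = 0, omega_p = 0)
  mats <- assemble_matrices(com, p, matrix(0, 1, 1), matrix(0, 1, 1))
  J <- analytic_jacobian(community_state(1, 1e-12, 1e-12), mats)
  expect_equal(J[1, 1], -1, tolerance = 1e-10)
})

test_that("with h = 0 the Jacobian has the classical Lotka-Volterra structure", {
  net <- make_test_net(S = 4, seed = 9, h = 0)
  st <- random_state(net, seed = 2)
  # diag(X) %*% A + diag(A %*% X + r) with the full interaction matrix A
  S <- 4
  A <- rbind(cbind(-net$beta_P, net$gamma, -net$tau),
             cbind(t(net$gamma), -net$beta_M, matrix(0, S, S)),
             cbind(net$params$eps * t(net$tau), matrix(0, S, S), -net$beta_H))
  x <- c(st$P, st$M, st$H)
  expected <- diag(x) %*% A + diag(drop(A %*% x) + 1)
  expect_equal(analytic_jacobian(st, net), expected, tolerance = 1e-12)
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(99)
  for (s in 1:30) {
    net <- make_test_net(S = sample(3:10, 1), seed = s,
                         omega_c = runif(1, 0.01, 0.1),
                         omega_m = runif(1, 0.035, 0.35),
                         omega_p = runif(1, 0.035, 0.35))
    st <- random_state(net, seed = s + 500)
    J <- analytic_jacobian(st, net)
    Jfd <- fd_jacobian(st, net, net$params)
    expect_lt(max(abs(J - Jfd)) / max(1, max(abs(Jfd))), 1e-5)
  }
})

test_that("resilience is |max real part| only under local stability", {
  eq <- structure(list(leading_eigen_real = -1), class = "equilibrium_result")
  expect_equal(resilience(eq), 1)
  eq$leading_eigen_real <- -0.05  # e.g. spectrum {-0.2 +- 3i, -0.05}
  expect_equal(resilience(eq), 0.05)
  eq$leading_eigen_real <- 0.2
  expect_true(is.na(resilience(eq)))
  eq$leading_eigen_real <- NA_real_
  expect_error(resilience(eq), "stability")
})

test_that("decoupled communities settle at X* = r with resilience min(r)", {
  p <- model_params(omega_c = 0, omega_m = 0, omega_p = 0)
  net <- generate_network(4, 4, 4, p, seed = 5, ensure_animal_degree = FALSE)
  eq <- integrate_to_equilibrium(NULL, net)
  expect_equal(c(eq$state$P, eq$state$M, eq$state$H), rep(1, 12),
               tolerance = 1e-7)
  expect_equal(eq$resilience, 1, tolerance = 1e-6)
})

test_that("energy budgets equal the plant flux terms of the growth equation", {
  net <- make_test_net(S = 6, seed = 21)
  st <- random_state(net, seed = 4)
  eb <- energy_budgets(st, net)
  expect_true(all(eb$b_mut >= 0) && all(eb$b_ant >= 0))
  # consistency: adding the fluxes back into the per-capita growth recovers rhs
  fl <- triguild:::plant_fluxes(st$P, st$M, st$H, net, net$params)
  expect_identical(eb$b_mut, unname(fl$gain))
  expect_identical(eb$b_ant, unname(fl$loss))
  dP <- unname(rhs(st, net))[1:6]
  rebuilt <- st$P * (1 - drop(net$beta_P %*% st$P) + eb$b_mut - eb$b_ant)
  expect_equal(dP, rebuilt, tolerance = 1e-12)
})

test_that("energy budget closed forms: single partner and the h = 0 limit", {
  com <- niche_community(1, 1, 1, pos_P = 0.5, pos_M = 0.5, pos_H = 0.9)
  p <- model_params(omega_c = 0, omega_m = 0.1, omega_p = 0, h = 0.1)
  mats <- assemble_matrices(com, p, matrix(1, 1, 1), matrix(0, 1, 1))
  eb <- energy_budgets(community_state(1, 1, 1), mats)
  expect_equal(eb$b_mut, 0.1 / 1.1, tolerance = 1e-12)
  expect_equal(eb$b_ant, 0)
  p0 <- model_params(omega_c = 0, omega_m = 0.1, omega_p = 0, h = 0)
  mats0 <- assemble_matrices(com, p0, matrix(1, 1, 1), matrix(0, 1, 1))
  eb0 <- energy_budgets(community_state(1, 1, 1), mats0)
  expect_equal(eb0$b_mut, 0.1, tolerance = 1e-12)
})

test_that("tidy and glance summarize equilibria", {
  net <- make_test_net(S = 3, seed = 2)
  eq <- integrate_to_equilibrium(NULL, net)
  td <- tidy(eq)
  expect_identical(nrow(td), 9L)
  expect_identical(unique(td$guild), c("plant", "pollinator", "herbivore"))
  gl <- glance(eq)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$resilience, eq$resilience)
})
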