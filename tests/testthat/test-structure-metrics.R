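test_that("NODF matches hand-computed and degenerate cases", {
  expect_equal(nodf(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))), 100)
  expect_equal(nodf(diag(2)), 0)
  expect_warning(z <- nodf(matrix(0, 3, 3)), "all-zero")
  expect_equal(z, 0)
  expect_error(nodf(matrix(1, 1, 5)), "at least 2")
  expect_error(nodf(matrix(2, 3, 3)), "binary")
})

test_that("NODF equals the pair-loop oracle on random matrices", {
  set.seed(11)
  for (i in 1:200) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    A <- matrix(rbinom(nr * nc, 1, runif(1, 0.1, 0.9)), nr, nc)
    if (sum(A) == 0) next
    expect_equal(nodf(A), naive_nodf(A), tolerance = 1e-12)
  }
})

test_that("NODF is permutation-invariant and symmetric under transposition", {
  set.seed(12)
  for (i in 1:25) {
    A <- matrix(rbinom(42, 1, 0.4), 6, 7)
    if (sum(A) == 0) next
    expect_equal(nodf(A), nodf(t(A)), tolerance = 1e-12)
    B <- A[sample(6), sample(7)]
    expect_equal(nodf(A), nodf(B), tolerance = 1e-12)
  }
})

test_that("NODF agrees with an established independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(13)
  for (i in 1:25) {
    A <- matrix(rbinom(80, 1, 0.35), 8, 10)
    if (sum(A) == 0 || any(rowSums(A) == 0) || any(colSums(A) == 0)) next
    ref <- unname(vegan::nestednodf(A, order = TRUE)$statistic["NODF"])
    expect_equal(nodf(A), ref, tolerance = 1e-10)
  }
})

test_that("modularity solves small benchmark structures exactly", {
  two_blocks <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                      c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(barber_modularity(two_blocks, seed = 1)$Q, 0.5)
  expect_equal(barber_modularity(matrix(1, 3, 4), seed = 1)$Q, 0)
  expect_error(barber_modularity(matrix(0, 3, 3)), "empty")
  # optimized Q can never fall below the single-module partition (Q = 0)
  set.seed(14)
  for (i in 1:20) {
    A <- matrix(rbinom(30, 1, 0.4), 5, 6)
    if (sum(A) == 0) next
    expect_gte(barber_modularity(A, seed = i)$Q, 0)
  }
})

test_that("heuristic modularity equals exhaustive search on small matrices", {
  set.seed(15)
  parts <- list()
  for (i in 1:300) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    A <- matrix(rbinom(nr * nc, 1, runif(1, 0.15, 0.85)), nr, nc)
    if (sum(A) == 0) next
    if (is.null(parts[[paste0("n", nr)]]))
      parts[[paste0("n", nr)]] <- set_partitions(nr)
    expect_equal(barber_modularity(A, n_restarts = 10, seed = i)$Q,
                 exhaustive_modularity(A, parts[[paste0("n", nr)]]),
                 tolerance = 1e-12)
  }
})

test_that("modularity is invariant under row and column permutations", {
  set.seed(16)
  A <- matrix(rbinom(56, 1, 0.3), 7, 8)
  q <- barber_modularity(A, seed = 1)$Q
  for (i in 1:5) {
    B <- A[sample(7), sample(8)]
    expect_equal(barber_modularity(B, seed = i)$Q, q, tolerance = 1e-10)
  }
})

test_that("null ensembles have the declared structure and edge cases", {
  A <- build_incidence(8, 8, 0.4, seed = 21)
  e <- null_ensemble(A, "nodf", n = 2, seed = 1)
  expect_equal(e$mean, mean(e$values))
  expect_identical(e$n_replicates, 2)
  expect_error(null_ensemble(A, "nodf", n = 1), ">= 2")
  # full matrix: equiprobable p = 1, every replicate identical, sd = 0
  ef <- null_ensemble(matrix(1, 4, 4), "nodf", n = 5, seed = 1)
  expect_equal(ef$sd, 0)
  expect_error(z_score_one_tailed(1, ef), "zero standard deviation")
  # degree-probabilistic model preserves degrees in expectation
  set.seed(22)
  B <- build_incidence(10, 10, 0.3, seed = 5)
  p_ij <- (matrix(rowSums(B) / 10, 10, 10) +
           matrix(colSums(B) / 10, 10, 10, byrow = TRUE)) / 2
  expect_equal(rowSums(p_ij), rowSums(B) / 2 + sum(B) / 20, tolerance = 1e-12)
  e2 <- null_ensemble(B, "nodf", model = "degree_probabilistic", n = 50,
                      seed = 2)
  expect_identical(e2$model_name, "degree_probabilistic")
  expect_true(e2$sd > 0)
})

test_that("ensemble means are self-consistent across independent reruns", {
  A <- build_incidence(10, 10, 0.3, seed = 30)
  e1 <- null_ensemble(A, "nodf", n = 300, seed = 1)
  e2 <- null_ensemble(A, "nodf", n = 1200, seed = 2)
  se <- sqrt(e1$sd^2 / e1$n_replicates + e2$sd^2 / e2$n_replicates)
  expect_lt(abs(e1$mean - e2$mean), 3 * se)
})

test_that("one-tailed z-scores use the strict 1.645 threshold", {
  ens <- structure(list(mean = 10, sd = 2), class = "null_ensemble")
  expect_equal(z_score_one_tailed(10, ens)$z, 0)
  expect_false(z_score_one_tailed(10, ens)$significant)
  zt <- z_score_one_tailed(14, ens)
  expect_equal(zt$z, 2)
  expect_true(zt$significant)
  exactly <- z_score_one_tailed(10 + 1.645 * 2, ens)
  expect_false(exactly$significant)  # strictly greater than
})

test_that("the z-test is calibrated at ~5% under its own null model", {
  # draw matrices from the equiprobable null at the study dimensions and
  # connectance, standardize against an independently drawn ensemble
  nr <- 30; nc <- 30; p <- 0.15
  set.seed(23)
  ref <- replicate(2000, nodf(matrix(rbinom(nr * nc, 1, p), nr, nc)))
  draws <- replicate(2000, nodf(matrix(rbinom(nr * nc, 1, p), nr, nc)))
  rate <- mean((draws - mean(ref)) / sd(ref) > 1.645)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rate - 0.05), 2 * se + 1e-12)
})

test_that("relative metrics compare observed structure to the null mean", {
  expect_equal(relative_metric(5, 5), 0)
  expect_equal(relative_metric(10, 5), 1)
  expect_equal(relative_metric(0, 5), -1)
  expect_error(relative_metric(1, 0), "undefined")
  expect_error(relative_metric(1, -2), "undefined")
})

test_that("structure reports cover both sub-networks and both metrics", {
  net <- make_test_net(S = 8, seed = 31)
  rep <- structure_report(net, n_null = 50, seed = 9)
  expect_identical(nrow(rep$table), 4L)
  expect_setequal(rep$table$subnetwork, c("mutualistic", "antagonistic"))
  expect_setequal(rep$table$metric, c("nodf", "modularity"))
  expect_equal(rep$table$relative,
               (rep$table$observed - rep$table$null_mean) / rep$table$null_mean,
               tolerance = 1e-12)
  expect_identical(rep$table$significant, rep$table$z > 1.645)
  f <- withr::local_tempfile(fileext = ".csv")
  write_structure_report(rep, csv_path = f)
  expect_identical(nrow(read.csv(f)), 4L)
})

test_that("plant node statistics have correct centralities and budgets", {
  com <- niche_community(3, 4, 5, seed = 40)
  p <- model_params()
  Theta_MP <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 0, 0))
  Theta_HP <- matrix(0, 5, 3); Theta_HP[1:3, 2] <- 1
  mats <- assemble_matrices(com, p, Theta_MP, Theta_HP)
  eq <- integrate_to_equilibrium(NULL, mats)
  ps <- plant_stats(mats, eq)
  expect_equal(ps$d_mut, c(1, 0.25, 0))      # plant 1 linked to all 4
  expect_equal(ps$d_ant, c(0, 0.6, 0))       # plant 2 has 3 of 5 herbivores
  eb <- energy_budgets(eq$state, mats)
  expect_identical(ps$b_mut, eb$b_mut)
  expect_identical(ps$b_ant, eb$b_ant)
  expect_equal(ps$d_diff, ps$d_mut - ps$d_ant)
  expect_true(all(ps$d_mut >= 0 & ps$d_mut <= 1))
})

test_that("the correlation suite matches first-principles computations", {
  stats <- tibble::tibble(d_mut = c(0.1, 0.2, 0.4, 0.5, 0.9),
                          d_ant = c(0.15, 0.3, 0.45, 0.7, 1.0))
  stats$d_diff <- stats$d_mut - stats$d_ant
  stats$b_diff <- 2 * stats$d_diff
  cs <- correlation_suite(stats)
  expect_equal(cs$spearman_dd, 1)
  expect_equal(cs$slope_db, 2, tolerance = 1e-12)
  expect_equal(cs$r2_db, 1, tolerance = 1e-12)
  set.seed(41)
  for (i in 1:20) {
    tb <- tibble::tibble(d_mut = runif(12), d_ant = runif(12))
    tb$d_diff <- tb$d_mut - tb$d_ant
    tb$b_diff <- runif(12)
    cs <- correlation_suite(tb)
    expect_equal(cs$spearman_dd, naive_spearman(tb$d_mut, tb$d_ant),
                 tolerance = 1e-12)
    expect_equal(cs$spearman_db, naive_spearman(tb$d_diff, tb$b_diff),
                 tolerance = 1e-12)
    fit <- lm(b_diff ~ d_diff, data = tb)
    expect_equal(cs$slope_db, unname(coef(fit)[2]), tolerance = 1e-12)
    expect_equal(cs$r2_db, summary(fit)$r.squared, tolerance = 1e-12)
  }
  # ties handled by average ranks
  tb2 <- tibble::tibble(d_mut = c(1, 1, 2, 3) / 10, d_ant = c(2, 1, 1, 3) / 10)
  tb2$d_diff <- tb2$d_mut - tb2$d_ant; tb2$b_diff <- tb2$d_diff
  expect_equal(correlation_suite(tb2)$spearman_dd,
               naive_spearman(tb2$d_mut, tb2$d_ant), tolerance = 1e-12)
  # degenerate: zero variance flagged as NA with a warning
  tb3 <- tibble::tibble(d_mut = rep(0.5, 4), d_ant = runif(4))
  tb3$d_diff <- 0; tb3$b_diff <- runif(4)
  w <- testthat::capture_warnings(cs3 <- correlation_suite(tb3))
  expect_true(any(grepl("zero variance", w)))
  expect_true(is.na(cs3$spearman_dd))
  expect_true(is.na(cs3$slope_db))
  expect_error(correlation_suite(tb3[1:2, ]), "at least 3")
})
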