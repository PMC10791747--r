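#' NODF nestedness of a binary matrix
#'
#' Classical NODF (nestedness metric based on overlap and decreasing fill):
#' for every ordered pair of rows whose marginal totals strictly decrease, the
#' paired overlap is the fraction of the poorer row's links shared with the
#' richer row; equal marginal totals contribute zero. Column pairs enter the
#' same way and the average over all row and column pairs is scaled to 0-100.
#' The value is invariant under row/column permutations and under
#' transposition.
#'
#' @param A Binary matrix with at least 2 rows and 2 columns.
#' @return NODF in `[0, 100]`; an all-zero matrix returns 0 with a warning.
#' @examples
#' nodf(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))  # 100
#' @export
nodf <- function(A) {
  A <- unname(as.matrix(A)) * 1
  if (nrow(A) < 2 || ncol(A) < 2)
    stopf("NODF needs a matrix with at least 2 rows and 2 columns")
  if (!all(A %in% c(0, 1))) stopf("matrix must be binary")
  if (sum(A) == 0) {
    warning("all-zero matrix: NODF defined as 0")
    return(0)
  }
  pair_sum <- function(M) {
    k <- rowSums(M)
    ov <- M %*% t(M)           # shared links per row pair
    kk <- outer(k, k, function(a, b) b)  # degree of the second row
    dec <- outer(k, k, `>`)    # strictly decreasing fill, row i richer
    contrib <- ifelse(dec & kk > 0, ov / kk, 0)
    sum(contrib[dec])
  }
  n_r <- nrow(A); n_c <- ncol(A)
  total <- pair_sum(A) + pair_sum(t(A))
  n_pairs <- n_r * (n_r - 1) / 2 + n_c * (n_c - 1) / 2
  100 * total / n_pairs
}

#' Barber bipartite modularity
#'
#' Maximizes Barber's bipartite modularity
#' `Q = (1/m) * sum_ij (A_ij - k_i d_j / m) * [row i and column j share a
#' module]` with a BRIM-style alternating optimizer plus module merges, run
#' from `n_restarts` random restarts (best result kept). Restarts draw from
#' R's RNG, so results are reproducible after `set.seed()` or via `seed`.
#'
#' @param A Binary incidence matrix with at least one link.
#' @param n_restarts Number of seeded restarts.
#' @param seed Optional seed.
#' @return List with `Q`, `row_modules`, `col_modules`.
#' @examples
#' A <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
#' barber_modularity(A)$Q  # 0.5
#' @export
barber_modularity <- function(A, n_restarts = 20, seed = NULL) {
  A <- unname(as.matrix(A)) * 1
  if (sum(A) == 0) stopf("modularity is undefined for an empty matrix")
  with_seed(seed, brim_modularity_cpp(A, as.integer(n_restarts)))
}

#' Null ensembles for structure metrics
#'
#' Generates `n` randomized incidence matrices and evaluates a structure
#' metric on each. Two null models are provided: `"equiprobable"` keeps the
#' dimensions and fills each cell with probability equal to the realized
#' connectance; `"degree_probabilistic"` fills cell (i, j) with probability
#' `(k_i / n_cols + d_j / n_rows) / 2`, preserving degrees in expectation.
#' All-zero replicates (on which the metrics are undefined) are redrawn and
#' counted.
#'
#' @param A Observed binary matrix.
#' @param metric `"nodf"` or `"modularity"`.
#' @param model `"equiprobable"` (default) or `"degree_probabilistic"`.
#' @param n Number of replicates (`>= 2`, default 1000).
#' @param seed Optional seed.
#' @param n_restarts Restarts per modularity optimization (replicates use a
#'   lighter search than the observed matrix).
#' @return An object of class `null_ensemble` with `values`, `mean`, `sd`,
#'   the model name and the redraw count.
#' @export
null_ensemble <- function(A, metric = c("nodf", "modularity"),
                          model = c("equiprobable", "degree_probabilistic"),
                          n = 1000, seed = NULL, n_restarts = 5) {
  metric <- match.arg(metric)
  model <- match.arg(model)
  if (n < 2) stopf("`n` must be >= 2")
  A <- unname(as.matrix(A)) * 1
  n_r <- nrow(A); n_c <- ncol(A)
  p <- switch(model,
    equiprobable = matrix(sum(A) / (n_r * n_c), n_r, n_c),
    degree_probabilistic =
      (matrix(rowSums(A) / n_c, n_r, n_c) +
       matrix(colSums(A) / n_r, n_r, n_c, byrow = TRUE)) / 2)
  eval_metric <- function(B) switch(metric,
    nodf = nodf(B),
    modularity = brim_modularity_cpp(B, n_restarts)$Q)
  redraws <- 0L
  values <- with_seed(seed, vapply(seq_len(n), function(i) {
    repeat {
      B <- matrix(rbinom(n_r * n_c, 1L, p), n_r, n_c)
      if (sum(B) > 0) break
      redraws <<- redraws + 1L
    }
    eval_metric(B)
  }, numeric(1)))
  structure(list(model_name = model, metric = metric, n_replicates = n,
                 values = values, mean = mean(values), sd = stats::sd(values),
                 redraws = redraws),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s under %s null, n = %d: mean %.4g, sd %.4g\n",
              x$metric, x$model_name, x$n_replicates, x$mean, x$sd))
  invisible(x)
}

#' One-tailed z-test against a null ensemble
#'
#' `z = (observed - null mean) / null sd`; the observed structure is declared
#' significantly larger than the null expectation when `z` strictly exceeds
#' 1.645 (upper 5% of a standard normal).
#'
#' @param observed Observed metric value.
#' @param ensemble A [null_ensemble()].
#' @param threshold Significance threshold (default 1.645).
#' @return List with `z` and `significant`.
#' @export
z_score_one_tailed <- function(observed, ensemble, threshold = 1.645) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (!is.finite(ensemble$sd) || ensemble$sd == 0)
    stopf("null ensemble has zero standard deviation; z is undefined")
  z <- (observed - ensemble$mean) / ensemble$sd
  list(z = z, significant = z > threshold)
}

#' Relative structure metric
#'
#' How much more (or less) structured the observed network is than the null
#' expectation: `(observed - null_mean) / null_mean`. Applies to both
#' relative nestedness and relative modularity.
#'
#' @param observed Observed metric value.
#' @param null_mean Mean of the metric under the null model (`> 0`).
#' @return Relative value (0 when observed equals the null mean).
#' @export
relative_metric <- function(observed, null_mean) {
  if (!is.finite(null_mean) || null_mean <= 0)
    stopf("relative metric is undefined for null mean <= 0")
  (observed - null_mean) / null_mean
}

#' Full structural report for both sub-networks
#'
#' NODF nestedness and Barber modularity of the mutualistic and antagonistic
#' incidence matrices, each standardized against a null ensemble: one-tailed
#' z-score (significance threshold 1.645), and relative values
#' `(observed - null mean) / null mean`.
#'
#' @param mats An `interaction_matrices` object (binary matrices are used).
#' @param n_null Null replicates per metric (default 1000).
#' @param model Null model, see [null_ensemble()].
#' @param seed Optional seed.
#' @param n_restarts Modularity restarts for the observed matrices.
#' @return An object of class `structure_report`; its `table` element is a
#'   tibble with one row per (sub-network, metric).
#' @export
structure_report <- function(mats, n_null = 1000,
                             model = c("equiprobable", "degree_probabilistic"),
                             seed = NULL, n_restarts = 20) {
  model <- match.arg(model)
  seeds <- child_seeds(seed, 4L)
  one <- function(A, subnet, metric, seed_i) {
    obs <- if (metric == "nodf") nodf(A)
           else barber_modularity(A, n_restarts = n_restarts, seed = seed_i)$Q
    ens <- null_ensemble(A, metric = metric, model = model, n = n_null,
                         seed = seed_i)
    zt <- tryCatch(z_score_one_tailed(obs, ens),
                   error = function(e) list(z = NA_real_, significant = NA))
    rel <- tryCatch(relative_metric(obs, ens$mean),
                    error = function(e) NA_real_)
    tibble::tibble(subnetwork = subnet, metric = metric, observed = obs,
                   null_mean = ens$mean, null_sd = ens$sd, z = zt$z,
                   significant = zt$significant, relative = rel)
  }
  tab <- dplyr::bind_rows(
    one(mats$Theta_MP, "mutualistic", "nodf", seeds[[1]]),
    one(mats$Theta_MP, "mutualistic", "modularity", seeds[[2]]),
    one(mats$Theta_HP, "antagonistic", "nodf", seeds[[3]]),
    one(mats$Theta_HP, "antagonistic", "modularity", seeds[[4]]))
  structure(list(table = tab, model = model, n_null = n_null),
            class = "structure_report")
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf("<structure_report> null model: %s (n = %d)\n", x$model, x$n_null))
  print(x$table)
  invisible(x)
}

#' Per-plant degree centralities, energy budgets and biomass
#'
#' Degree centrality of each plant in a sub-network is its partner count
#' divided by the maximum possible degree (the animal guild size): `d_mut`
#' with respect to pollinators, `d_ant` with respect to herbivores. Energy
#' budgets come from [energy_budgets()] at the supplied equilibrium.
#'
#' @param mats An `interaction_matrices` object.
#' @param eq A converged `equilibrium_result`.
#' @param params A [model_params()].
#' @return Tibble with one row per plant: `plant`, `d_mut`, `d_ant`, `b_mut`,
#'   `b_ant`, `biomass`, `d_diff`, `b_diff`.
#' @export
plant_stats <- function(mats, eq, params = mats$params) {
  com <- mats$community
  d_mut <- colSums(mats$Theta_MP) / com$S_M
  d_ant <- colSums(mats$Theta_HP) / com$S_H
  eb <- energy_budgets(eq$state, mats, params)
  tibble::tibble(plant = seq_len(com$S_P),
                 d_mut = d_mut, d_ant = d_ant,
                 b_mut = eb$b_mut, b_ant = eb$b_ant,
                 biomass = eq$state$P,
                 d_diff = d_mut - d_ant, b_diff = eb$b_mut - eb$b_ant)
}

#' Correlation and regression suite over plant node statistics
#'
#' Computes (i) the Spearman rank correlation (average ranks for ties)
#' between the two degree centralities, with the r-squared of the linear fit
#' of `d_ant` on `d_mut`; and (ii) the least-squares regression of the energy
#' budget difference `b_mut - b_ant` on the degree difference
#' `d_mut - d_ant`, returning its slope and r-squared together with the
#' Spearman correlation of that pair.
#'
#' @param stats A [plant_stats()] tibble (needs >= 3 plants).
#' @return A one-row tibble: `spearman_dd`, `r2_dd`, `slope_db`, `r2_db`,
#'   `spearman_db`. Entries are `NA` (with a warning) when a variable has
#'   zero variance.
#' @export
correlation_suite <- function(stats) {
  if (nrow(stats) < 3) stopf("need at least 3 plants")
  safe_spearman <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance: Spearman correlation undefined")
      return(NA_real_)
    }
    cor(x, y, method = "spearman")
  }
  safe_fit <- function(x, y) {
    if (stats::sd(x) == 0) {
      warning("zero variance in predictor: regression undefined")
      return(c(slope = NA_real_, r2 = NA_real_))
    }
    fit <- lm(y ~ x)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
    c(slope = unname(coef(fit)[2]), r2 = r2)
  }
  dd <- safe_fit(stats$d_mut, stats$d_ant)
  db <- safe_fit(stats$d_diff, stats$b_diff)
  tibble::tibble(spearman_dd = safe_spearman(stats$d_mut, stats$d_ant),
                 r2_dd = dd[["r2"]],
                 slope_db = db[["slope"]], r2_db = db[["r2"]],
                 spearman_db = safe_spearman(stats$d_diff, stats$b_diff))
}

#' Export a structure report
#'
#' @param report A `structure_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_structure_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(report$table, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$table, json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(report)
}
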