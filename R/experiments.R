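#' The 55-point interaction-strength grid
#'
#' The simulation design varies competition over `omega_c = 0.01..0.1` (step
#' 0.01) and mutualism/antagonism over `0.035..0.35` (step 0.035), combined on
#' a ternary simplex: integer compositions `a + b + c = 9` (`a, b, c >= 0`)
#' mapped to `omega_c = 0.01 (a + 1)`, `omega_p = 0.035 (b + 1)`,
#' `omega_m = 0.035 (c + 1)`. This yields exactly `choose(11, 2) = 55`
#' distinct triples spanning the stated ranges (the hexagonal layout of the
#' design). An explicit list of triples can be supplied instead wherever a
#' design is accepted.
#'
#' @return A tibble with columns `omega_c`, `omega_p`, `omega_m` (55 rows)
#'   and the composition indices `a`, `b`, `c`.
#' @examples
#' nrow(enumerate_strength_grid())  # 55
#' @export
enumerate_strength_grid <- function() {
  idx <- expand.grid(a = 0:9, b = 0:9)
  idx <- idx[idx$a + idx$b <= 9, ]
  idx$c <- 9 - idx$a - idx$b
  tb <- tibble::tibble(
    omega_c = 0.01 * (idx$a + 1),
    omega_p = 0.035 * (idx$b + 1),
    omega_m = 0.035 * (idx$c + 1),
    a = idx$a, b = idx$b, c = idx$c)
  stopifnot(nrow(tb) == 55, !anyDuplicated(tb[, 1:3]))
  dplyr::arrange(tb, .data$omega_c, .data$omega_p)
}

#' Run one simulation replicate
#'
#' Builds a random 3-guild network at the given interaction strengths,
#' equilibrates it (recording the "random counterpart" metrics of the
#' pre-rewiring equilibrium), runs the adaptive rewiring process, and records
#' the adaptive network's metrics. If the initial random network is not
#' locally stable it is redrawn with the next derived sub-seed (up to
#' `max_redraws`, count reported). Everything is derived from `seed`, so a
#' replicate is exactly reproducible.
#'
#' @param omega_c,omega_p,omega_m Interaction strengths.
#' @param seed Integer seed for the replicate.
#' @param params Template [model_params()] (the omegas are overridden).
#' @param S_P,S_M,S_H Guild sizes (default 30 each).
#' @param n_attempts Rewiring attempts (default `1e5`).
#' @param n_null Null replicates for structure z-scores; `0` skips the null
#'   standardization (raw NODF/Q are always reported).
#' @param max_redraws Maximum redraws of an unstable initial network.
#' @param detail Return the full objects (`trajectory`, `mats`, equilibria)
#'   alongside the summary row?
#' @param ... Passed to [run_rewiring()].
#' @return A one-row tibble (or, with `detail = TRUE`, a list with `summary`
#'   plus the underlying objects).
#' @export
run_replicate <- function(omega_c, omega_p, omega_m, seed,
                          params = model_params(), S_P = 30, S_M = 30,
                          S_H = 30, n_attempts = 1e5, n_null = 1000,
                          max_redraws = 10, detail = FALSE, ...) {
  params$omega_c <- omega_c; params$omega_p <- omega_p; params$omega_m <- omega_m
  seeds <- child_seeds(seed, max_redraws + 2L)
  redraws <- 0L
  eq0 <- NULL
  mats <- NULL
  for (k in seq_len(max_redraws + 1L)) {
    mats_try <- generate_network(S_P, S_M, S_H, params, seed = seeds[[k]])
    eq_try <- integrate_to_equilibrium(NULL, mats_try, params)
    if (isTRUE(eq_try$converged) && isTRUE(eq_try$locally_stable)) {
      mats <- mats_try; eq0 <- eq_try
      break
    }
    redraws <- redraws + 1L
  }
  if (is.null(mats))
    stopf("no locally stable initial network found in %d draws", redraws)

  metric_block <- function(mats, eq, suffix) {
    ps <- plant_stats(mats, eq, params)
    cs <- suppressWarnings(correlation_suite(ps))
    out <- tibble::tibble(
      resilience = eq$resilience, min_biomass = eq$min_biomass,
      total_P = sum(eq$state$P), total_M = sum(eq$state$M),
      total_H = sum(eq$state$H),
      N_mut = nodf(mats$Theta_MP), N_ant = nodf(mats$Theta_HP),
      Q_mut = barber_modularity(mats$Theta_MP, seed = seeds[[max_redraws + 2L]])$Q,
      Q_ant = barber_modularity(mats$Theta_HP, seed = seeds[[max_redraws + 2L]])$Q)
    out <- dplyr::bind_cols(out, cs)
    names(out) <- paste0(names(out), "_", suffix)
    out
  }
  random_block <- metric_block(mats, eq0, "random")

  traj <- run_rewiring(mats, params, n_attempts = n_attempts,
                       seed = seeds[[max_redraws + 2L]], eq0 = eq0, ...)
  adaptive_block <- metric_block(traj$mats, traj$eq, "adaptive")

  row <- dplyr::bind_cols(
    tibble::tibble(omega_c = omega_c, omega_p = omega_p, omega_m = omega_m,
                   seed = seed, redraws = redraws,
                   S_P = S_P, S_M = S_M, S_H = S_H,
                   C_mut = params$C_mut, C_ant = params$C_ant,
                   n_attempts = n_attempts,
                   log_complexity_mut = log(S_M * params$C_mut),
                   log_complexity_ant = log(S_H * params$C_ant),
                   n_accepted = traj$n_accepted,
                   n_proposals = traj$n_proposals),
    random_block, adaptive_block)
  row$relative_resilience <- row$resilience_adaptive - row$resilience_random

  if (n_null > 0) {
    rep_ad <- structure_report(traj$mats, n_null = n_null,
                               seed = seeds[[max_redraws + 2L]])
    zt <- tidyr::pivot_wider(
      rep_ad$table[, c("subnetwork", "metric", "z", "relative")],
      names_from = c("subnetwork", "metric"), values_from = c("z", "relative"))
    names(zt) <- sub("_nodf", "_N", sub("_modularity", "_Q",
                 sub("mutualistic", "mut", sub("antagonistic", "ant", names(zt)))))
    row <- dplyr::bind_cols(row, zt)
  }
  if (detail)
    list(summary = row, trajectory = traj, mats_random = mats, eq_random = eq0)
  else row
}

#' Run a sweep design
#'
#' Maps [run_replicate()] over every design point x replicate combination.
#' Replicate seeds are derived deterministically from `base_seed` and the
#' (design row, replicate) indices, so results are reproducible and
#' independent of execution order.
#'
#' @param design Tibble with columns `omega_c`, `omega_p`, `omega_m`
#'   (e.g. from [enumerate_strength_grid()]); optional per-row columns `S_M`,
#'   `S_H`, `C_mut`, `C_ant` override the defaults.
#' @param replicates Replicates per design point (default 60).
#' @param base_seed Root seed for the whole sweep.
#' @param params Template [model_params()].
#' @param progress Print one line per design point?
#' @param ... Passed to [run_replicate()].
#' @return Tibble of per-replicate rows.
#' @export
run_sweep <- function(design, replicates = 60, base_seed = 1,
                      params = model_params(), progress = FALSE, ...) {
  stopifnot(all(c("omega_c", "omega_p", "omega_m") %in% names(design)))
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    if (progress) message(sprintf("design point %d/%d", i, nrow(design)))
    row <- design[i, ]
    p_i <- params
    if ("C_mut" %in% names(row)) p_i$C_mut <- row$C_mut
    if ("C_ant" %in% names(row)) p_i$C_ant <- row$C_ant
    extra <- list(...)
    if ("S_M" %in% names(row)) extra$S_M <- row$S_M
    if ("S_H" %in% names(row)) extra$S_H <- row$S_H
    purrr::map_dfr(seq_len(replicates), function(r) {
      seed_ir <- (base_seed * 10007L + i * 101L + r) %% (.Machine$integer.max - 1L)
      do.call(run_replicate,
              c(list(omega_c = row$omega_c, omega_p = row$omega_p,
                     omega_m = row$omega_m, seed = seed_ir, params = p_i),
                extra))
    })
  })
}

#' Aggregate sweep results
#'
#' Mean and standard deviation of every numeric outcome per design point,
#' recomputable from the stored per-replicate rows.
#'
#' @param results Tibble from [run_sweep()].
#' @return Tibble with one row per (design point, outcome) and columns
#'   `mean`, `sd`, `n`.
#' @export
aggregate_sweep <- function(results) {
  keys <- intersect(c("omega_c", "omega_p", "omega_m", "S_M", "S_H",
                      "C_mut", "C_ant"), names(results))
  long <- tidyr::pivot_longer(
    results,
    cols = -dplyr::any_of(c(keys, "seed", "redraws", "n_attempts")),
    names_to = "outcome", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(keys, "outcome")))),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)), .groups = "drop")
}

#' Asymmetric sub-network complexity scenarios
#'
#' Design points in which one sub-network's complexity (richness x
#' connectance) is varied over the supplied levels while the other
#' sub-network is held constant. The natural-log complexity covariate
#' `log(S * C)` is attached for each sub-network.
#'
#' @param vary `"mutualistic"` (vary `S_M`, `C_mut`) or `"antagonistic"`.
#' @param levels Tibble or data frame with columns `S` and `C`, one row per
#'   scenario.
#' @param omega_c,omega_p,omega_m Interaction strengths of the design.
#' @param S_fixed,C_fixed Size and connectance of the sub-network held
#'   constant.
#' @return A design tibble consumable by [run_sweep()].
#' @export
asymmetric_scenarios <- function(vary = c("mutualistic", "antagonistic"),
                                 levels, omega_c, omega_p, omega_m,
                                 S_fixed = 30, C_fixed = 0.15) {
  vary <- match.arg(vary)
  levels <- tibble::as_tibble(levels)
  stopifnot(nrow(levels) >= 1, all(c("S", "C") %in% names(levels)))
  if (any(levels$S <= 0) || any(levels$C <= 0))
    stopf("scenario sizes and connectances must be positive")
  if (vary == "mutualistic")
    tb <- tibble::tibble(omega_c = omega_c, omega_p = omega_p,
                         omega_m = omega_m,
                         S_M = levels$S, C_mut = levels$C,
                         S_H = S_fixed, C_ant = C_fixed)
  else
    tb <- tibble::tibble(omega_c = omega_c, omega_p = omega_p,
                         omega_m = omega_m,
                         S_M = S_fixed, C_mut = C_fixed,
                         S_H = levels$S, C_ant = levels$C)
  tb$log_complexity_mut <- log(tb$S_M * tb$C_mut)
  tb$log_complexity_ant <- log(tb$S_H * tb$C_ant)
  tb
}

#' Latin hypercube sensitivity design
#'
#' Samples `n` points from the 6-dimensional box spanning
#' `baseline * (1 - frac)` to `baseline * (1 + frac)` for species number,
#' connectance, growth rate, half-saturation constant, conversion coefficient
#' and niche breadth, using a Latin hypercube (each of the `n` strata used
#' exactly once per dimension). Species counts are rounded to the nearest
#' integer and floored at 2.
#'
#' @param baseline Named list of baseline values: `S`, `C`, `r`, `h`, `eps`,
#'   `sigma`.
#' @param frac Half-width of the box as a fraction of baseline (default 0.3).
#' @param n Number of samples (default 10).
#' @param seed Optional seed.
#' @return A design tibble with one row per sample; the raw unit-cube
#'   coordinates are kept in the `"lhs_unit"` attribute.
#' @export
lhs_sensitivity <- function(baseline = list(S = 30, C = 0.15, r = 1, h = 0.1,
                                            eps = 0.8, sigma = 0.1),
                            frac = 0.3, n = 10, seed = NULL) {
  check_number(frac, "frac", lower = 0, upper = 1, allow_equal_upper = FALSE)
  if (n < 2) stopf("`n` must be >= 2")
  dims <- c("S", "C", "r", "h", "eps", "sigma")
  stopifnot(all(dims %in% names(baseline)))
  u <- with_seed(seed, lhs::randomLHS(n, length(dims)))
  colnames(u) <- dims
  scale_dim <- function(uu, base) base * (1 - frac) + uu * (2 * frac * base)
  tb <- tibble::as_tibble(
    purrr::map2_dfc(as.data.frame(u), baseline[dims], scale_dim))
  tb$S <- pmax(2L, as.integer(round(tb$S)))
  tb$sample <- seq_len(n)
  attr(tb, "lhs_unit") <- u
  tb
}
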