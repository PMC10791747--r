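#' Community biomass state
#'
#' Biomass vectors for the three guilds at model time `t`. All biomasses must
#' be non-negative; during integration a small floor (default `1e-9`) keeps
#' near-extinct species represented so that community dimensions stay fixed.
#'
#' @param P,M,H Numeric biomass vectors (plants, pollinators, herbivores).
#' @param t Model time.
#' @return An object of class `community_state`.
#' @export
community_state <- function(P, M, H, t = 0) {
  if (any(!is.finite(c(P, M, H))) || any(c(P, M, H) < 0))
    stopf("biomasses must be finite and non-negative")
  structure(list(P = as.numeric(P), M = as.numeric(M), H = as.numeric(H),
                 t = t), class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("<community_state> t = %.4g; totals P %.4g, M %.4g, H %.4g\n",
              x$t, sum(x$P), sum(x$M), sum(x$H)))
  invisible(x)
}

state_vector <- function(state) c(state$P, state$M, state$H)

vector_state <- function(y, mats, t = 0) {
  S_P <- mats$community$S_P; S_M <- mats$community$S_M; S_H <- mats$community$S_H
  community_state(y[seq_len(S_P)], y[S_P + seq_len(S_M)],
                  y[S_P + S_M + seq_len(S_H)], t = t)
}

# Shared saturating-flux pieces of the plant equation. The mutualistic gain of
# plant i saturates over plant i's own pollinator partners; the herbivory loss
# saturates, inside the sum over herbivores j, over herbivore j's own plant
# partners. These identical expressions define the per-plant energy budgets.
plant_fluxes <- function(P, M, H, mats, params) {
  D_P <- 1 + params$h * drop(t(mats$Theta_MP) %*% M) # per plant
  E_H <- 1 + params$h * drop(mats$Theta_HP %*% P)    # per herbivore
  list(gain = drop(mats$gamma %*% M) / D_P,
       loss = drop(mats$tau %*% (H / E_H)),
       D_P = D_P, E_H = E_H)
}

#' Lotka-Volterra derivatives of the 3-guild system
#'
#' Per-capita growth combines the intrinsic rate, within-guild competition
#' (`-beta %*% X`), and saturating (type II) cross-guild terms: plants gain
#' from pollinators and lose to herbivores, pollinators gain from their plant
#' partners, and herbivores gain `eps`-discounted intake from theirs.
#'
#' @param state A [community_state()].
#' @param mats An `interaction_matrices` object.
#' @param params A [model_params()].
#' @return Named numeric derivative vector of length `S_P + S_M + S_H`.
#' @export
rhs <- function(state, mats, params = mats$params) {
  P <- state$P; M <- state$M; H <- state$H
  if (any(!is.finite(c(P, M, H))))
    stopf("state contains non-finite biomasses")
  fl <- plant_fluxes(P, M, H, mats, params)
  D_M <- 1 + params$h * drop(mats$Theta_MP %*% P)    # per pollinator
  gain_M <- drop(t(mats$gamma) %*% P) / D_M
  gain_H <- params$eps * drop(t(mats$tau) %*% P) / fl$E_H
  dP <- P * (params$r_P - drop(mats$beta_P %*% P) + fl$gain - fl$loss)
  dM <- M * (params$r_M - drop(mats$beta_M %*% M) + gain_M)
  dH <- H * (params$r_H - drop(mats$beta_H %*% H) + gain_H)
  setNames(c(dP, dM, dH),
           c(paste0("P", seq_along(P)), paste0("M", seq_along(M)),
             paste0("H", seq_along(H))))
}

params_r_vectors <- function(mats, params) {
  list(rP = rep_len(params$r_P, mats$community$S_P),
       rM = rep_len(params$r_M, mats$community$S_M),
       rH = rep_len(params$r_H, mats$community$S_H))
}

#' Integrate the community to equilibrium
#'
#' Integrates the system in chunks of `chunk` time units until the
#' relative-derivative criterion `max_i |dX_i/dt| < tol * (1 + |X_i|)` is met
#' or `max_time` is reached. The default method is a compiled adaptive
#' Dormand-Prince 5(4) stepper; `method = "lsoda"` uses the implicit
#' stiff-capable solver from \pkg{deSolve} with the analytic Jacobian. A
#' biomass floor is applied so near-extinct species are clamped rather than
#' removed (exact zeros are absorbing and stay zero). When the equilibrium is
#' reached, local stability and resilience are evaluated from the analytic
#' Jacobian unless `compute_stability = FALSE`.
#'
#' @param state0 Initial [community_state()] (or `NULL` for all biomasses 1).
#' @param mats An `interaction_matrices` object.
#' @param params A [model_params()].
#' @param chunk Integration chunk length (time units).
#' @param max_time Maximum total integration time per call.
#' @param tol Relative-derivative equilibrium tolerance.
#' @param method `"dp45"` (compiled, default) or `"lsoda"` (deSolve).
#' @param rtol,atol Integrator relative/absolute tolerances.
#' @param floor Biomass floor.
#' @param compute_stability Evaluate the Jacobian spectrum at the end?
#' @return An object of class `equilibrium_result` with elements `state`,
#'   `converged`, `locally_stable`, `leading_eigen_real`, `resilience`
#'   (`NA` unless locally stable), `min_biomass`, and (optionally)
#'   `eigenvalues`.
#' @examples
#' net <- generate_network(5, 5, 5, model_params(omega_c = 0.05), seed = 1)
#' eq <- integrate_to_equilibrium(NULL, net)
#' eq$resilience
#' @export
integrate_to_equilibrium <- function(state0, mats, params = mats$params,
                                     chunk = 50, max_time = 5000, tol = 1e-8,
                                     method = c("dp45", "lsoda"),
                                     rtol = 1e-8, atol = 1e-10, floor = 1e-9,
                                     compute_stability = TRUE) {
  method <- match.arg(method)
  check_number(chunk, "chunk", lower = 0, allow_equal_lower = FALSE)
  check_number(tol, "tol", lower = 0, allow_equal_lower = FALSE)
  com <- mats$community
  if (is.null(state0))
    state0 <- community_state(rep(1, com$S_P), rep(1, com$S_M), rep(1, com$S_H))
  rr <- params_r_vectors(mats, params)
  if (method == "dp45") {
    res <- integrate_guilds_cpp(state_vector(state0), com$S_P, com$S_M, com$S_H,
                                rr$rP, rr$rM, rr$rH,
                                mats$beta_P, mats$beta_M, mats$beta_H,
                                mats$gamma, mats$tau,
                                mats$Theta_MP, mats$Theta_HP,
                                params$h, params$eps,
                                chunk, max_time, tol, rtol, atol, floor)
    if (isTRUE(res$failed))
      rlang::abort(sprintf("integration failed at t = %.4g", res$t),
                   class = "triguild_integration_error",
                   partial_state = vector_state(pmax(drop(res$y), 0), mats,
                                                state0$t + res$t))
    y <- drop(res$y); t_end <- state0$t + res$t; converged <- res$converged
  } else {
    dfun <- function(t, y, p) {
      st <- vector_state(y, mats, t)
      list(unname(rhs(st, mats, params)))
    }
    jfun <- function(t, y, p)
      analytic_jacobian(vector_state(y, mats, t), mats, params)
    y <- state_vector(state0)
    t_end <- state0$t
    converged <- FALSE
    elapsed <- 0
    while (elapsed < max_time) {
      span <- min(chunk, max_time - elapsed)
      out <- deSolve::ode(y, c(0, span), dfun, parms = NULL,
                          method = "lsoda", jacfunc = jfun, jactype = "fullusr",
                          rtol = rtol, atol = atol)
      y <- out[nrow(out), -1]
      y <- ifelse(y != 0 & y < floor, floor, y)
      elapsed <- elapsed + span
      t_end <- t_end + span
      d <- rhs(vector_state(y, mats), mats, params)
      at_floor <- y <= floor & d < 0
      if (max(abs(d[!at_floor]) / (1 + abs(y[!at_floor])), 0) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  state <- vector_state(pmax(y, 0), mats, t_end)
  res <- structure(list(state = state, converged = converged,
                        locally_stable = NA, leading_eigen_real = NA_real_,
                        resilience = NA_real_,
                        min_biomass = min(state_vector(state)),
                        eigenvalues = NULL),
                   class = "equilibrium_result")
  if (compute_stability) {
    J <- analytic_jacobian(state, mats, params)
    ev <- eigen(J, only.values = TRUE)$values
    lead <- max(Re(ev))
    res$eigenvalues <- ev
    res$leading_eigen_real <- lead
    res$locally_stable <- lead < 0
    res$resilience <- if (lead < 0) -lead else NA_real_
  }
  res
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("<equilibrium_result> converged: %s; locally stable: %s\n",
              x$converged, x$locally_stable))
  if (!is.na(x$resilience))
    cat(sprintf("  resilience: %.6g\n", x$resilience))
  cat(sprintf("  min biomass: %.4g; t = %.4g\n", x$min_biomass, x$state$t))
  invisible(x)
}

#' Analytic Jacobian of the 3-guild system
#'
#' Exact partial derivatives of the Lotka-Volterra equations, including the
#' quotient-rule terms generated by the type II denominators: because a
#' herbivore's saturation pools all of its plant partners, the derivative of
#' plant i's herbivory loss with respect to plant k is nonzero whenever k is a
#' partner of a herbivore shared with i.
#'
#' @inheritParams rhs
#' @return Square matrix of order `S_P + S_M + S_H`.
#' @export
analytic_jacobian <- function(state, mats, params = mats$params) {
  P <- state$P; M <- state$M; H <- state$H
  com <- mats$community
  if (length(P) != com$S_P || length(M) != com$S_M || length(H) != com$S_H)
    stopf("state dimensions do not match the community")
  h <- params$h; eps <- params$eps
  rr <- params_r_vectors(mats, params)
  fl <- plant_fluxes(P, M, H, mats, params)
  D_P <- fl$D_P; E_H <- fl$E_H
  D_M <- 1 + h * drop(mats$Theta_MP %*% P)
  num_P <- drop(mats$gamma %*% M)         # plant mutualistic numerators
  num_M <- drop(t(mats$gamma) %*% P)      # pollinator numerators
  num_H <- drop(t(mats$tau) %*% P)        # herbivore numerators

  F_P <- rr$rP - drop(mats$beta_P %*% P) + fl$gain - fl$loss
  F_M <- rr$rM - drop(mats$beta_M %*% M) + num_M / D_M
  F_H <- rr$rH - drop(mats$beta_H %*% H) + eps * num_H / E_H

  tMP <- t(mats$Theta_MP)                 # S_P x S_M mask
  # dF_P/dP: competition plus the shared-herbivore quotient term
  dFP_dP <- -mats$beta_P +
    h * sweep(mats$tau, 2, H / E_H^2, `*`) %*% mats$Theta_HP
  dFP_dM <- sweep(mats$gamma, 1, D_P, `/`) -
    h * sweep(tMP, 1, num_P / D_P^2, `*`)
  dFP_dH <- -sweep(mats$tau, 2, E_H, `/`)

  dFM_dP <- sweep(t(mats$gamma), 1, D_M, `/`) -
    h * sweep(mats$Theta_MP, 1, num_M / D_M^2, `*`)
  dFH_dP <- eps * sweep(t(mats$tau), 1, E_H, `/`) -
    eps * h * sweep(mats$Theta_HP, 1, num_H / E_H^2, `*`)

  J_PP <- diag(F_P, com$S_P) + P * dFP_dP
  J_PM <- P * dFP_dM
  J_PH <- P * dFP_dH
  J_MP <- M * dFM_dP
  J_MM <- diag(F_M, com$S_M) + M * (-mats$beta_M)
  J_MH <- matrix(0, com$S_M, com$S_H)
  J_HP <- H * dFH_dP
  J_HM <- matrix(0, com$S_H, com$S_M)
  J_HH <- diag(F_H, com$S_H) + H * (-mats$beta_H)

  rbind(cbind(J_PP, J_PM, J_PH),
        cbind(J_MP, J_MM, J_MH),
        cbind(J_HP, J_HM, J_HH))
}

#' Resilience at a locally stable equilibrium
#'
#' Resilience is the recovery rate after a small perturbation: the absolute
#' value of the largest real part over all Jacobian eigenvalues, defined only
#' when the equilibrium is locally asymptotically stable (all real parts
#' negative); otherwise `NA` is returned and the result is flagged unstable.
#'
#' @param eq An `equilibrium_result` carrying a Jacobian evaluation.
#' @return Non-negative resilience, or `NA` if not locally stable.
#' @export
resilience <- function(eq) {
  stopifnot(inherits(eq, "equilibrium_result"))
  if (is.na(eq$leading_eigen_real))
    stopf("equilibrium carries no stability evaluation; rerun with compute_stability = TRUE")
  if (eq$leading_eigen_real < 0) -eq$leading_eigen_real else NA_real_
}

#' Per-plant energy budgets at equilibrium
#'
#' For each plant, the per-capita energy intake from pollinators (`b_mut`) and
#' the per-capita loss to herbivores (`b_ant`), using exactly the saturating
#' flux expressions of the plant growth equation.
#'
#' @inheritParams rhs
#' @return A tibble with columns `plant`, `b_mut`, `b_ant`.
#' @export
energy_budgets <- function(state, mats, params = mats$params) {
  fl <- plant_fluxes(state$P, state$M, state$H, mats, params)
  tibble::tibble(plant = seq_along(state$P), b_mut = fl$gain, b_ant = fl$loss)
}

#' Export a trajectory of states as tidy CSV
#'
#' @param states List of [community_state()] snapshots.
#' @param path CSV path.
#' @param stride Keep every `stride`-th snapshot.
#' @return The tibble written, invisibly.
#' @export
write_trajectory_csv <- function(states, path, stride = 1L) {
  keep <- states[seq(1, length(states), by = stride)]
  tb <- purrr::map_dfr(keep, function(s) {
    tibble::tibble(
      t = s$t,
      guild = rep(c("plant", "pollinator", "herbivore"),
                  c(length(s$P), length(s$M), length(s$H))),
      species_index = c(seq_along(s$P), seq_along(s$M), seq_along(s$H)),
      biomass = c(s$P, s$M, s$H))
  })
  write.csv(tb, path, row.names = FALSE)
  invisible(tb)
}
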