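#' Probability of abandoning a plant partner
#'
#' An animal discontinues its interaction with plant `j` with probability
#' `1 - 1/psi_j`, where `psi_j` is the number of partners plant `j` has within
#' the focal animal's guild: the more specialized (fewer-partnered) a plant,
#' the less likely it is abandoned, and a plant with a single partner is never
#' abandoned.
#'
#' @param psi Integer partner count (`>= 1`); vectorized.
#' @return Detachment probability in `[0, 1)`.
#' @examples
#' rewiring_probability(c(1, 2, 4))
#' @export
rewiring_probability <- function(psi) {
  if (any(!is.finite(psi)) || any(psi < 1))
    stopf("`psi` must be >= 1")
  1 - 1 / psi
}

#' Propose a single rewiring event
#'
#' Draws one animal uniformly from the pooled pollinator + herbivore guilds,
#' one of its current plant partners `j` uniformly, triggers detachment with
#' probability `1 - 1/psi_j`, and, if triggered, draws the attachment target
#' uniformly from the plants not currently linked to that animal. The attempt
#' yields no proposal when the animal has no partner, detachment is not
#' triggered, or no unlinked plant exists; such attempts still count in the
#' attempt tally.
#'
#' Uses the current RNG stream; seed via `set.seed()` for reproducibility.
#'
#' @param mats An `interaction_matrices` object.
#' @return An object of class `rewiring_proposal`. Its `triggered` field is
#'   `FALSE` for no-proposal attempts, with the reason in `reason`.
#' @export
propose_rewire <- function(mats) {
  com <- mats$community
  a <- sample.int(com$S_M + com$S_H, 1L)
  if (a <= com$S_M) {
    guild <- "pollinator"; animal <- a; Theta <- mats$Theta_MP
  } else {
    guild <- "herbivore"; animal <- a - com$S_M; Theta <- mats$Theta_HP
  }
  partners <- which(Theta[animal, ] == 1L)
  prop <- list(guild = guild, animal = animal, detach_plant = NA_integer_,
               attach_plant = NA_integer_, psi = NA_integer_,
               p_detach = NA_real_, triggered = FALSE, reason = NA_character_)
  class(prop) <- "rewiring_proposal"
  if (length(partners) == 0L) {
    prop$reason <- "no_partner"
    return(prop)
  }
  j <- partners[sample.int(length(partners), 1L)]
  psi <- sum(Theta[, j])
  p <- rewiring_probability(psi)
  prop$detach_plant <- j; prop$psi <- as.integer(psi); prop$p_detach <- p
  if (runif(1) >= p) {
    prop$reason <- "not_triggered"
    return(prop)
  }
  free <- which(Theta[animal, ] == 0L)
  if (length(free) == 0L) {
    prop$reason <- "no_attach_target"
    return(prop)
  }
  prop$attach_plant <- free[sample.int(length(free), 1L)]
  prop$triggered <- TRUE
  prop
}

#' @export
print.rewiring_proposal <- function(x, ...) {
  if (x$triggered)
    cat(sprintf("<rewiring_proposal> %s %d: plant %d -> plant %d (psi = %d, p = %.3f)\n",
                x$guild, x$animal, x$detach_plant, x$attach_plant, x$psi,
                x$p_detach))
  else
    cat(sprintf("<rewiring_proposal> no proposal (%s)\n", x$reason))
  invisible(x)
}

# Apply a triggered proposal: update the incidence matrix and the matching
# strength matrix (new link strength = omega * niche overlap; old link 0).
apply_proposal <- function(mats, prop, params = mats$params) {
  a <- prop$animal; j <- prop$detach_plant; k <- prop$attach_plant
  if (prop$guild == "pollinator") {
    mats$Theta_MP[a, j] <- 0L; mats$Theta_MP[a, k] <- 1L
    mats$gamma[j, a] <- 0
    mats$gamma[k, a] <- params$omega_m * mats$alpha_PM[k, a]
  } else {
    mats$Theta_HP[a, j] <- 0L; mats$Theta_HP[a, k] <- 1L
    mats$tau[j, a] <- 0
    mats$tau[k, a] <- params$omega_p * mats$alpha_PH[k, a]
  }
  mats
}

focal_biomass <- function(eq, prop) {
  if (prop$guild == "pollinator") eq$state$M[prop$animal]
  else eq$state$H[prop$animal]
}

#' Evaluate a rewiring proposal against the biomass-gain rule
#'
#' Applies the partner swap, re-equilibrates the community from the previous
#' equilibrium (warm start, integrated in chunks of `chunk` time units until
#' the equilibrium criterion is met, up to `max_chunks` chunks), and accepts
#' the swap only if the focal animal's equilibrium biomass strictly exceeds
#' its pre-swap value (by more than `epsilon`). On rejection the incidence and
#' strength matrices and the equilibrium state are all restored, so a
#' rejected attempt leaves the system bit-identical.
#'
#' @param prop A triggered [propose_rewire()] proposal.
#' @param mats Current `interaction_matrices`.
#' @param eq_before Converged `equilibrium_result` of the current network.
#' @param params A [model_params()].
#' @param chunk Inter-event integration interval (time units).
#' @param max_chunks Maximum chunks per evaluation.
#' @param epsilon Acceptance tolerance (default 0: strict increase).
#' @param ... Passed to [integrate_to_equilibrium()].
#' @return List with elements `accepted`, `mats`, `eq` (the post-decision
#'   matrices and equilibrium) and `eq_candidate` (the post-swap equilibrium,
#'   also on rejection).
#' @export
evaluate_proposal <- function(prop, mats, eq_before, params = mats$params,
                              chunk = 50, max_chunks = 20, epsilon = 0, ...) {
  stopifnot(inherits(prop, "rewiring_proposal"), isTRUE(prop$triggered))
  cand <- apply_proposal(mats, prop, params)
  eq_after <- tryCatch(
    integrate_to_equilibrium(eq_before$state, cand, params, chunk = chunk,
                             max_time = chunk * max_chunks,
                             compute_stability = FALSE, ...),
    error = function(e) NULL)
  if (is.null(eq_after))
    return(list(accepted = FALSE, mats = mats, eq = eq_before,
                eq_candidate = NULL, error = TRUE))
  gain <- focal_biomass(eq_after, prop) - focal_biomass(eq_before, prop)
  if (gain > epsilon)
    list(accepted = TRUE, mats = cand, eq = eq_after, eq_candidate = eq_after,
         error = FALSE)
  else
    list(accepted = FALSE, mats = mats, eq = eq_before,
         eq_candidate = eq_after, error = FALSE)
}

#' Run the adaptive rewiring process
#'
#' Executes `n_attempts` sequential propose/evaluate cycles starting from an
#' equilibrated, locally stable network. Every attempt is counted, including
#' untriggered detachments and no-proposal cases. Species richness and the
#' realized link counts of both sub-networks are conserved throughout (a swap
#' removes one link and adds one). Periodic snapshots record guild biomass
#' totals and link counts, optionally with raw sub-network structure metrics,
#' and structure metrics are additionally sampled over the final
#' `metrics_window` attempts.
#'
#' @param mats Initial `interaction_matrices`.
#' @param params A [model_params()].
#' @param n_attempts Number of rewiring attempts (default `1e5`).
#' @param snapshot_every Snapshot interval in attempts.
#' @param seed Optional seed for the proposal stream.
#' @param eq0 Optional pre-computed initial equilibrium (must be converged
#'   and locally stable); computed from all-ones biomass when `NULL`.
#' @param chunk,max_chunks,epsilon Passed to [evaluate_proposal()].
#' @param metrics_window Length (in attempts) of the final window over which
#'   structure metrics are sampled; `0` disables window sampling.
#' @param metrics_every Sampling stride within the final window (default:
#'   `metrics_window / 10`).
#' @param snapshot_metrics Also compute NODF/modularity at every snapshot?
#' @param progress Print progress every `snapshot_every` attempts?
#' @return An object of class `rewiring_trajectory`: per-attempt tibble
#'   (`attempts`), snapshot tibble (`snapshots`), window metric samples
#'   (`window_metrics`), final matrices (`mats`), final equilibrium with
#'   stability (`eq`), and bookkeeping counts.
#' @export
run_rewiring <- function(mats, params = mats$params, n_attempts = 1e5,
                         snapshot_every = max(1L, floor(n_attempts / 100)),
                         seed = NULL, eq0 = NULL, chunk = 50, max_chunks = 20,
                         epsilon = 0, metrics_window = min(1e4, n_attempts),
                         metrics_every = NULL, snapshot_metrics = FALSE,
                         progress = FALSE) {
  if (is.null(eq0))
    eq0 <- integrate_to_equilibrium(NULL, mats, params, chunk = chunk)
  if (!isTRUE(eq0$converged)) stopf("initial network failed to equilibrate")
  if (!isTRUE(eq0$locally_stable))
    stopf("initial network is not locally stable; refusing to start rewiring")
  init_links <- link_counts(mats)
  n_attempts <- as.integer(n_attempts)
  if (is.null(metrics_every) && metrics_window > 0)
    metrics_every <- max(1L, floor(metrics_window / 10))

  att <- list(attempt = integer(n_attempts), guild = character(n_attempts),
              animal = integer(n_attempts), detach = integer(n_attempts),
              attach = integer(n_attempts), psi = integer(n_attempts),
              triggered = logical(n_attempts), accepted = logical(n_attempts),
              focal_before = numeric(n_attempts),
              focal_after = numeric(n_attempts))
  snaps <- list()
  wmetrics <- list()
  take_snapshot <- function(attempt, eq, mats) {
    row <- tibble::tibble(attempt = attempt,
                          total_P = sum(eq$state$P), total_M = sum(eq$state$M),
                          total_H = sum(eq$state$H),
                          links_mut = unname(link_counts(mats)[1]),
                          links_ant = unname(link_counts(mats)[2]))
    if (snapshot_metrics) {
      row$N_mut <- nodf(mats$Theta_MP); row$N_ant <- nodf(mats$Theta_HP)
      row$Q_mut <- barber_modularity(mats$Theta_MP)$Q
      row$Q_ant <- barber_modularity(mats$Theta_HP)$Q
    }
    row
  }

  eq <- eq0
  with_seed(seed, {
    snaps[[length(snaps) + 1L]] <- take_snapshot(0L, eq, mats)
    for (i in seq_len(n_attempts)) {
      prop <- propose_rewire(mats)
      att$attempt[i] <- i
      att$guild[i] <- prop$guild
      att$animal[i] <- prop$animal
      att$detach[i] <- prop$detach_plant
      att$attach[i] <- prop$attach_plant
      att$psi[i] <- prop$psi
      att$triggered[i] <- prop$triggered
      if (prop$triggered) {
        before <- focal_biomass(eq, prop)
        ev <- evaluate_proposal(prop, mats, eq, params, chunk = chunk,
                                max_chunks = max_chunks, epsilon = epsilon)
        att$accepted[i] <- ev$accepted
        att$focal_before[i] <- before
        att$focal_after[i] <- if (is.null(ev$eq_candidate)) NA_real_
                              else focal_biomass(ev$eq_candidate, prop)
        mats <- ev$mats
        eq <- ev$eq
      } else {
        att$accepted[i] <- FALSE
        att$focal_before[i] <- NA_real_
        att$focal_after[i] <- NA_real_
      }
      if (i %% snapshot_every == 0L || i == n_attempts) {
        snaps[[length(snaps) + 1L]] <- take_snapshot(i, eq, mats)
        if (progress)
          message(sprintf("attempt %d/%d (accepted so far: %d)", i, n_attempts,
                          sum(att$accepted[seq_len(i)])))
      }
      if (metrics_window > 0 && i > n_attempts - metrics_window &&
          (i %% metrics_every == 0L || i == n_attempts)) {
        wmetrics[[length(wmetrics) + 1L]] <- tibble::tibble(
          attempt = i,
          N_mut = nodf(mats$Theta_MP), N_ant = nodf(mats$Theta_HP),
          Q_mut = barber_modularity(mats$Theta_MP)$Q,
          Q_ant = barber_modularity(mats$Theta_HP)$Q)
      }
    }
  })
  final_eq <- integrate_to_equilibrium(eq$state, mats, params, chunk = chunk,
                                       compute_stability = TRUE)
  snapshots <- dplyr::bind_rows(snaps)
  stopifnot(all(snapshots$links_mut == init_links[["mutualistic"]]),
            all(snapshots$links_ant == init_links[["antagonistic"]]))
  structure(list(
    attempts = tibble::as_tibble(att), snapshots = snapshots,
    window_metrics = if (length(wmetrics)) dplyr::bind_rows(wmetrics) else NULL,
    mats = mats, eq = final_eq, eq0 = eq0, params = params,
    n_attempts = n_attempts, seed = seed,
    n_proposals = sum(att$triggered), n_accepted = sum(att$accepted)),
    class = "rewiring_trajectory")
}

#' @export
print.rewiring_trajectory <- function(x, ...) {
  cat(sprintf("<rewiring_trajectory> %d attempts, %d proposals, %d accepted\n",
              x$n_attempts, x$n_proposals, x$n_accepted))
  cat(sprintf("  final resilience: %.6g (locally stable: %s)\n",
              x$eq$resilience, x$eq$locally_stable))
  invisible(x)
}

#' Checkpoint and restore a rewiring run
#'
#' Serializes matrices, equilibrium state and the RNG stream so long runs can
#' be resumed. The archive is a single RDS file.
#'
#' @param traj A `rewiring_trajectory` (or any list of engine state).
#' @param path Archive path.
#' @return `restore_checkpoint()` returns the stored object; the RNG stream
#'   is reinstated as a side effect if one was saved.
#' @export
save_checkpoint <- function(traj, path) {
  rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(object = traj, rng = rng), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
restore_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!is.null(x$rng)) assign(".Random.seed", x$rng, envir = globalenv())
  x$object
}

#' Export a trajectory's attempt and snapshot tables
#'
#' @param traj A `rewiring_trajectory`.
#' @param attempts_path,snapshots_path CSV paths (either may be `NULL`).
#' @return `traj`, invisibly.
#' @export
write_trajectory_tables <- function(traj, attempts_path = NULL,
                                    snapshots_path = NULL) {
  if (!is.null(attempts_path))
    write.csv(traj$attempts, attempts_path, row.names = FALSE)
  if (!is.null(snapshots_path))
    write.csv(traj$snapshots, snapshots_path, row.names = FALSE)
  invisible(traj)
}
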