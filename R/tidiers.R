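#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom rlang .data
NULL

#' Tidy an equilibrium result into a per-species tibble
#'
#' @param x An `equilibrium_result`.
#' @param ... Unused.
#' @return Tibble with columns `guild`, `species_index`, `biomass`.
#' @export
tidy.equilibrium_result <- function(x, ...) {
  s <- x$state
  tibble::tibble(
    guild = rep(c("plant", "pollinator", "herbivore"),
                c(length(s$P), length(s$M), length(s$H))),
    species_index = c(seq_along(s$P), seq_along(s$M), seq_along(s$H)),
    biomass = c(s$P, s$M, s$H))
}

#' @rdname tidy.equilibrium_result
#' @export
glance.equilibrium_result <- function(x, ...) {
  tibble::tibble(converged = x$converged, locally_stable = x$locally_stable,
                 leading_eigen_real = x$leading_eigen_real,
                 resilience = x$resilience, min_biomass = x$min_biomass,
                 t = x$state$t)
}

#' Tidy a rewiring trajectory
#'
#' `tidy()` returns the per-attempt table; `glance()` a one-row summary.
#'
#' @param x A `rewiring_trajectory`.
#' @param ... Unused.
#' @export
tidy.rewiring_trajectory <- function(x, ...) x$attempts

#' @rdname tidy.rewiring_trajectory
#' @export
glance.rewiring_trajectory <- function(x, ...) {
  tibble::tibble(n_attempts = x$n_attempts, n_proposals = x$n_proposals,
                 n_accepted = x$n_accepted,
                 acceptance_rate = x$n_accepted / max(1L, x$n_attempts),
                 resilience = x$eq$resilience,
                 locally_stable = x$eq$locally_stable,
                 links_mut = unname(link_counts(x$mats)[1]),
                 links_ant = unname(link_counts(x$mats)[2]))
}

#' Tidy a structure report or null ensemble
#'
#' @param x A `structure_report` or `null_ensemble`.
#' @param ... Unused.
#' @export
tidy.structure_report <- function(x, ...) x$table

#' @rdname tidy.structure_report
#' @export
tidy.null_ensemble <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$values), value = x$values)
}

#' @rdname tidy.structure_report
#' @export
glance.null_ensemble <- function(x, ...) {
  tibble::tibble(metric = x$metric, model = x$model_name,
                 n_replicates = x$n_replicates, mean = x$mean, sd = x$sd,
                 redraws = x$redraws)
}

#' Plot guild biomass totals along a rewiring trajectory
#'
#' @param object A `rewiring_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rewiring_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object$snapshots,
                              cols = c("total_P", "total_M", "total_H"),
                              names_to = "guild", values_to = "total_biomass")
  long$guild <- factor(long$guild, levels = c("total_P", "total_M", "total_H"),
                       labels = c("plants", "pollinators", "herbivores"))
  ggplot2::ggplot(long, ggplot2::aes(.data$attempt, .data$total_biomass,
                                     colour = .data$guild)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rewiring attempt", y = "total biomass",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot observed vs null structure metrics
#'
#' Bar chart of the z-scores of nestedness and modularity for both
#' sub-networks, with the one-tailed significance threshold marked.
#'
#' @param object A `structure_report`.
#' @param threshold Significance line (default 1.645).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_report <- function(object, threshold = 1.645, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(.data$metric, .data$z,
                                    fill = .data$subnetwork)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(y = "one-tailed z-score", x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of plant degree centralities
#'
#' Each point is a plant; size is proportional to equilibrium biomass. Panel
#' choice: `which = "dd"` plots `d_ant` against `d_mut`; `which = "db"` plots
#' the energy-budget difference against the degree difference, with the
#' least-squares fit.
#'
#' @param stats A [plant_stats()] tibble.
#' @param which `"dd"` or `"db"`.
#' @return A ggplot object.
#' @export
plot_plant_stats <- function(stats, which = c("dd", "db")) {
  which <- match.arg(which)
  if (which == "dd") {
    ggplot2::ggplot(stats, ggplot2::aes(.data$d_mut, .data$d_ant)) +
      ggplot2::geom_point(ggplot2::aes(size = .data$biomass), alpha = 0.6) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "red", show.legend = FALSE) +
      ggplot2::labs(x = "degree centrality (pollinators)",
                    y = "degree centrality (herbivores)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(stats, ggplot2::aes(.data$d_diff, .data$b_diff)) +
      ggplot2::geom_point(ggplot2::aes(size = .data$biomass), alpha = 0.6) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "red", show.legend = FALSE) +
      ggplot2::labs(x = "degree centrality difference (d_mut - d_ant)",
                    y = "energy budget difference (b_mut - b_ant)") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
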