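#' Model parameters for the 3-guild community
#'
#' Bundles every scalar the simulator needs: the interaction-strength scalars
#' at perfect niche overlap (`omega_c` for within-guild competition, `omega_m`
#' for mutualism, `omega_p` for antagonism), per-capita intrinsic growth rates,
#' the half-saturation constant of the type II functional response, the
#' predation conversion efficiency, the target connectances of the two
#' bipartite sub-networks, and the Gaussian niche breadth.
#'
#' Defaults are the reference values used throughout the package's simulation
#' experiments: growth rates 1, `h = 0.1`, `eps = 0.8`, connectances 0.15 and
#' niche breadth 0.1.
#'
#' @param omega_c,omega_m,omega_p Interaction strength for perfect niche
#'   overlap (competition, mutualism, antagonism); all `>= 0`.
#' @param r_P,r_M,r_H Per-capita intrinsic growth rates (plants, pollinators,
#'   herbivores).
#' @param h Half-saturation constant of the type II functional response.
#' @param eps Conversion coefficient of predation, in `(0, 1]`.
#' @param C_mut,C_ant Target connectance of the mutualistic and antagonistic
#'   sub-networks, in `[0, 1]`.
#' @param sigma Niche breadth (`> 0`) of the Gaussian niche profiles.
#' @return An object of class `model_params` (a named list).
#' @examples
#' model_params(omega_c = 0.1, omega_m = 0.1, omega_p = 0.1)
#' @export
model_params <- function(omega_c = 0.05, omega_m = 0.175, omega_p = 0.175,
                         r_P = 1, r_M = 1, r_H = 1,
                         h = 0.1, eps = 0.8,
                         C_mut = 0.15, C_ant = 0.15, sigma = 0.1) {
  check_number(omega_c, "omega_c", lower = 0)
  check_number(omega_m, "omega_m", lower = 0)
  check_number(omega_p, "omega_p", lower = 0)
  check_number(h, "h", lower = 0)
  check_number(eps, "eps", lower = 0, upper = 1, allow_equal_lower = FALSE)
  check_number(C_mut, "C_mut", lower = 0, upper = 1)
  check_number(C_ant, "C_ant", lower = 0, upper = 1)
  check_number(sigma, "sigma", lower = 0, allow_equal_lower = FALSE)
  structure(list(omega_c = omega_c, omega_m = omega_m, omega_p = omega_p,
                 r_P = r_P, r_M = r_M, r_H = r_H, h = h, eps = eps,
                 C_mut = C_mut, C_ant = C_ant, sigma = sigma),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  Omega (c, m, p): %.4g, %.4g, %.4g\n",
              x$omega_c, x$omega_m, x$omega_p))
  cat(sprintf("  r (P, M, H): %.3g, %.3g, %.3g   h: %.3g   eps: %.3g\n",
              x$r_P, x$r_M, x$r_H, x$h, x$eps))
  cat(sprintf("  C (mut, ant): %.3g, %.3g   sigma: %.3g\n",
              x$C_mut, x$C_ant, x$sigma))
  invisible(x)
}

#' Read or write a simulation configuration file
#'
#' Configurations are stored as flat JSON holding every [model_params()] field
#' plus optional guild sizes and seeds. Unknown keys are preserved and
#' returned in the `extra` attribute.
#'
#' @param path File path.
#' @param params A `model_params` object.
#' @param ... Extra scalar fields to store alongside the parameters (for
#'   example `S_P`, `seed`).
#' @return `read_config()` returns a list with elements `params` (a
#'   `model_params`) and `extra` (named list of any non-parameter keys).
#' @export
write_config <- function(params, path, ...) {
  stopifnot(inherits(params, "model_params"))
  extra <- list(...)
  jsonlite::write_json(c(unclass(params), extra), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(model_params))
  pars <- raw[intersect(names(raw), known)]
  params <- do.call(model_params, pars)
  list(params = params, extra = raw[setdiff(names(raw), known)])
}
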