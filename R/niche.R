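#' Sample niche central positions
#'
#' Each species carries a Gaussian niche profile on a one-dimensional niche
#' axis; its central position is drawn independently and uniformly on
#' `[0, 1]`.
#'
#' @param n Number of species (`>= 1`).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG stream is left untouched.
#' @return Numeric vector of length `n` with values in `[0, 1]`.
#' @examples
#' sample_niche_positions(5, seed = 1)
#' @export
sample_niche_positions <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stopf("`n` must be a positive integer (got %s)", deparse(n))
  with_seed(seed, runif(as.integer(n)))
}

#' Gaussian niche-overlap coefficient
#'
#' The interaction coefficient between two species is the ratio of their
#' interspecific niche overlap to the conspecific overlap, which for Gaussian
#' niche profiles of common breadth `sigma` has the closed form
#' `exp(-(s_i - s_j)^2 / (4 sigma^2))`. It is symmetric, equals 1 at zero
#' niche distance and decays with distance. Vectorized over `s_i`, `s_j`.
#'
#' @param s_i,s_j Niche central positions.
#' @param sigma Niche breadth (`> 0`).
#' @return Values in `(0, 1]`.
#' @examples
#' niche_overlap_coefficient(0.1, 0.3, sigma = 0.1)  # exp(-1)
#' @export
niche_overlap_coefficient <- function(s_i, s_j, sigma) {
  check_number(sigma, "sigma", lower = 0, allow_equal_lower = FALSE)
  exp(-((s_i - s_j)^2) / (4 * sigma^2))
}

# Dense overlap matrix between two position vectors.
alpha_matrix <- function(pos_rows, pos_cols, sigma) {
  outer(pos_rows, pos_cols,
        function(a, b) niche_overlap_coefficient(a, b, sigma))
}

#' Construct a niche-based community
#'
#' A community is the list of guild sizes together with the niche positions of
#' every species; positions are fixed for the lifetime of a community (species
#' identity is guild + index + position). Child seeds for the three guilds are
#' derived from `seed` in the order plants, pollinators, herbivores.
#'
#' @param S_P,S_M,S_H Species counts for plants, pollinators, herbivores.
#' @param sigma Niche breadth.
#' @param seed Optional integer root seed.
#' @param pos_P,pos_M,pos_H Optional explicit position vectors (override
#'   sampling; lengths must match the guild sizes).
#' @return An object of class `niche_community`.
#' @examples
#' niche_community(10, 10, 10, seed = 42)
#' @export
niche_community <- function(S_P, S_M, S_H, sigma = 0.1, seed = NULL,
                            pos_P = NULL, pos_M = NULL, pos_H = NULL) {
  check_number(sigma, "sigma", lower = 0, allow_equal_lower = FALSE)
  seeds <- child_seeds(seed, 3L)
  pos_P <- if (is.null(pos_P)) sample_niche_positions(S_P, seeds[[1]]) else pos_P
  pos_M <- if (is.null(pos_M)) sample_niche_positions(S_M, seeds[[2]]) else pos_M
  pos_H <- if (is.null(pos_H)) sample_niche_positions(S_H, seeds[[3]]) else pos_H
  if (length(pos_P) != S_P || length(pos_M) != S_M || length(pos_H) != S_H)
    stopf("position vector lengths must equal the declared guild sizes")
  if (any(c(pos_P, pos_M, pos_H) < 0) || any(c(pos_P, pos_M, pos_H) > 1))
    stopf("niche positions must lie in [0, 1]")
  structure(list(S_P = S_P, S_M = S_M, S_H = S_H,
                 pos_P = pos_P, pos_M = pos_M, pos_H = pos_H,
                 sigma = sigma),
            class = "niche_community")
}

#' @export
print.niche_community <- function(x, ...) {
  cat(sprintf("<niche_community> %d plants, %d pollinators, %d herbivores (sigma = %.3g)\n",
              x$S_P, x$S_M, x$S_H, x$sigma))
  invisible(x)
}

#' Draw a random bipartite incidence matrix
#'
#' Every animal-plant link is an independent Bernoulli draw with probability
#' equal to the target connectance `C`. With `ensure_animal_degree = TRUE`
#' (the default in network assembly) any all-zero animal row is redrawn until
#' it has at least one partner, so every animal can later take part in
#' rewiring; the number of redraws is recorded in the `"redraws"` attribute.
#'
#' @param n_rows Number of animal rows.
#' @param n_cols Number of plant columns.
#' @param C Connectance in `[0, 1]`.
#' @param seed Optional seed.
#' @param ensure_animal_degree Redraw all-zero animal rows?
#' @param exact_fill If `TRUE`, instead place exactly
#'   `round(C * n_rows * n_cols)` links uniformly at random (variance-free
#'   fill; `ensure_animal_degree` is then ignored).
#' @return Binary matrix (`n_rows` x `n_cols`).
#' @examples
#' build_incidence(5, 5, C = 0.3, seed = 1)
#' @export
build_incidence <- function(n_rows, n_cols, C, seed = NULL,
                            ensure_animal_degree = FALSE, exact_fill = FALSE) {
  check_number(C, "C", lower = 0, upper = 1)
  with_seed(seed, {
    if (exact_fill) {
      n_links <- round(C * n_rows * n_cols)
      A <- matrix(0L, n_rows, n_cols)
      A[sample.int(n_rows * n_cols, n_links)] <- 1L
      attr(A, "redraws") <- 0L
      return(A)
    }
    A <- matrix(rbinom(n_rows * n_cols, 1L, C), n_rows, n_cols)
    redraws <- 0L
    if (ensure_animal_degree && C > 0) {
      empty <- which(rowSums(A) == 0L)
      while (length(empty) > 0L) {
        redraws <- redraws + length(empty)
        A[empty, ] <- matrix(rbinom(length(empty) * n_cols, 1L, C),
                             length(empty), n_cols)
        empty <- which(rowSums(A) == 0L)
      }
    }
    attr(A, "redraws") <- redraws
    A
  })
}

#' Assemble all interaction matrices of a 3-guild community
#'
#' From niche positions, the interaction-strength scalars and the two binary
#' incidence matrices, builds: within-guild competition matrices
#' (`beta = omega_c * alpha` off-diagonal, exactly 1 on the diagonal), the
#' quantitative mutualistic strengths `gamma[i, j] = omega_m * alpha_ij` for
#' every realized pollinator-plant link, and the antagonistic strengths
#' `tau[i, j] = omega_p * alpha_ij` for every realized herbivore-plant link.
#'
#' Orientation convention: incidence matrices are animal-rows x plant-columns
#' (`Theta_MP`: pollinators x plants, `Theta_HP`: herbivores x plants);
#' strength matrices `gamma` (plants x pollinators) and `tau` (plants x
#' herbivores) are plant-rows, mirroring the plant dynamics. The same `gamma`
#' and `tau` values serve both directions of an interaction because the
#' overlap coefficient is symmetric.
#'
#' @param community A [niche_community()].
#' @param params A [model_params()].
#' @param Theta_MP Binary pollinator x plant incidence (`S_M` x `S_P`).
#' @param Theta_HP Binary herbivore x plant incidence (`S_H` x `S_P`).
#' @return An object of class `interaction_matrices`.
#' @export
assemble_matrices <- function(community, params, Theta_MP, Theta_HP) {
  stopifnot(inherits(community, "niche_community"),
            inherits(params, "model_params"))
  if (!all(dim(Theta_MP) == c(community$S_M, community$S_P)))
    stopf("Theta_MP must be %d x %d", community$S_M, community$S_P)
  if (!all(dim(Theta_HP) == c(community$S_H, community$S_P)))
    stopf("Theta_HP must be %d x %d", community$S_H, community$S_P)
  sg <- community$sigma
  a_PP <- alpha_matrix(community$pos_P, community$pos_P, sg)
  a_MM <- alpha_matrix(community$pos_M, community$pos_M, sg)
  a_HH <- alpha_matrix(community$pos_H, community$pos_H, sg)
  a_PM <- alpha_matrix(community$pos_P, community$pos_M, sg)
  a_PH <- alpha_matrix(community$pos_P, community$pos_H, sg)
  comp <- function(alpha, omega) {
    b <- omega * alpha
    diag(b) <- 1
    b
  }
  mats <- structure(list(
    Theta_MP = unname(Theta_MP 	* 1L), Theta_HP = unname(Theta_HP * 1L),
    alpha_PP = a_PP, alpha_MM = a_MM, alpha_HH = a_HH,
    alpha_PM = a_PM, alpha_PH = a_PH,
    beta_P = comp(a_PP, params$omega_c),
    beta_M = comp(a_MM, params$omega_c),
    beta_H = comp(a_HH, params$omega_c),
    gamma = params$omega_m * t(Theta_MP) * a_PM,
    tau   = params$omega_p * t(Theta_HP) * a_PH,
    community = community, params = params), class = "interaction_matrices")
  mats
}

#' @export
print.interaction_matrices <- function(x, ...) {
  lk <- link_counts(x)
  cat(sprintf("<interaction_matrices> %d/%d/%d species; %d mutualistic, %d antagonistic links\n",
              x$community$S_P, x$community$S_M, x$community$S_H,
              lk[["mutualistic"]], lk[["antagonistic"]]))
  invisible(x)
}

#' Realized link counts of the two sub-networks
#'
#' @param mats An `interaction_matrices` object.
#' @return Named integer vector with elements `mutualistic` and
#'   `antagonistic`.
#' @export
link_counts <- function(mats) {
  c(mutualistic = sum(mats$Theta_MP), antagonistic = sum(mats$Theta_HP))
}

#' Generate a full random 3-guild network
#'
#' Convenience wrapper: samples niche positions, draws both incidence matrices
#' at the connectances in `params` (redrawing all-zero animal rows so every
#' animal can rewire), and assembles all strength matrices. Child seeds are
#' derived from `seed` in the order: community positions, mutualistic
#' incidence, antagonistic incidence.
#'
#' @param S_P,S_M,S_H Guild sizes.
#' @param params A [model_params()].
#' @param seed Optional root seed.
#' @param ensure_animal_degree Redraw all-zero animal rows (default `TRUE`).
#' @return An `interaction_matrices` object.
#' @examples
#' net <- generate_network(10, 10, 10, model_params(), seed = 1)
#' link_counts(net)
#' @export
generate_network <- function(S_P, S_M, S_H, params = model_params(),
                             seed = NULL, ensure_animal_degree = TRUE) {
  seeds <- child_seeds(seed, 3L)
  community <- niche_community(S_P, S_M, S_H, sigma = params$sigma,
                               seed = seeds[[1]])
  Theta_MP <- build_incidence(S_M, S_P, params$C_mut, seed = seeds[[2]],
                              ensure_animal_degree = ensure_animal_degree)
  Theta_HP <- build_incidence(S_H, S_P, params$C_ant, seed = seeds[[3]],
                              ensure_animal_degree = ensure_animal_degree)
  assemble_matrices(community, params, Theta_MP, Theta_HP)
}
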