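#' Read and write incidence matrices
#'
#' Two plain-text formats are supported: a dense 0/1 CSV whose header row
#' carries the plant labels (rows are animals), and a 3-column edge list with
#' columns `animal_id`, `plant_id`, `guild`.
#'
#' @param A Binary incidence matrix (animals x plants).
#' @param path File path.
#' @param guild Guild label stored in the edge-list `guild` column
#'   (`"pollinator"` or `"herbivore"`).
#' @param n_rows,n_cols Dimensions for reconstructing a matrix from an edge
#'   list; defaults to the largest index present.
#' @return The matrix (readers) or `path`, invisibly (writers).
#' @export
write_incidence_csv <- function(A, path) {
  df <- as.data.frame(A)
  names(df) <- paste0("plant_", seq_len(ncol(A)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_incidence_csv
#' @export
read_incidence_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  A <- as.matrix(df)
  if (!all(A %in% c(0, 1))) stopf("incidence CSV must contain only 0/1 values")
  dimnames(A) <- NULL
  storage.mode(A) <- "integer"
  A
}

#' @rdname write_incidence_csv
#' @export
write_edge_list <- function(A, path, guild = "pollinator") {
  idx <- which(A == 1, arr.ind = TRUE)
  df <- data.frame(animal_id = idx[, 1], plant_id = idx[, 2], guild = guild)
  write.csv(df[order(df$animal_id, df$plant_id), ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_incidence_csv
#' @export
read_edge_list <- function(path, n_rows = NULL, n_cols = NULL) {
  df <- read.csv(path)
  need <- c("animal_id", "plant_id")
  if (!all(need %in% names(df)))
    stopf("edge list must have columns animal_id, plant_id (and optionally guild)")
  if (is.null(n_rows)) n_rows <- max(df$animal_id)
  if (is.null(n_cols)) n_cols <- max(df$plant_id)
  A <- matrix(0L, n_rows, n_cols)
  A[cbind(df$animal_id, df$plant_id)] <- 1L
  A
}

#' Export a community's species table
#'
#' One row per species with columns `guild`, `species_index`,
#' `niche_position`.
#'
#' @param community A [niche_community()].
#' @param path Optional CSV path; when `NULL` the tibble is returned only.
#' @return A tibble (invisibly when written to file).
#' @export
community_table <- function(community, path = NULL) {
  stopifnot(inherits(community, "niche_community"))
  tb <- tibble::tibble(
    guild = rep(c("plant", "pollinator", "herbivore"),
                c(community$S_P, community$S_M, community$S_H)),
    species_index = c(seq_len(community$S_P), seq_len(community$S_M),
                      seq_len(community$S_H)),
    niche_position = c(community$pos_P, community$pos_M, community$pos_H))
  if (!is.null(path)) {
    write.csv(tb, path, row.names = FALSE)
    return(invisible(tb))
  }
  tb
}
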