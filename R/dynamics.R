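# Temporal stability analyses on hourly rating trajectories.

#' Per-hour dominance ranks from hourly rating trajectories
#'
#' Ranks animals within each rating period by descending rating (rank 1 =
#' highest). Ties are broken by the higher previous-period rating (the
#' initial rating before period 1), then by animal id, so ranks are always
#' a full permutation.
#'
#' @param x a `glicko_result`, or an animals-by-periods rating matrix with
#'   row names.
#' @param initial_rating rating before the first period; taken from
#'   `x$params` when `x` is a `glicko_result`.
#' @return Integer matrix of ranks, rows = animals, columns = periods.
#' @export
hourly_ranks <- function(x, initial_rating = NULL) {
  if (inherits(x, "glicko_result")) {
    if (is.null(initial_rating)) initial_rating <- x$params$initial_rating
    x <- rating_matrix(x)
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (is.null(initial_rating)) initial_rating <- x[1, 1]
  prev <- rep(as.numeric(initial_rating), nrow(x))
  R <- matrix(NA_integer_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (h in seq_len(ncol(x))) {
    o <- order(-x[, h], -prev, rownames(x))
    R[o, h] <- seq_len(nrow(x))
    prev <- x[, h]
  }
  R
}

#' Time to social stability per animal
#'
#' Rank-fixation definition: the smallest hour h such that the animal's
#' rank is identical at every hour from h to the last; 1 if the rank never
#' changes, and the final hour if the last change happens there.
#'
#' @param rank_table rank matrix from [hourly_ranks()].
#' @return data.frame with `animal_id` and `stability_h`.
#' @export
stability_time <- function(rank_table) {
  H <- ncol(rank_table)
  final <- rank_table[, H]
  st <- apply(rank_table != final, 1, function(ch)
    if (any(ch)) max(which(ch)) + 1L else 1L)
  data.frame(animal_id = rownames(rank_table),
             stability_h = as.integer(st),
             stringsAsFactors = FALSE)
}

#' Time to rating plateau per animal
#'
#' Alternative stability definition for sensitivity analysis: the smallest
#' hour h such that every subsequent hour-to-hour rating change is below
#' `eps` rating points in magnitude.
#'
#' @param rating_mat animals-by-periods rating matrix (see
#'   [rating_matrix()]).
#' @param eps plateau threshold in rating points (default 10).
#' @return data.frame with `animal_id` and `stability_h`.
#' @export
rating_plateau_time <- function(rating_mat, eps = 10) {
  st <- apply(rating_mat, 1, function(r) {
    big <- which(abs(diff(r)) >= eps) + 1L  # hour at which the jump lands
    if (length(big)) max(big) else 1L
  })
  data.frame(animal_id = rownames(rating_mat),
             stability_h = as.integer(st),
             stringsAsFactors = FALSE)
}

#' Hour from which the eventual top animal holds rank 1 continuously
#'
#' @param rank_table rank matrix from [hourly_ranks()].
#' @return Integer hour; 1 when the final leader leads in every period.
#' @export
first_rank_emergence <- function(rank_table) {
  H <- ncol(rank_table)
  top <- rownames(rank_table)[rank_table[, H] == 1L]
  holder <- rownames(rank_table)[apply(rank_table == 1L, 2, which)]
  changed <- which(holder != top)
  if (length(changed)) max(changed) + 1L else 1L
}

#' Spearman correlation of each hour's ratings with the final hour
#'
#' For a set of individuals, correlates the hour-h ratings with the
#' final-hour ratings, hour by hour; used to ask how early the eventual
#' hierarchy is predictable.
#'
#' @param rating_mat individuals-by-periods rating matrix with at least 3
#'   rows.
#' @return data.frame with `hour`, `rho`, `p_value`, `significant`
#'   (p < 0.05). A constant rating vector in either variable yields `NA`
#'   for that hour.
#' @export
hourly_final_correlation <- function(rating_mat) {
  if (nrow(rating_mat) < 3)
    stop("need at least 3 individuals for rank correlation")
  H <- ncol(rating_mat)
  final <- rating_mat[, H]
  res <- lapply(seq_len(H), function(h) {
    v <- rating_mat[, h]
    if (stats::sd(v) == 0 || stats::sd(final) == 0)
      return(data.frame(hour = h, rho = NA_real_, p_value = NA_real_,
                        significant = NA))
    ct <- suppressWarnings(
      stats::cor.test(v, final, method = "spearman", exact = FALSE))
    data.frame(hour = h, rho = unname(ct$estimate),
               p_value = ct$p.value,
               significant = ct$p.value < 0.05)
  })
  do.call(rbind, res)
}

#' Per-pen-leader rating trajectories pooled by sex
#'
#' Extracts, for each pen, the hourly rating trajectory of the animal
#' ranked first at the final hour, pools the leaders of each sex, and runs
#' [hourly_final_correlation()] per sex.
#'
#' @param glicko_results named list of `glicko_result` objects, one per
#'   pen.
#' @param animals animal metadata table.
#' @return list with one data.frame per sex (element missing when a sex
#'   has fewer than 3 pens).
#' @export
leader_final_correlation <- function(glicko_results, animals) {
  sex_of <- stats::setNames(animals$sex, animals$animal_id)
  rows <- lapply(glicko_results, function(g) {
    M <- rating_matrix(g)
    R <- hourly_ranks(g)
    leader <- rownames(R)[R[, ncol(R)] == 1L]
    list(sex = unname(sex_of[leader]), traj = M[leader, , drop = FALSE])
  })
  out <- list()
  for (s in unique(vapply(rows, `[[`, "", "sex"))) {
    mats <- lapply(rows[vapply(rows, `[[`, "", "sex") == s], `[[`, "traj")
    M <- do.call(rbind, mats)
    if (nrow(M) >= 3) out[[s]] <- hourly_final_correlation(M)
  }
  out
}
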