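# Sequential Elo ratings from the temporal sequence of decided
# interactions.

#' Elo rating parameters
#'
#' @param k points at stake per encounter (default 100).
#' @param initial_rating rating every animal starts with (default 1000).
#' @param model expected-score function of the rating difference:
#'   `"normal_cdf"` (p = Phi(diff/200), the convention of Elo applications
#'   to animal contest data) or `"logistic"`
#'   (p = 1/(1 + 10^(-diff/400)), the chess convention).
#' @return list of class `elo_params`.
#' @export
elo_params <- function(k = 100, initial_rating = 1000,
                       model = c("normal_cdf", "logistic")) {
  stopifnot(k > 0)
  structure(list(k = k, initial_rating = initial_rating,
                 model = match.arg(model)),
            class = "elo_params")
}

#' Expected score of the higher-rated individual
#'
#' @param r_high,r_low ratings of the higher- and lower-rated individual
#'   (`r_high >= r_low`).
#' @param model `"normal_cdf"` or `"logistic"` (see [elo_params()]).
#' @return Winning probability in `[0.5, 1]`; 0.5 at equal ratings,
#'   strictly increasing in the rating difference.
#' @export
elo_expected_score <- function(r_high, r_low,
                               model = c("normal_cdf", "logistic")) {
  stopifnot(all(r_high >= r_low))
  d <- r_high - r_low
  switch(match.arg(model),
         normal_cdf = stats::pnorm(d / 200),
         logistic   = 1 / (1 + 10 ^ (-d / 400)))
}

#' Single Elo update after a decided interaction
#'
#' If the winner was the higher-rated (or ratings were equal), it gains
#' `(1 - p) * k`; if the winner was lower-rated — an upset — it gains
#' `p * k`. The loser loses the same amount, so pen rating totals are
#' conserved. `p` is the expected score of the higher-rated of the pair.
#'
#' @param r_winner,r_loser pre-interaction ratings.
#' @param params an [elo_params()] object.
#' @return Numeric vector `c(winner = ..., loser = ...)` of new ratings.
#' @export
elo_update <- function(r_winner, r_loser, params = elo_params()) {
  if (r_winner >= r_loser) {
    p <- elo_expected_score(r_winner, r_loser, params$model)
    delta <- (1 - p) * params$k
  } else {
    p <- elo_expected_score(r_loser, r_winner, params$model)
    delta <- p * params$k
  }
  c(winner = r_winner + delta, loser = r_loser - delta)
}

#' Elo rating trajectories for one pen
#'
#' Replays the pen's decided interactions in time order, updating the two
#' participants after each one. Draws are skipped. All animals start at
#' `params$initial_rating`.
#'
#' @param interactions filtered/merged interaction table, sorted by time.
#' @param animals animal metadata table.
#' @param pen_id pen to rate.
#' @param params an [elo_params()] object.
#' @return Object of class `elo_result`: list with `pen_id`, `params`,
#'   `final` (named rating vector) and `trajectory`, a long data.frame
#'   (`animal_id`, `t_s`, `rating`) starting with a t = 0 sample at the
#'   initial rating for every animal.
#' @export
elo_sequence <- function(interactions, animals, pen_id,
                         params = elo_params()) {
  ids <- pen_members(animals, pen_id)
  r <- stats::setNames(rep(params$initial_rating, length(ids)), ids)
  x <- interactions[interactions$pen_id == pen_id &
                      interactions$outcome != "draw", , drop = FALSE]
  n_ev <- nrow(x)
  traj_id <- character(2L * n_ev)
  traj_t <- numeric(2L * n_ev)
  traj_r <- numeric(2L * n_ev)
  for (k in seq_len(n_ev)) {
    w <- if (x$outcome[k] == "actor_wins") x$actor_id[k] else x$receiver_id[k]
    l <- if (x$outcome[k] == "actor_wins") x$receiver_id[k] else x$actor_id[k]
    upd <- elo_update(r[[w]], r[[l]], params)
    r[[w]] <- upd[["winner"]]
    r[[l]] <- upd[["loser"]]
    i <- 2L * k - 1L
    traj_id[i:(i + 1L)] <- c(w, l)
    traj_t[i:(i + 1L)] <- x$t_start_s[k]
    traj_r[i:(i + 1L)] <- c(r[[w]], r[[l]])
  }
  trajectory <- rbind(
    data.frame(animal_id = ids, t_s = 0, rating = params$initial_rating,
               stringsAsFactors = FALSE),
    data.frame(animal_id = traj_id, t_s = traj_t, rating = traj_r,
               stringsAsFactors = FALSE))
  structure(list(pen_id = pen_id, params = params, final = r,
                 trajectory = trajectory),
            class = "elo_result")
}

#' @export
print.elo_result <- function(x, ...) {
  cat(sprintf("<elo_result> pen %s (k = %g, init = %g, %s)\n",
              x$pen_id, x$params$k, x$params$initial_rating,
              x$params$model))
  print(round(sort(x$final, decreasing = TRUE), 1))
  invisible(x)
}
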