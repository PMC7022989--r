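# Glicko-1 ratings with rating deviations, updated in fixed rating
# periods (hourly by default), yielding per-hour trajectories.

#' Glicko rating parameters
#'
#' @param initial_rating rating every animal starts with (default 2200).
#' @param initial_rd initial rating deviation (default 300).
#' @param rd_floor lower bound on the rating deviation (default 30);
#'   prevents degenerate certainty after many games.
#' @param c per-period RD inflation for inactive periods (default 0: a
#'   continuous 72 h observation window has no meaningful inactivity decay,
#'   and c = 0 keeps RD monotone non-increasing).
#' @param period_s rating-period length in seconds (default 3600, one
#'   hour).
#' @param draws how tied outcomes enter: `"exclude"` (default, consistent
#'   with the Elo module's decided-only convention) or `"half"` (score
#'   0.5).
#' @return list of class `glicko_params`; also carries the Glicko constant
#'   `q = ln(10)/400`.
#' @export
glicko_params <- function(initial_rating = 2200, initial_rd = 300,
                          rd_floor = 30, c = 0, period_s = 3600,
                          draws = c("exclude", "half")) {
  stopifnot(initial_rd > 0, period_s > 0, rd_floor > 0, c >= 0)
  structure(list(initial_rating = initial_rating, initial_rd = initial_rd,
                 rd_floor = rd_floor, c = c, period_s = period_s,
                 draws = match.arg(draws), q = log(10) / 400),
            class = "glicko_params")
}

#' One Glicko-1 rating-period update
#'
#' Applies the standard Glicko-1 equations to all individuals at once,
#' using every opponent's pre-period rating and deviation: with
#' `g(RD) = 1/sqrt(1 + 3 q^2 RD^2 / pi^2)` and
#' `E = 1/(1 + 10^(-g(RD_j)(r - r_j)/400))`,
#' `d^2 = 1 / (q^2 sum g(RD_j)^2 E (1 - E))`,
#' `r' = r + q / (1/RD^2 + 1/d^2) * sum g(RD_j) (s_j - E)` and
#' `RD' = sqrt(1 / (1/RD^2 + 1/d^2))`, floored at `rd_floor`. Individuals
#' with no games keep their rating; their RD inflates to
#' `sqrt(RD^2 + c^2)`, capped at `initial_rd`.
#'
#' @param states data.frame with columns `animal_id`, `rating`, `rd`.
#' @param period_results data.frame with columns `a`, `b`, `score_a`
#'   (1 = a won, 0 = b won, 0.5 = draw); one row per game in the period.
#' @param params a [glicko_params()] object.
#' @return `states` with updated `rating` and `rd`.
#' @export
glicko_period_update <- function(states, period_results,
                                 params = glicko_params()) {
  stopifnot(all(c("animal_id", "rating", "rd") %in% names(states)))
  q <- params$q
  if (nrow(period_results)) {
    unknown <- setdiff(c(period_results$a, period_results$b),
                       states$animal_id)
    if (length(unknown))
      stop("period results reference unknown id(s): ",
           paste(unique(unknown), collapse = ", "))
  }
  r0 <- stats::setNames(states$rating, states$animal_id)
  rd0 <- stats::setNames(states$rd, states$animal_id)
  g <- function(rd) 1 / sqrt(1 + 3 * q^2 * rd^2 / pi^2)
  new_r <- r0
  new_rd <- rd0
  for (id in states$animal_id) {
    as_a <- period_results$a == id
    as_b <- period_results$b == id
    opp <- c(period_results$b[as_a], period_results$a[as_b])
    s <- c(period_results$score_a[as_a], 1 - period_results$score_a[as_b])
    if (!length(opp)) {
      new_rd[id] <- min(sqrt(rd0[id]^2 + params$c^2), params$initial_rd)
      next
    }
    gj <- g(rd0[opp])
    E <- 1 / (1 + 10 ^ (-gj * (r0[id] - r0[opp]) / 400))
    d2 <- 1 / (q^2 * sum(gj^2 * E * (1 - E)))
    denom <- 1 / rd0[id]^2 + 1 / d2
    new_r[id] <- r0[id] + q / denom * sum(gj * (s - E))
    new_rd[id] <- max(sqrt(1 / denom), params$rd_floor)
  }
  states$rating <- unname(new_r[states$animal_id])
  states$rd <- unname(new_rd[states$animal_id])
  states
}

#' Hourly Glicko rating trajectories for one pen
#'
#' Buckets the pen's interactions into fixed rating periods (hours by
#' default) and applies one [glicko_period_update()] per period. Hours with
#' no games leave ratings unchanged (with `c = 0`). The history holds one
#' entry per animal per period, which is the data behind per-pen rating
#' trajectory plots.
#'
#' @param interactions filtered/merged interaction table, sorted by time.
#' @param animals animal metadata table.
#' @param pen_id pen to rate.
#' @param params a [glicko_params()] object.
#' @param hours observation window length in hours (default 72).
#' @return Object of class `glicko_result`: list with `pen_id`, `params`,
#'   `history` (long data.frame `animal_id`, `period`, `rating`, `rd`,
#'   periods 1..hours), `final` and `final_rd` (named vectors at the last
#'   period).
#' @export
glicko_hourly <- function(interactions, animals, pen_id,
                          params = glicko_params(), hours = 72) {
  ids <- pen_members(animals, pen_id)
  n_periods <- as.integer(ceiling(hours))
  states <- data.frame(animal_id = ids, rating = params$initial_rating,
                       rd = params$initial_rd, stringsAsFactors = FALSE)
  x <- interactions[interactions$pen_id == pen_id, , drop = FALSE]
  if (params$draws == "exclude")
    x <- x[x$outcome != "draw", , drop = FALSE]
  score_a <- ifelse(x$outcome == "actor_wins", 1,
                    ifelse(x$outcome == "receiver_wins", 0, 0.5))
  period <- pmin(floor(x$t_start_s / params$period_s) + 1L, n_periods)
  hist_list <- vector("list", n_periods)
  for (p in seq_len(n_periods)) {
    in_p <- which(period == p)
    results <- data.frame(a = x$actor_id[in_p], b = x$receiver_id[in_p],
                          score_a = score_a[in_p],
                          stringsAsFactors = FALSE)
    states <- glicko_period_update(states, results, params)
    hist_list[[p]] <- data.frame(animal_id = states$animal_id, period = p,
                                 rating = states$rating, rd = states$rd,
                                 stringsAsFactors = FALSE)
  }
  history <- do.call(rbind, hist_list)
  structure(list(pen_id = pen_id, params = params, history = history,
                 final = stats::setNames(states$rating, states$animal_id),
                 final_rd = stats::setNames(states$rd, states$animal_id)),
            class = "glicko_result")
}

#' @export
print.glicko_result <- function(x, ...) {
  cat(sprintf("<glicko_result> pen %s, %d periods\n", x$pen_id,
              max(x$history$period)))
  print(round(sort(x$final, decreasing = TRUE), 1))
  invisible(x)
}

#' Rating trajectories as an animals-by-periods matrix
#'
#' @param x a `glicko_result`.
#' @param what `"rating"` or `"rd"`.
#' @return Numeric matrix, rows = animals (sorted ids), columns = periods.
#' @export
rating_matrix <- function(x, what = c("rating", "rd")) {
  what <- match.arg(what)
  stopifnot(inherits(x, "glicko_result"))
  h <- x$history
  ids <- sort(unique(h$animal_id))
  periods <- sort(unique(h$period))
  M <- matrix(NA_real_, length(ids), length(periods),
              dimnames = list(ids, periods))
  M[cbind(match(h$animal_id, ids), match(h$period, periods))] <- h[[what]]
  M
}
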