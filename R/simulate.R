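# Synthetic-herd generator: a latent-ability logistic win model over a
# time-inhomogeneous contact process, emulating 72 h of post-mixing
# agonistic interactions in single-sex pens.

#' Configuration for the synthetic herd
#'
#' Defaults emulate the design the pipeline targets: 10 single-sex pens of
#' 10-11 weaned pigs (5 female pens, 5 barrow pens; 102 animals) observed
#' for 72 h after mixing. Each animal carries a latent dominance value
#' `d ~ N(0, 1)`; conditional on a decided event between i and j,
#' `P(i wins) = plogis(steepness * (d_i - d_j))`, so `steepness` sets how
#' detectable the hierarchy is (0 = coin-flip outcomes) while the latent
#' scale stays fixed. Per-pair event rates decay
#' exponentially with half-life `h_decay` (most fighting right after
#' mixing); female pens' half-life is shortened and barrow pens' lengthened
#' by `sex_effect_h / 2` each, so female hierarchies settle earlier and the
#' sex contrast has a recoverable direction of truth.
#'
#' @param n_pens number of pens.
#' @param pen_sizes integer vector of pen sizes (10 or 11), length
#'   `n_pens`.
#' @param pen_sex `"female"`/`"barrow"` per pen.
#' @param hours observation window (default 72).
#' @param steepness multiplier on latent differences in the win model;
#'   0 = no hierarchy.
#' @param rate_per_pair_per_h initial event rate per dyad per hour.
#' @param h_decay event-rate half-life in hours.
#' @param sex_effect_h difference in half-life between barrow and female
#'   pens, in hours.
#' @param draw_prob probability a non-standoff event ends undecided.
#' @param behavior_mix named probabilities over the behavior classes.
#' @param dur_meanlog,dur_sdlog lognormal event-duration parameters
#'   (seconds).
#' @param seed integer seed; the whole simulation is deterministic given
#'   it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pens = 10,
                       pen_sizes = c(10, 10, 10, 10, 10, 10, 10, 10, 11, 11),
                       pen_sex = rep(c("female", "barrow"), each = 5),
                       hours = 72,
                       steepness = 1.5,
                       rate_per_pair_per_h = 0.4,
                       h_decay = 24,
                       sex_effect_h = 15,
                       draw_prob = 0.15,
                       behavior_mix = c(active_attack = 0.6,
                                        being_bullied = 0.25,
                                        standoff = 0.15),
                       dur_meanlog = log(10), dur_sdlog = 0.6,
                       seed = 1L) {
  stopifnot(length(pen_sizes) == n_pens, length(pen_sex) == n_pens,
            all(pen_sex %in% SEXES), hours > 0,
            steepness >= 0, rate_per_pair_per_h >= 0, h_decay > 0,
            draw_prob >= 0, draw_prob <= 1,
            setequal(names(behavior_mix), BEHAVIORS),
            abs(sum(behavior_mix) - 1) < 1e-8, all(behavior_mix >= 0))
  structure(as.list(environment()), class = "sim_config")
}

# inverse-CDF draw of event times (hours) under rate ~ 2^(-t / hl)
sample_decay_times <- function(n, hl, hours) {
  tail_mass <- 2 ^ (-hours / hl)
  u <- stats::runif(n)
  -hl * log2(1 - u * (1 - tail_mass))
}

#' Simulate a synthetic herd
#'
#' Draws animal metadata and a 72 h agonistic interaction log under the
#' model described in [sim_config()]. The output passes all dataset
#' validation, and the latent dominance values are returned as `truth` for
#' rank-recovery studies.
#'
#' @param config a [sim_config()].
#' @return An [agon_dataset()] whose `truth` element is a data.frame
#'   (`animal_id`, `pen_id`, `latent`).
#' @export
simulate_herd <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(config$seed), {
    animals_list <- list()
    events_list <- list()
    for (p in seq_len(config$n_pens)) {
      pen <- LETTERS[p]
      n <- config$pen_sizes[p]
      sexp <- config$pen_sex[p]
      ids <- sprintf("%s%02d", pen, seq_len(n))
      latent <- stats::rnorm(n)
      names(latent) <- ids
      hl <- config$h_decay +
        ifelse(sexp == "female", -1, 1) * config$sex_effect_h / 2
      hl <- max(hl, 1)
      initial_bw <- round(stats::rnorm(n, 10, 1.2), 2)
      adg <- stats::rnorm(n, 0.25, 0.08)
      animals_list[[p]] <- data.frame(
        animal_id = ids, pen_id = pen, sex = sexp,
        litter_id = sprintf("L%02d", sample.int(37, n, replace = TRUE)),
        parity = sample.int(4, n, replace = TRUE),
        sire_id = sprintf("S%d", sample.int(8, n, replace = TRUE)),
        initial_bw_kg = initial_bw,
        final_bw_kg = round(initial_bw + 3 * adg, 2),
        backtest_1 = stats::rpois(n, 3),
        backtest_2 = stats::rpois(n, 3),
        stringsAsFactors = FALSE)
      animals_list[[p]]$latent <- unname(latent)

      if (config$rate_per_pair_per_h == 0) next
      pair_idx <- utils::combn(n, 2)
      # expected events per dyad over the whole window
      lambda <- config$rate_per_pair_per_h * hl / log(2) *
        (1 - 2 ^ (-config$hours / hl))
      for (k in seq_len(ncol(pair_idx))) {
        i <- ids[pair_idx[1, k]]
        j <- ids[pair_idx[2, k]]
        m <- stats::rpois(1, lambda)
        if (m == 0) next
        t_h <- sort(sample_decay_times(m, hl, config$hours))
        t_s <- t_h * 3600
        dur <- stats::rlnorm(m, config$dur_meanlog, config$dur_sdlog)
        dur <- pmin(dur, config$hours * 3600 - t_s)
        behavior <- sample(names(config$behavior_mix), m, replace = TRUE,
                           prob = config$behavior_mix)
        i_wins <- stats::runif(m) <
          stats::plogis(config$steepness * (latent[i] - latent[j]))
        undecided <- behavior == "standoff" |
          stats::runif(m) < config$draw_prob
        actor <- ifelse(undecided,
                        ifelse(stats::runif(m) < 0.5, i, j),
                        ifelse(i_wins, i, j))
        events_list[[length(events_list) + 1L]] <- data.frame(
          pen_id = pen, t_start_s = t_s, duration_s = dur,
          actor_id = actor,
          receiver_id = ifelse(actor == i, j, i),
          behavior = behavior,
          outcome = ifelse(undecided, "draw", "actor_wins"),
          stringsAsFactors = FALSE)
      }
    }
    animals <- do.call(rbind, animals_list)
    truth <- animals[c("animal_id", "pen_id", "latent")]
    animals$latent <- NULL
    interactions <- if (length(events_list)) do.call(rbind, events_list)
      else data.frame(pen_id = character(), t_start_s = numeric(),
                      duration_s = numeric(), actor_id = character(),
                      receiver_id = character(), behavior = character(),
                      outcome = character(), stringsAsFactors = FALSE)
    agon_dataset(animals, interactions, truth = truth)
  })
}

#' Rank-recovery experiment on simulated herds
#'
#' For each seed: simulate a herd, run the event filter and the three
#' hierarchy indices per pen, and correlate (Spearman) the latent
#' dominance values with I&SI rank, final Elo and final Glicko ratings.
#' All three indices are only identified within a pen (I&SI ranks are
#' 1..n per pen, Elo/Glicko totals are conserved per pen), so both the
#' latent values and the indices are converted to within-pen ranks before
#' the animals are pooled over pens; otherwise between-pen differences in
#' latent level would attenuate the correlation for reasons unrelated to
#' index quality.
#'
#' @param config a [sim_config()]; its `seed` is replaced by each element
#'   of `seeds`.
#' @param seeds integer vector of simulation seeds.
#' @param n_restarts I&SI restarts per pen (default 5; pens are small).
#' @return list with `per_seed` (data.frame `seed`, `rho_isi`, `rho_elo`,
#'   `rho_glicko`, signed) and `mean_abs_rho` (named vector of mean
#'   absolute correlations).
#' @export
recovery_experiment <- function(config = sim_config(), seeds = 1:10,
                                n_restarts = 5) {
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    ds <- simulate_herd(cfg)
    ev <- filter_and_merge_fights(ds$interactions)
    idx <- pipeline_indices(ev, ds$animals, seed = s,
                            n_restarts = n_restarts)
    m <- merge(idx, ds$truth, by = c("animal_id", "pen_id"))
    wr <- function(v) stats::ave(v, m$pen_id, FUN = rank)  # within-pen rank
    latent_r <- wr(-m$latent)  # rank 1 = highest latent dominance
    rho <- function(v) suppressWarnings(
      stats::cor(latent_r, v, method = "spearman"))
    data.frame(seed = s, rho_isi = rho(m$isi_rank),
               rho_elo = rho(wr(-m$elo)),
               rho_glicko = rho(wr(-m$glicko)))
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       mean_abs_rho = c(isi = mean(abs(per_seed$rho_isi)),
                        elo = mean(abs(per_seed$rho_elo)),
                        glicko = mean(abs(per_seed$rho_glicko))))
}

# per-pen indices pooled into one table (helper shared with run_pipeline)
pipeline_indices <- function(events, animals, seed = 1,
                             n_restarts = 20,
                             elo_par = elo_params(),
                             glicko_par = glicko_params(),
                             hours = 72) {
  pens <- unique(animals$pen_id)
  rows <- lapply(pens, function(pen) {
    B <- binarize(build_sociomatrix(events, animals, pen))
    rk <- isi_rank(B, seed = seed, n_restarts = n_restarts)
    elo <- elo_sequence(events, animals, pen, elo_par)
    gl <- glicko_hourly(events, animals, pen, glicko_par, hours = hours)
    ids <- sort(names(elo$final))
    data.frame(animal_id = ids, pen_id = pen,
               isi_rank = unname(rk$ranks[ids]),
               elo = unname(elo$final[ids]),
               glicko = unname(gl$final[ids]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
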