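# End-to-end orchestration: events -> sociomatrices -> I&SI -> Elo ->
# Glicko -> stability dynamics -> statistical panel, with all outputs
# written beside a manifest and the resolved configuration.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full hierarchy pipeline and write a result bundle
#'
#' Runs event filtering/merging, dyadic summaries, per-pen sociomatrices
#' and binarization, I&SI ranking, Elo and hourly Glicko ratings,
#' stability dynamics, and the statistical panel; every stage's outputs
#' are written under `outdir` and listed, with MD5 hashes, in
#' `manifest.json`. Reruns with the same dataset, seed and parameters
#' produce byte-identical bundles.
#'
#' @param dataset an [agon_dataset()], e.g. from [read_interactions()] or
#'   [simulate_herd()].
#' @param outdir output directory (created if needed).
#' @param seed integer seed for the I&SI restarts.
#' @param min_dur_s,merge_gap_s fight filter parameters (see
#'   [filter_and_merge_fights()]).
#' @param elo_par an [elo_params()].
#' @param glicko_par a [glicko_params()].
#' @param n_restarts I&SI random restarts per pen.
#' @param hours observation window in hours (default 72).
#' @param plateau_eps rating-plateau threshold (see
#'   [rating_plateau_time()]).
#' @return Invisibly, a list with all intermediate and final results
#'   (`events`, `dyadic`, `indices`, `sociomatrices`, `rank_orders`,
#'   `elo`, `glicko`, `stability`, `dynamics`, `stats`, `manifest`).
#' @export
run_pipeline <- function(dataset, outdir, seed = 1L,
                         min_dur_s = 3, merge_gap_s = 8,
                         elo_par = elo_params(),
                         glicko_par = glicko_params(),
                         n_restarts = 20, hours = 72,
                         plateau_eps = 10) {
  stopifnot(inherits(dataset, "agon_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  animals <- dataset$animals
  pens <- sort(unique(animals$pen_id))
  written <- character()
  emit <- function(path) written <<- c(written, basename(path))

  events <- stage("events", filter_and_merge_fights(
    dataset$interactions, min_dur_s, merge_gap_s))

  dyadic <- stage("dyadic_summary", summarize_dyadic(events, animals))
  f <- file.path(outdir, "dyadic_summary.tsv")
  utils::write.table(dyadic, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emit(f)

  socs <- list(); bins <- list(); ranks <- list()
  elos <- list(); glickos <- list()
  for (pen in pens) {
    socs[[pen]] <- stage("sociomatrix",
                         build_sociomatrix(events, animals, pen))
    bins[[pen]] <- binarize(socs[[pen]])
    emit(write_sociomatrix(socs[[pen]],
         file.path(outdir, paste0("sociomatrix_", pen, ".tsv"))))
    emit(write_sociomatrix(bins[[pen]],
         file.path(outdir, paste0("binary_", pen, ".tsv"))))
    ranks[[pen]] <- stage("isi", isi_rank(bins[[pen]], seed = seed,
                                          n_restarts = n_restarts))
    emit(write_json_file(
      ranks[[pen]][c("pen_id", "order", "I", "SI", "n_restarts_used",
                     "seed", "multiple_optima")],
      file.path(outdir, paste0("isi_", pen, ".json"))))
    elos[[pen]] <- stage("elo", elo_sequence(events, animals, pen,
                                             elo_par))
    f <- file.path(outdir, paste0("elo_", pen, ".tsv"))
    utils::write.table(elos[[pen]]$trajectory, f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(f)
    glickos[[pen]] <- stage("glicko", glicko_hourly(events, animals, pen,
                                                    glicko_par,
                                                    hours = hours))
    f <- file.path(outdir, paste0("glicko_", pen, ".tsv"))
    utils::write.table(glickos[[pen]]$history, f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(f)
  }

  dynamics <- stage("dynamics", {
    stab_rows <- list(); emergence <- list()
    for (pen in pens) {
      R <- hourly_ranks(glickos[[pen]])
      M <- rating_matrix(glickos[[pen]])
      s1 <- stability_time(R)
      s2 <- rating_plateau_time(M, eps = plateau_eps)
      stab_rows[[pen]] <- data.frame(
        animal_id = s1$animal_id, pen_id = pen,
        stability_h = s1$stability_h,
        plateau_h = s2$stability_h[match(s1$animal_id, s2$animal_id)],
        stringsAsFactors = FALSE)
      emergence[[pen]] <- first_rank_emergence(R)
    }
    stab <- do.call(rbind, stab_rows)
    stab <- merge(stab, animals[c("animal_id", "sex", "parity", "sire_id",
                                  "initial_bw_kg")], by = "animal_id")
    stab <- stab[order(stab$animal_id), ]
    rownames(stab) <- NULL
    list(stability = stab,
         emergence = stats::setNames(unlist(emergence), pens),
         leader_correlation = leader_final_correlation(glickos, animals))
  })
  f <- file.path(outdir, "stability.tsv")
  utils::write.table(dynamics$stability, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emit(f)
  emit(write_json_file(
    list(first_rank_emergence_h = as.list(dynamics$emergence),
         leader_correlation = dynamics$leader_correlation),
    file.path(outdir, "dynamics.json")))

  indices <- do.call(rbind, lapply(pens, function(pen) {
    ids <- sort(names(elos[[pen]]$final))
    data.frame(animal_id = ids, pen_id = pen,
               isi_rank = unname(ranks[[pen]]$ranks[ids]),
               elo = unname(elos[[pen]]$final[ids]),
               glicko = unname(glickos[[pen]]$final[ids]),
               stringsAsFactors = FALSE)
  }))

  stats_res <- stage("stats", {
    tab <- merge(indices, dyadic[c("animal_id", "lgDAA", "lgDSO", "lgDBB",
                                   "lgFAA", "lgFSO", "lgFBB")],
                 by = "animal_id")
    tab <- merge(tab, animals[c("animal_id", "backtest_mean",
                                "initial_bw_kg")], by = "animal_id")
    tab$adg <- unname(compute_adg(animals)[tab$animal_id])
    tab <- tab[order(tab$animal_id), ]
    lg <- c("lgDAA", "lgDSO", "lgDBB", "lgFAA", "lgFSO", "lgFBB")
    pc <- list()
    for (idx in c("isi_rank", "elo", "glicko")) {
      # panel A: each behavior indicator, remaining five as covariates
      for (v in lg) {
        r <- partial_correlation(tab[[idx]], tab[[v]],
                                 tab[setdiff(lg, v)])
        pc[[length(pc) + 1L]] <- data.frame(
          index = idx, indicator = v, r = r$r, abs_r = abs(r$r),
          p_value = r$p_value, stringsAsFactors = FALSE)
      }
      # panel B: backtest / body weight / ADG with all six as covariates
      for (v in c("backtest_mean", "initial_bw_kg", "adg")) {
        ok <- stats::complete.cases(tab[c(idx, v, lg)])
        r <- partial_correlation(tab[[idx]][ok], tab[[v]][ok],
                                 tab[lg][ok, ])
        pc[[length(pc) + 1L]] <- data.frame(
          index = idx, indicator = v, r = r$r, abs_r = abs(r$r),
          p_value = r$p_value, stringsAsFactors = FALSE)
      }
    }
    regressions <- lapply(c(isi_rank = "isi_rank", elo = "elo",
                            glicko = "glicko"), function(idx) {
      mr <- multiple_regression(tab, idx)
      mr[c("response", "n", "coefficients")]
    })
    sc <- if (length(unique(dynamics$stability$sex)) > 1)
      sex_contrast(dynamics$stability)[c("means", "p_sex",
                                         "estimate_diff_h", "se_diff_h",
                                         "n")]
    else NULL
    list(index_table = tab,
         index_correlations = index_correlations(indices),
         partial_correlations = do.call(rbind, pc),
         regressions = regressions,
         sex_contrast = sc)
  })
  emit(write_json_file(
    stats_res[c("index_correlations", "partial_correlations",
                "regressions", "sex_contrast")],
    file.path(outdir, "stats_report.json")))

  cfg <- list(seed = seed, min_dur_s = min_dur_s,
              merge_gap_s = merge_gap_s, hours = hours,
              n_restarts = n_restarts, plateau_eps = plateau_eps,
              elo = unclass(elo_par), glicko = unclass(glicko_par))
  emit(write_json_file(cfg, file.path(outdir, "config.json")))

  written <- sort(unique(written))
  manifest <- data.frame(
    file = written,
    md5 = unname(tools::md5sum(file.path(outdir, written))),
    stringsAsFactors = FALSE)
  write_json_file(manifest, file.path(outdir, "manifest.json"))

  invisible(list(events = events, dyadic = dyadic, indices = indices,
                 sociomatrices = socs, binary = bins, rank_orders = ranks,
                 elo = elos, glicko = glickos,
                 stability = dynamics$stability,
                 dynamics = dynamics, stats = stats_res,
                 manifest = manifest))
}
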