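# Statistical panel: index inter-correlations, partial correlations,
# multiple regression, and the sex contrast on stability time.

#' Pairwise Spearman correlations between hierarchy indices
#'
#' Correlates I&SI rank, final Elo rating and final Glicko rating over the
#' pooled animals. Because rank 1 is the most dominant while ratings grow
#' with dominance, rank-vs-rating correlations are negative; the absolute
#' value is reported alongside the signed coefficient.
#'
#' @param index_table data.frame with columns `isi_rank`, `elo`, `glicko`
#'   (one row per animal).
#' @return data.frame with `pair`, `rho`, `abs_rho`, `p_value`, `n`.
#' @export
index_correlations <- function(index_table) {
  stopifnot(all(c("isi_rank", "elo", "glicko") %in% names(index_table)))
  pairs <- list(c("isi_rank", "glicko"), c("elo", "glicko"),
                c("isi_rank", "elo"))
  res <- lapply(pairs, function(p) {
    x <- index_table[[p[1]]]
    y <- index_table[[p[2]]]
    ok <- stats::complete.cases(x, y)
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(pair = paste(p, collapse = " vs "),
               rho = unname(ct$estimate),
               abs_rho = abs(unname(ct$estimate)),
               p_value = ct$p.value, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Partial correlation controlling for a covariate matrix
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares projection on `[1, Z]`. With no covariates this is the
#' plain Pearson correlation. The p-value uses the t distribution with
#' `n - ncol(Z) - 2` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param Z optional numeric matrix/data.frame of covariates (may be
#'   `NULL` or zero columns).
#' @return list with `r`, `p_value`, `df`, `n`. If either residual vector
#'   is (numerically) constant — e.g. `y` is itself a covariate — `r` and
#'   `p_value` are `NA`.
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(Z) || NCOL(Z) == 0 || (is.data.frame(Z) && ncol(Z) == 0)) {
    k <- 0L
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == n)
    k <- ncol(Z)
    if (n <= k + 2) stop("need n > number of covariates + 2")
    design <- cbind(`(Intercept)` = 1, Z)
    qd <- qr(design)
    if (qd$rank < ncol(design)) {
      bad <- colnames(design)[qd$pivot[seq(qd$rank + 1, ncol(design))]]
      stop("singular covariate matrix; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
    rx <- stats::lm.fit(design, x)$residuals
    ry <- stats::lm.fit(design, y)$residuals
  }
  eps <- sqrt(.Machine$double.eps)
  if (sqrt(mean(rx^2)) < eps * max(1, sqrt(mean(x^2))) ||
      sqrt(mean(ry^2)) < eps * max(1, sqrt(mean(y^2))))
    return(list(r = NA_real_, p_value = NA_real_, df = n - k - 2L, n = n))
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(tval), df), df = df, n = n)
}

#' Multiple linear regression of behavior indicators on a hierarchy index
#'
#' Ordinary least squares with intercept of one hierarchy index on the six
#' log-transformed dyadic behavior indicators, reporting the
#' unstandardized coefficient, its standard error, t statistic and
#' p-value per covariate.
#'
#' @param data data.frame holding `response` and all `covariates`;
#'   incomplete rows are dropped.
#' @param response name of the response column (e.g. `"isi_rank"`, `"elo"`,
#'   `"glicko"`).
#' @param covariates covariate column names; default the six dyadic
#'   indicators.
#' @return list with `response`, `n`, and `coefficients`, a data.frame
#'   (`term`, `B`, `SE`, `t`, `p_value`) excluding the intercept.
#' @export
multiple_regression <- function(data, response,
                                covariates = c("lgDAA", "lgDSO", "lgDBB",
                                               "lgFAA", "lgFSO", "lgFBB")) {
  cols <- c(response, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (nrow(d) <= length(covariates) + 1)
    stop("too few complete cases (n = ", nrow(d),
         ") for ", length(covariates), " covariates")
  fml <- stats::reformulate(covariates, response = response)
  fit <- stats::lm(fml, data = d)
  cf <- summary(fit)$coefficients
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  list(response = response, n = nrow(d),
       coefficients = data.frame(term = rownames(cf),
                                 B = cf[, 1], SE = cf[, 2], t = cf[, 3],
                                 p_value = cf[, 4], row.names = NULL,
                                 stringsAsFactors = FALSE),
       fit = fit)
}

#' Sex contrast on time to social stability
#'
#' Fixed-effects linear model of per-animal stability time on sex plus
#' (optionally) parity, sire and initial body weight with a sex-by-weight
#' interaction. Reports covariate-adjusted sex means with standard errors
#' (via estimated marginal means) and the p-value of the sex difference.
#'
#' @param stability_tbl data.frame with `stability_h`, `sex`, and — when
#'   `covariates = TRUE` — `parity`, `sire_id`, `initial_bw_kg`.
#' @param covariates include the metadata covariates (default TRUE). With
#'   FALSE the contrast reduces to a pooled-variance two-sample t test.
#' @return list with `means` (data.frame `sex`, `mean_h`, `se_h`),
#'   `p_sex`, `n`, and the underlying `fit`.
#' @export
sex_contrast <- function(stability_tbl, covariates = TRUE) {
  d <- stability_tbl
  stopifnot(all(c("stability_h", "sex") %in% names(d)))
  d <- d[stats::complete.cases(d[c("stability_h", "sex")]), , drop = FALSE]
  if (length(unique(d$sex)) < 2)
    stop("sex contrast undefined for single-sex data")
  d$sex <- factor(d$sex)
  if (covariates) {
    stopifnot(all(c("parity", "sire_id", "initial_bw_kg") %in% names(d)))
    d$sire_id <- factor(d$sire_id)
    fit <- stats::lm(stability_h ~ sex + parity + sire_id +
                       initial_bw_kg + sex:initial_bw_kg, data = d)
  } else {
    fit <- stats::lm(stability_h ~ sex, data = d)
  }
  emm <- suppressMessages(emmeans::emmeans(fit, "sex"))
  ms <- as.data.frame(emm)
  ctr <- as.data.frame(suppressMessages(emmeans::contrast(emm, "pairwise")))
  list(means = data.frame(sex = as.character(ms$sex), mean_h = ms$emmean,
                          se_h = ms$SE, stringsAsFactors = FALSE),
       p_sex = ctr$p.value[1],
       estimate_diff_h = ctr$estimate[1],
       se_diff_h = ctr$SE[1],
       n = nrow(d), fit = fit)
}
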