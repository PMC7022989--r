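test_that("partial correlation with no covariates is Pearson correlation", {
  set.seed(1)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-14)
  expect_equal(pc$p_value, ct$p.value, tolerance = 1e-12)
  expect_equal(partial_correlation(x, y, Z = NULL)$r,
               partial_correlation(x, y, Z = matrix(nrow = 40,
                                                    ncol = 0))$r)
})

test_that("degenerate and singular covariate cases are handled", {
  set.seed(2)
  x <- rnorm(30); z <- rnorm(30)
  # y identical to a covariate: residual vanishes, reported missing
  pc <- partial_correlation(x, z, Z = cbind(z = z))
  expect_true(is.na(pc$r) && is.na(pc$p_value))
  Z <- cbind(z1 = z, z2 = 2 * z)
  expect_error(partial_correlation(x, rnorm(30), Z), "collinear")
  expect_error(partial_correlation(x, rnorm(30), Z), "z2")
  expect_error(partial_correlation(rnorm(5), rnorm(5),
                                   Z = matrix(rnorm(15), 5)))
})

test_that("partial correlation recovers the generating value", {
  # x = Z + e1, y = Z + e1 + sqrt(3) e2 has partial corr(x, y | Z)
  # equal to cor(e1, e1 + sqrt(3) e2) = 1/sqrt(1 + 3) = 0.5
  set.seed(33)
  n <- 10000
  Z <- rnorm(n); e1 <- rnorm(n); e2 <- rnorm(n)
  x <- Z + e1
  y <- Z + e1 + sqrt(3) * e2
  pc <- partial_correlation(x, y, Z = cbind(Z))
  expect_equal(pc$r, 0.5, tolerance = 0.03)
  expect_lt(pc$p_value, 1e-10)
  expect_equal(pc$df, n - 3)
})

test_that("regression recovers a noiseless linear response exactly", {
  set.seed(3)
  d <- as.data.frame(matrix(rnorm(40 * 6), 40,
                            dimnames = list(NULL, c("lgDAA", "lgDSO",
                                                    "lgDBB", "lgFAA",
                                                    "lgFSO", "lgFBB"))))
  d$y <- 2 + 3 * d$lgDAA - 1.5 * d$lgDBB + 0.25 * d$lgFSO
  mr <- multiple_regression(d, "y")
  cf <- setNames(mr$coefficients$B, mr$coefficients$term)
  expect_equal(unname(cf[c("lgDAA", "lgDBB", "lgFSO")]),
               c(3, -1.5, 0.25), tolerance = 1e-10)
  expect_equal(unname(cf[c("lgDSO", "lgFAA", "lgFBB")]),
               c(0, 0, 0), tolerance = 1e-8)
  expect_true(all(mr$coefficients$SE < 1e-8))
  expect_error(multiple_regression(d[1:7, ], "y"), "too few")
})

test_that("OLS output matches the normal equations on a small fixture", {
  set.seed(4)
  n <- 25
  d <- data.frame(lgDAA = rnorm(n), lgDSO = rnorm(n), lgDBB = rnorm(n),
                  lgFAA = rnorm(n), lgFSO = rnorm(n), lgFBB = rnorm(n))
  d$y <- 1 + d$lgDAA - 2 * d$lgFBB + rnorm(n)
  mr <- multiple_regression(d, "y")
  X <- cbind(1, as.matrix(d[, 1:6]))
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  res <- d$y - X %*% beta
  s2 <- sum(res^2) / (n - 7)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(mr$coefficients$B, unname(beta[-1, 1]), tolerance = 1e-10)
  expect_equal(mr$coefficients$SE, unname(se[-1]), tolerance = 1e-10)
  expect_equal(mr$coefficients$t, mr$coefficients$B / mr$coefficients$SE)
  # residuals orthogonal to the design
  expect_lt(max(abs(t(X) %*% residuals(mr$fit))), 1e-8)
})

test_that("index correlations report signed and absolute Spearman rho", {
  # a perfectly linear hierarchy: all indices agree up to direction
  tab <- data.frame(isi_rank = 1:12, elo = seq(1300, 800, length = 12),
                    glicko = seq(2600, 1900, length = 12))
  ic <- index_correlations(tab)
  expect_equal(ic$abs_rho, rep(1, 3))
  expect_equal(ic$rho[ic$pair == "isi_rank vs glicko"], -1)
  expect_equal(ic$rho[ic$pair == "elo vs glicko"], 1)
  set.seed(5)
  tab2 <- data.frame(isi_rank = sample(12), elo = rnorm(12, 1000, 80),
                     glicko = rnorm(12, 2200, 150))
  ic2 <- index_correlations(tab2)
  o <- oracle_spearman(tab2$isi_rank, tab2$glicko)
  expect_equal(ic2$rho[1], o$rho, tolerance = 1e-10)
})

test_that("sex contrast without covariates reduces to a two-sample t test", {
  set.seed(6)
  d <- data.frame(stability_h = c(rnorm(15, 25, 5), rnorm(15, 40, 5)),
                  sex = rep(c("female", "barrow"), each = 15))
  sc <- sex_contrast(d, covariates = FALSE)
  tt <- t.test(stability_h ~ sex, data = d, var.equal = TRUE)
  expect_equal(sc$p_sex, tt$p.value, tolerance = 1e-10)
  expect_equal(sort(sc$means$mean_h),
               sort(unname(tt$estimate)), tolerance = 1e-10)
  # identical groups: no detectable difference
  d2 <- data.frame(stability_h = rep(c(20, 30, 40), 2),
                   sex = rep(c("female", "barrow"), each = 3))
  expect_gt(sex_contrast(d2, covariates = FALSE)$p_sex, 0.99)
  expect_error(sex_contrast(d[d$sex == "female", ], covariates = FALSE),
               "single-sex")
})

test_that("a simulated 15 h sex effect is recovered within 2 SE", {
  set.seed(7)
  n <- 100
  d <- data.frame(
    sex = rep(c("female", "barrow"), each = n / 2),
    parity = sample(1:4, n, TRUE),
    sire_id = sprintf("S%d", sample(1:6, n, TRUE)),
    initial_bw_kg = rnorm(n, 10, 1))
  d$stability_h <- ifelse(d$sex == "female", 25, 40) + rnorm(n, 0, 5)
  sc <- sex_contrast(d, covariates = TRUE)
  expect_lt(abs(abs(sc$estimate_diff_h) - 15), 2 * sc$se_diff_h)
  expect_lt(sc$p_sex, 0.001)
  means <- setNames(sc$means$mean_h, sc$means$sex)
  expect_lt(means[["female"]], means[["barrow"]])
})
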