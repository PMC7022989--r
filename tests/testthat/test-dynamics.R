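# small trajectory fixture: 3 animals, 6 hourly ratings
traj_fixture <- function() {
  M <- rbind(a = c(2200, 2250, 2300, 2310, 2320, 2330),
             b = c(2200, 2250, 2140, 2180, 2200, 2210),
             c = c(2200, 2100, 2150, 2120, 2100, 2090))
  colnames(M) <- 1:6
  M
}

test_that("hourly ranks sort by rating with the declared tie-breaks", {
  M <- traj_fixture()
  R <- hourly_ranks(M, initial_rating = 2200)
  expect_equal(unname(R[, 1]), c(1L, 2L, 3L))  # hour-1 tie broken by id
  expect_equal(unname(R[, 2]), c(1L, 2L, 3L))  # a/b tie: equal prev -> id
  expect_equal(unname(R[, 3]), c(1L, 3L, 2L))
  # tie at hour 3 between b and c resolved by hour-2 rating (b higher)
  M2 <- M; M2["c", 3] <- M2["b", 3]
  R2 <- hourly_ranks(M2, initial_rating = 2200)
  expect_equal(unname(R2[, 3]), c(1L, 2L, 3L))
  # every column is a full permutation
  expect_true(all(apply(R, 2, sort) == 1:3))
})

test_that("stability hour is the hour after the last rank change", {
  M <- traj_fixture()
  R <- hourly_ranks(M, initial_rating = 2200)
  st <- stability_time(R)
  expect_equal(st$stability_h[st$animal_id == "a"], 1)  # always rank 1
  expect_equal(st$stability_h[st$animal_id == "b"], 4)  # last swap at h3
  expect_equal(st$stability_h[st$animal_id == "c"], 4)
  # change at the final hour pins stability to the final hour
  Rl <- R; Rl["b", 5] <- 3L; Rl["c", 5] <- 2L
  stl <- stability_time(Rl)
  expect_equal(stl$stability_h[stl$animal_id == "b"], 6)
})

test_that("stability agrees with a reverse-scan oracle on random tables", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 6; H <- 20
    R <- sapply(1:H, function(h) sample(n))
    rownames(R) <- sprintf("x%d", 1:n)
    st <- stability_time(R)
    for (i in 1:n) {
      h <- H
      while (h > 1 && R[i, h - 1] == R[i, H]) h <- h - 1
      # oracle: walk back while the rank still equals the final rank
      expect_equal(st$stability_h[i], h)
    }
  }
})

test_that("freezing ratings from hour h on bounds stability by h", {
  ds <- simulate_herd(sim_config(n_pens = 1, pen_sizes = 10,
                                 pen_sex = "female", seed = 9))
  g <- glicko_hourly(filter_and_merge_fights(ds$interactions),
                     ds$animals, "A")
  M <- rating_matrix(g)
  for (h in c(10, 30, 50)) {
    Mf <- M
    Mf[, h:72] <- Mf[, h]
    st <- stability_time(hourly_ranks(Mf, 2200))
    expect_true(all(st$stability_h <= h))
  }
})

test_that("first-rank emergence scans the leader's tenure backwards", {
  M <- traj_fixture()
  expect_equal(first_rank_emergence(hourly_ranks(M, 2200)), 1)
  M["b", 4] <- 2400  # brief usurper at hour 4
  expect_equal(first_rank_emergence(hourly_ranks(M, 2200)), 5)
  M["b", 6] <- 2400  # leadership changes at the last hour
  expect_equal(first_rank_emergence(hourly_ranks(M, 2200)), 6)
})

test_that("hour-by-final correlations match an independent computation", {
  set.seed(21)
  M <- matrix(rnorm(8 * 12, 2200, 100), nrow = 8,
              dimnames = list(sprintf("x%d", 1:8), 1:12))
  hc <- hourly_final_correlation(M)
  expect_equal(nrow(hc), 12)
  expect_equal(hc$rho[12], 1)
  for (h in c(1, 5, 9)) {
    o <- oracle_spearman(M[, h], M[, 12])
    expect_equal(hc$rho[h], o$rho, tolerance = 1e-10)
    expect_equal(hc$p_value[h], o$p, tolerance = 1e-6)
  }
  expect_equal(hc$significant, hc$p_value < 0.05)
  expect_error(hourly_final_correlation(M[1:2, ]), "at least 3")
  Mc <- M; Mc[, 3] <- 2200
  expect_true(is.na(hourly_final_correlation(Mc)$rho[3]))
})

test_that("per-sex leader correlations pool one leader per pen", {
  ds <- simulate_herd(sim_config(n_pens = 6, pen_sizes = rep(8, 6),
                                 pen_sex = rep(c("female", "barrow"), 3),
                                 seed = 3))
  ev <- filter_and_merge_fights(ds$interactions)
  gl <- lapply(sort(unique(ds$animals$pen_id)), function(p)
    glicko_hourly(ev, ds$animals, p))
  names(gl) <- sort(unique(ds$animals$pen_id))
  lc <- leader_final_correlation(gl, ds$animals)
  expect_setequal(names(lc), c("female", "barrow"))
  for (s in names(lc)) {
    expect_equal(nrow(lc[[s]]), 72)
    expect_equal(lc[[s]]$rho[72], 1)
  }
})
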