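fresh_states <- function(ids, par = glicko_params()) {
  data.frame(animal_id = ids, rating = par$initial_rating,
             rd = par$initial_rd, stringsAsFactors = FALSE)
}

test_that("an individual with no games keeps its state when c = 0", {
  st <- fresh_states(c("A", "B", "C"))
  games <- data.frame(a = "A", b = "B", score_a = 1)
  out <- glicko_period_update(st, games)
  expect_equal(out[out$animal_id == "C", c("rating", "rd")],
               st[st$animal_id == "C", c("rating", "rd")],
               ignore_attr = TRUE)
  # with inflation, an idle RD grows but is capped at the initial value
  par <- glicko_params(c = 50)
  infl <- glicko_period_update(fresh_states("A", par),
                               data.frame(a = character(),
                                          b = character(),
                                          score_a = numeric()), par)
  expect_equal(infl$rd, 300)  # already at the cap
  shrunk <- data.frame(animal_id = "A", rating = 2200, rd = 100)
  expect_equal(glicko_period_update(shrunk, data.frame(a = character(),
                                                       b = character(),
                                                       score_a = numeric()),
                                    par)$rd, sqrt(100^2 + 50^2))
})

test_that("one decided game between fresh opponents moves both symmetrically", {
  st <- fresh_states(c("A", "B"))
  out <- glicko_period_update(st, data.frame(a = "A", b = "B",
                                             score_a = 1))
  # frozen values from a scalar computation of the Glicko-1 equations
  expect_equal(out$rating[out$animal_id == "A"], 2334.8650130551,
               tolerance = 1e-9)
  expect_equal(out$rating[out$animal_id == "B"], 2065.1349869449,
               tolerance = 1e-9)
  expect_equal(out$rd, rep(254.3588805439, 2), tolerance = 1e-9)
  expect_equal(sum(out$rating), 2 * 2200, tolerance = 1e-9)
  expect_true(all(out$rd < 300))
})

test_that("a multi-game period matches the hand-computed formulas", {
  st <- fresh_states(c("A", "B", "C"))
  games <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                      score_a = c(1, 1, 1))
  out <- glicko_period_update(st, games)
  # frozen step-by-step formula replay (all opponents at 2200/300)
  expect_equal(out$rating, c(2410.54097077, 2200, 1989.45902923),
               tolerance = 1e-6)
  expect_equal(out$rd, rep(224.72457526, 3), tolerance = 1e-6)
  # and agreement with the independent scalar oracle on an uneven state
  st2 <- data.frame(animal_id = c("A", "B", "C"),
                    rating = c(2350, 2180, 2070),
                    rd = c(120, 260, 300))
  out2 <- glicko_period_update(st2, games)
  for (id in st2$animal_id) {
    opp <- ifelse(games$a == id, games$b, games$a)
    mine <- games$a == id | games$b == id
    s <- ifelse(games$a[mine] == id, games$score_a[mine],
                1 - games$score_a[mine])
    o <- oracle_glicko(st2$rating[st2$animal_id == id],
                       st2$rd[st2$animal_id == id],
                       st2$rating[match(opp[mine], st2$animal_id)],
                       st2$rd[match(opp[mine], st2$animal_id)], s)
    expect_equal(out2$rating[out2$animal_id == id], unname(o["rating"]),
                 tolerance = 1e-9)
    expect_equal(out2$rd[out2$animal_id == id],
                 max(unname(o["rd"]), 30), tolerance = 1e-9)
  }
  expect_error(glicko_period_update(st, data.frame(a = "A", b = "Z",
                                                   score_a = 1)),
               "unknown id")
})

test_that("hourly trajectories compose sequential period updates", {
  animals <- make_animals(5)
  set.seed(4)
  n_ev <- 80
  pair <- t(replicate(n_ev, sample(animals$animal_id, 2)))
  x <- make_inter(pair[, 1], pair[, 2],
                  t = sort(runif(n_ev, 0, 72 * 3600)))
  x$outcome[sample(n_ev, 10)] <- "draw"
  res <- glicko_hourly(x, animals, "A", hours = 72)
  expect_equal(sort(unique(res$history$period)), 1:72)
  # replay period by period with the exported single-period update
  par <- glicko_params()
  st <- fresh_states(sort(animals$animal_id))
  dec <- x[x$outcome != "draw", ]
  for (p in 1:72) {
    inp <- dec[floor(dec$t_start_s / 3600) + 1 == p, ]
    st <- glicko_period_update(st,
                               data.frame(a = inp$actor_id,
                                          b = inp$receiver_id,
                                          score_a = rep(1, nrow(inp))),
                               par)
  }
  expect_equal(res$final, setNames(st$rating, st$animal_id))
  expect_equal(res$final_rd, setNames(st$rd, st$animal_id))
})

test_that("with c = 0, RD never increases and idle hours change nothing", {
  animals <- make_animals(4)
  x <- rbind(make_inter("A01", "A02", t = 100),
             make_inter("A03", "A04", t = 2000))
  res <- glicko_hourly(x, animals, "A", hours = 72)
  M <- rating_matrix(res)
  RD <- rating_matrix(res, "rd")
  expect_true(all(M[, 2:72] == M[, 1]))  # all games are in hour 1
  expect_true(all(RD[, -1] - RD[, -72] <= 1e-12))
  empty <- glicko_hourly(x[0, ], animals, "A", hours = 72)
  expect_true(all(rating_matrix(empty) == 2200))
  # RD monotone on a dense simulated pen, floored at rd_floor
  ds <- simulate_herd(sim_config(n_pens = 1, pen_sizes = 10,
                                 pen_sex = "female", seed = 2))
  g <- glicko_hourly(filter_and_merge_fights(ds$interactions),
                     ds$animals, "A")
  RD2 <- rating_matrix(g, "rd")
  expect_true(all(RD2[, -1] - RD2[, -72] <= 1e-12))
  expect_true(all(RD2 >= 30))
})
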