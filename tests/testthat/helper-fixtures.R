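# In-code fixture builders shared across test files.

make_animals <- function(n, pen = "A", sex = "female", prefix = pen) {
  data.frame(
    animal_id = sprintf("%s%02d", prefix, seq_len(n)),
    pen_id = pen, sex = sex,
    litter_id = sprintf("L%02d", seq_len(n)),
    parity = rep_len(1:3, n),
    sire_id = sprintf("S%d", rep_len(1:3, n)),
    initial_bw_kg = 10 + seq_len(n) / 10,
    final_bw_kg = 10.6 + seq_len(n) / 10,
    backtest_1 = rep_len(0:4, n),
    backtest_2 = rep_len(1:5, n),
    stringsAsFactors = FALSE)
}

make_inter <- function(actor, receiver, t, dur = 10,
                       behavior = "active_attack",
                       outcome = "actor_wins", pen = "A") {
  data.frame(pen_id = pen, t_start_s = t, duration_s = dur,
             actor_id = actor, receiver_id = receiver,
             behavior = behavior, outcome = outcome,
             stringsAsFactors = FALSE)
}

# random antisymmetric 0/1 dominance matrix (ties allowed)
random_dominance <- function(n, tie_prob = 0.2) {
  ids <- sprintf("X%02d", seq_len(n))
  B <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    u <- stats::runif(1)
    if (u < tie_prob) next
    if (u < tie_prob + (1 - tie_prob) / 2) B[i, j] <- 1L else B[j, i] <- 1L
  }
  B
}
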