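# Independent oracle implementations, deliberately written in a plain
# scalar style so they share no code path with the package.

# one Glicko-1 update for a single individual, straight from the formulas
oracle_glicko <- function(r, rd, opp_r, opp_rd, s) {
  q <- log(10) / 400
  gsum <- 0; esum <- 0
  for (k in seq_along(opp_r)) {
    gk <- 1 / sqrt(1 + 3 * q^2 * opp_rd[k]^2 / pi^2)
    Ek <- 1 / (1 + 10 ^ (-gk * (r - opp_r[k]) / 400))
    gsum <- gsum + gk * (s[k] - Ek)
    esum <- esum + gk^2 * Ek * (1 - Ek)
  }
  d2 <- 1 / (q^2 * esum)
  denom <- 1 / rd^2 + 1 / d2
  c(rating = r + q / denom * gsum, rd = sqrt(1 / denom))
}

# Spearman rho and its t-approximation p-value from first principles
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tv <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tv), n - 2))
}

# exhaustive I&SI search with its own permutation enumerator
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, 1] <- i
    rest <- seq_len(n)[-i]
    for (r in seq_len(nrow(sub))) block[r, -1] <- rest[sub[r, ]]
    out <- rbind(out, block)
  }
  out
}

oracle_isi_objective <- function(B, perm) {
  I <- 0L; SI <- 0L
  n <- length(perm)
  for (pi in seq_len(n - 1)) for (pj in seq(pi + 1, n)) {
    if (B[perm[pj], perm[pi]] == 1) {
      I <- I + 1L
      SI <- SI + (pj - pi)
    }
  }
  c(I, SI)
}

oracle_isi_best <- function(B) {
  P <- oracle_perms(nrow(B))
  best <- c(Inf, Inf)
  for (k in seq_len(nrow(P))) {
    o <- oracle_isi_objective(B, P[k, ])
    if (o[1] < best[1] || (o[1] == best[1] && o[2] < best[2])) best <- o
  }
  best
}
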