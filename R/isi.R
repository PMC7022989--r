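# I&SI rank orders: minimize the number of inconsistencies in a binary
# dominance matrix, then the total strength (rank distance) of those that
# remain.

as_dominance_matrix <- function(B) {
  if (inherits(B, "binary_dominance")) B <- B$B
  stopifnot(is.matrix(B), nrow(B) == ncol(B), all(B %in% c(0L, 1L)),
            all(diag(B) == 0), all(B * t(B) == 0))
  if (is.null(rownames(B)))
    dimnames(B) <- list(as.character(seq_len(nrow(B))),
                        as.character(seq_len(nrow(B))))
  B
}

#' Count inconsistencies of a rank order against a dominance matrix
#'
#' An inconsistency is a dyad in which the lower-positioned individual
#' dominates the higher-positioned one; its strength is the positional
#' distance between the two. Position 1 is most dominant.
#'
#' @param B a `binary_dominance` object or a 0/1 matrix with named rows.
#' @param order permutation of the ids (character) or of row indices
#'   (integer), most dominant first.
#' @return Integer vector `c(I = ..., SI = ...)`.
#' @export
count_inconsistencies <- function(B, order) {
  B <- as_dominance_matrix(B)
  perm <- if (is.character(order)) match(order, rownames(B)) else
    as.integer(order)
  if (anyNA(perm) || length(perm) != nrow(B) ||
      !setequal(perm, seq_len(nrow(B))))
    stop("order is not a permutation of the matrix ids")
  Bp <- B[perm, perm]
  inc <- Bp == 1 & lower.tri(Bp)
  c(I = sum(inc), SI = sum(row(Bp)[inc] - col(Bp)[inc]))
}

# lexicographic "a strictly better than b" on (I, SI)
lex_better <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])

isi_objective <- function(B, perm) {
  Bp <- B[perm, perm]
  inc <- Bp == 1 & lower.tri(Bp)
  c(sum(inc), sum(row(Bp)[inc] - col(Bp)[inc]))
}

# first-improvement local search over swap and single-insertion moves
isi_local_search <- function(B, perm, max_sweeps) {
  n <- length(perm)
  obj <- isi_objective(B, perm)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      cand <- perm
      cand[c(i, j)] <- cand[c(j, i)]
      cobj <- isi_objective(B, cand)
      if (lex_better(cobj, obj)) {
        perm <- cand; obj <- cobj; improved <- TRUE
      }
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      cand <- append(perm[-i], perm[i], after = j - 1)
      cobj <- isi_objective(B, cand)
      if (lex_better(cobj, obj)) {
        perm <- cand; obj <- cobj; improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(perm = perm, obj = obj)
}

#' I&SI rank order of a binary dominance matrix
#'
#' Finds an ordering of individuals minimizing first the number of
#' inconsistencies I, then their total strength SI (lexicographically).
#' The search starts from the order of descending net wins (row sums minus
#' column sums of `B`) and improves it by strictly-improving swap and
#' insertion moves; seeded random restarts guard against local optima. The
#' result is deterministic given `seed`.
#'
#' @param B a `binary_dominance` object or 0/1 matrix.
#' @param seed integer seed for the restart shuffles.
#' @param n_restarts number of random restarts after the deterministic
#'   start (default 20).
#' @param max_sweeps cap on improvement sweeps per start (default 1000).
#' @return An object of class `rank_order`: list with `pen_id`, `order`
#'   (ids, most dominant first), `ranks` (named 1..n vector), `I`, `SI`,
#'   `n_restarts_used`, `seed` and `multiple_optima` (TRUE if distinct
#'   orders attaining the optimal (I, SI) were observed).
#' @export
isi_rank <- function(B, seed = 1L, n_restarts = 20L, max_sweeps = 1000L) {
  pen_id <- if (inherits(B, "binary_dominance")) B$pen_id else NA_character_
  B <- as_dominance_matrix(B)
  n <- nrow(B)
  if (n < 2) stop("need at least 2 individuals")
  ids <- rownames(B)
  net <- rowSums(B) - colSums(B)
  start <- order(-net, ids)
  best <- isi_local_search(B, start, max_sweeps)
  multiple <- FALSE
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      res <- isi_local_search(B, sample(n), max_sweeps)
      if (lex_better(res$obj, best$obj)) {
        best <- res
        multiple <- FALSE
      } else if (all(res$obj == best$obj) &&
                 !all(res$perm == best$perm)) {
        multiple <- TRUE
      }
    }
  })
  structure(list(pen_id = pen_id,
                 order = ids[best$perm],
                 ranks = stats::setNames(match(ids, ids[best$perm]), ids),
                 I = best$obj[1], SI = best$obj[2],
                 n_restarts_used = n_restarts, seed = as.integer(seed),
                 multiple_optima = multiple),
            class = "rank_order")
}

#' @export
print.rank_order <- function(x, ...) {
  cat(sprintf("<rank_order> pen %s: I = %d, SI = %d\n  %s\n",
              x$pen_id, x$I, x$SI, paste(x$order, collapse = " > ")))
  invisible(x)
}

all_permutations <- function(v) {
  n <- length(v)
  if (n <= 1) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(v[i], all_permutations(v[-i]))))
}

#' Exact I&SI optimum by exhaustive search
#'
#' Enumerates every permutation and returns the lexicographic (I, SI)
#' optimum. Intended for small groups (n <= 9) and as a correctness check
#' for [isi_rank()].
#'
#' @param B a `binary_dominance` object or 0/1 matrix with n <= 9 rows.
#' @return list with `order` (ids), `I`, `SI` and `n_optima`, the number of
#'   permutations attaining the optimum.
#' @export
isi_exhaustive <- function(B) {
  B <- as_dominance_matrix(B)
  n <- nrow(B)
  if (n > 9) stop("exhaustive search limited to n <= 9")
  P <- all_permutations(seq_len(n))
  best <- c(Inf, Inf)
  best_perm <- NULL
  n_opt <- 0L
  for (k in seq_len(nrow(P))) {
    obj <- isi_objective(B, P[k, ])
    if (lex_better(obj, best)) {
      best <- obj; best_perm <- P[k, ]; n_opt <- 1L
    } else if (all(obj == best)) n_opt <- n_opt + 1L
  }
  list(order = rownames(B)[best_perm], I = best[1], SI = best[2],
       n_optima = n_opt)
}
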