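# Win/loss frequency sociomatrices and their binarized dominance form.

#' Build a per-pen win/loss frequency sociomatrix
#'
#' Tallies decided interactions of one pen into a square matrix with winners
#' in rows and losers in columns: `W[i, j]` is the number of decided events
#' in which `i` beat `j`. Draws contribute nothing. Row/column order is the
#' stable alphabetical sort of animal ids, so input row order does not
#' affect the matrix.
#'
#' @param interactions filtered/merged interaction table.
#' @param animals animal metadata table (defines pen membership).
#' @param pen_id pen to tabulate.
#' @return An object of class `sociomatrix`: list with `pen_id`, `ids` and
#'   the integer matrix `W` (zero diagonal).
#' @export
build_sociomatrix <- function(interactions, animals, pen_id) {
  ids <- pen_members(animals, pen_id)
  n <- length(ids)
  W <- matrix(0L, n, n, dimnames = list(ids, ids))
  x <- interactions[interactions$pen_id == pen_id &
                      interactions$outcome != "draw", , drop = FALSE]
  if (nrow(x)) {
    winner <- ifelse(x$outcome == "actor_wins", x$actor_id, x$receiver_id)
    loser  <- ifelse(x$outcome == "actor_wins", x$receiver_id, x$actor_id)
    for (k in seq_along(winner))
      W[winner[k], loser[k]] <- W[winner[k], loser[k]] + 1L
  }
  structure(list(pen_id = pen_id, ids = ids, W = W), class = "sociomatrix")
}

#' @export
print.sociomatrix <- function(x, ...) {
  cat(sprintf("<sociomatrix> pen %s, %d animals, %d decided interactions\n",
              x$pen_id, length(x$ids), sum(x$W)))
  print(x$W)
  invisible(x)
}

#' Binarize a sociomatrix into a dominance matrix
#'
#' `B[i, j] = 1` if `i` won more often against `j` than vice versa
#' (`W[i, j] > W[j, i]`); if the dyad is tied — including never having
#' interacted — both entries are 0.
#'
#' @param m a [build_sociomatrix()] result.
#' @return An object of class `binary_dominance`: list with `pen_id`, `ids`
#'   and the 0/1 matrix `B` satisfying `B[i, j] == 1 => B[j, i] == 0`.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "sociomatrix"))
  B <- (m$W > t(m$W)) + 0L
  dimnames(B) <- dimnames(m$W)
  structure(list(pen_id = m$pen_id, ids = m$ids, B = B),
            class = "binary_dominance")
}

#' @export
print.binary_dominance <- function(x, ...) {
  cat(sprintf("<binary_dominance> pen %s, %d animals\n",
              x$pen_id, length(x$ids)))
  print(x$B)
  invisible(x)
}

#' Write a sociomatrix (or binary dominance matrix) as TSV
#'
#' @param m a `sociomatrix` or `binary_dominance` object.
#' @param path output path; row and column headers are animal ids.
#' @return Invisibly, `path`.
#' @export
write_sociomatrix <- function(m, path) {
  M <- if (inherits(m, "sociomatrix")) m$W else m$B
  utils::write.table(data.frame(animal_id = rownames(M), M,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
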