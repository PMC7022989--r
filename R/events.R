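# Fight-validity filtering, same-pair fight merging, dyadic summaries.

#' Apply fight-validity and fight-merging rules
#'
#' Two rules define a countable fight: it must last at least `min_dur_s`
#' seconds, and two fights of the same (unordered) pair must be separated by
#' at least `merge_gap_s` seconds, otherwise they are one fight event.
#' Events shorter than `min_dur_s` are dropped first; then, scanning each
#' pair's events left-to-right in time, an event whose start follows the
#' previous event's end by less than `merge_gap_s` is merged into it
#' transitively. A merged event spans from the first constituent's start to
#' the last constituent's end (duration = span) and takes its behavior and
#' outcome from the last constituent.
#'
#' @param interactions interaction table (see [agon_dataset()]), sorted by
#'   `t_start_s`.
#' @param min_dur_s minimum fight duration in seconds (default 3).
#' @param merge_gap_s minimum separation between distinct fights of one pair
#'   in seconds, measured end-to-start (default 8).
#' @return Filtered/merged interaction table, sorted by `t_start_s`.
#' @export
filter_and_merge_fights <- function(interactions, min_dur_s = 3,
                                    merge_gap_s = 8) {
  x <- interactions
  if (nrow(x) == 0) return(x)
  x <- x[x$duration_s >= min_dur_s, , drop = FALSE]
  if (nrow(x) <= 1 || merge_gap_s <= 0) {
    rownames(x) <- NULL
    return(x)
  }
  pair <- ifelse(x$actor_id < x$receiver_id,
                 paste(x$pen_id, x$actor_id, x$receiver_id, sep = "\r"),
                 paste(x$pen_id, x$receiver_id, x$actor_id, sep = "\r"))
  out <- lapply(split(seq_len(nrow(x)), pair), function(idx) {
    ev <- x[idx, , drop = FALSE]
    keep <- ev[1, , drop = FALSE]
    k <- 1
    end_k <- keep$t_start_s[k] + keep$duration_s[k]
    for (i in seq_len(nrow(ev))[-1]) {
      if (ev$t_start_s[i] - end_k < merge_gap_s) {
        # extend the open fight; identity of the event follows its last part
        end_k <- max(end_k, ev$t_start_s[i] + ev$duration_s[i])
        keep$duration_s[k] <- end_k - keep$t_start_s[k]
        keep$behavior[k]   <- ev$behavior[i]
        keep$outcome[k]    <- ev$outcome[i]
        keep$actor_id[k]   <- ev$actor_id[i]
        keep$receiver_id[k] <- ev$receiver_id[i]
      } else {
        keep <- rbind(keep, ev[i, , drop = FALSE])
        k <- k + 1
        end_k <- keep$t_start_s[k] + keep$duration_s[k]
      }
    }
    keep
  })
  res <- do.call(rbind, out)
  res <- res[order(res$t_start_s, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-animal dyadic behavior summaries
#'
#' Accrues durations and counts of the three behavior classes to
#' individuals: active attacks credit the actor (DAA/FAA); being the
#' receiver of an active attack or of bullying credits the receiver
#' (DBB/FBB); standoffs have no aggressor and credit both participants
#' (DSO/FSO). Log columns are `log10(x + 1)`, which keeps zero-activity
#' animals defined.
#'
#' @param interactions filtered/merged interaction table.
#' @param animals animal metadata table; every animal gets a row, zeros if
#'   it never interacted.
#' @return data.frame with one row per animal: `animal_id`, `pen_id`, the
#'   raw fields `DAA, DSO, DBB` (seconds) and `FAA, FSO, FBB` (counts), and
#'   their log10(x+1) transforms `lgDAA, ..., lgFBB`.
#' @export
summarize_dyadic <- function(interactions, animals) {
  ids <- animals$animal_id
  z <- stats::setNames(numeric(length(ids)), ids)
  acc <- list(DAA = z, DSO = z, DBB = z, FAA = z, FSO = z, FBB = z)
  add <- function(field, who, amount) {
    t <- tapply(amount, who, sum)
    acc[[field]][names(t)] <<- acc[[field]][names(t)] + t
  }
  x <- interactions
  aa <- x[x$behavior == "active_attack", , drop = FALSE]
  if (nrow(aa)) {
    add("DAA", aa$actor_id, aa$duration_s)
    add("FAA", aa$actor_id, rep(1, nrow(aa)))
    add("DBB", aa$receiver_id, aa$duration_s)
    add("FBB", aa$receiver_id, rep(1, nrow(aa)))
  }
  bb <- x[x$behavior == "being_bullied", , drop = FALSE]
  if (nrow(bb)) {
    add("DBB", bb$receiver_id, bb$duration_s)
    add("FBB", bb$receiver_id, rep(1, nrow(bb)))
  }
  so <- x[x$behavior == "standoff", , drop = FALSE]
  if (nrow(so)) {
    for (side in c("actor_id", "receiver_id")) {
      add("DSO", so[[side]], so$duration_s)
      add("FSO", so[[side]], rep(1, nrow(so)))
    }
  }
  res <- data.frame(animal_id = ids, pen_id = animals$pen_id,
                    stringsAsFactors = FALSE)
  for (f in names(acc)) res[[f]] <- unname(acc[[f]])
  for (f in names(acc)) res[[paste0("lg", f)]] <- log10(res[[f]] + 1)
  res
}
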