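# Shared domain objects: animal metadata, interaction records, datasets.

SEXES      <- c("female", "barrow")
BEHAVIORS  <- c("active_attack", "being_bullied", "standoff")
OUTCOMES   <- c("actor_wins", "receiver_wins", "draw")

ANIMAL_COLS <- c("animal_id", "pen_id", "sex", "litter_id", "parity",
                 "sire_id", "initial_bw_kg", "final_bw_kg",
                 "backtest_1", "backtest_2")
INTER_COLS  <- c("pen_id", "t_start_s", "duration_s", "actor_id",
                 "receiver_id", "behavior", "outcome")

#' Assemble and validate a dataset of animals and interactions
#'
#' Bundles an animal metadata table and an interaction log into a single
#' validated object. Interactions are sorted ascending by start time with a
#' stable tie-break on input order, which sequential rating methods rely on.
#'
#' @param animals data.frame with columns `animal_id`, `pen_id`, `sex`
#'   (`"female"` or `"barrow"`), `litter_id`, `parity`, `sire_id`,
#'   `initial_bw_kg`, `final_bw_kg`, `backtest_1`, `backtest_2`. Weights and
#'   backtest counts may be `NA`.
#' @param interactions data.frame with columns `pen_id`, `t_start_s`,
#'   `duration_s`, `actor_id`, `receiver_id`, `behavior`, `outcome`.
#' @param truth optional data.frame of latent simulation truth
#'   (`animal_id`, `latent`); carried along for validation studies.
#' @return An object of class `agon_dataset`: a list with elements
#'   `animals`, `interactions` and optionally `truth`.
#' @export
agon_dataset <- function(animals, interactions, truth = NULL) {
  animals <- validate_animals(animals)
  interactions <- validate_interactions(interactions, animals)
  structure(list(animals = animals, interactions = interactions,
                 truth = truth),
            class = "agon_dataset")
}

#' @export
print.agon_dataset <- function(x, ...) {
  cat(sprintf("<agon_dataset> %d animals in %d pens, %d interactions\n",
              nrow(x$animals), length(unique(x$animals$pen_id)),
              nrow(x$interactions)))
  invisible(x)
}

validate_animals <- function(animals) {
  miss <- setdiff(ANIMAL_COLS, names(animals))
  if (length(miss))
    stop("animals table lacks columns: ", paste(miss, collapse = ", "))
  animals <- as.data.frame(animals)[ANIMAL_COLS]
  for (col in c("animal_id", "pen_id", "sex", "litter_id", "sire_id"))
    animals[[col]] <- as.character(animals[[col]])
  for (col in c("parity", "initial_bw_kg", "final_bw_kg",
                "backtest_1", "backtest_2"))
    animals[[col]] <- as.numeric(animals[[col]])
  if (anyDuplicated(animals$animal_id))
    stop("duplicate animal_id: ",
         paste(unique(animals$animal_id[duplicated(animals$animal_id)]),
               collapse = ", "))
  if (anyNA(animals$animal_id) || anyNA(animals$pen_id))
    stop("animal_id and pen_id are required for every animal")
  bad_sex <- !animals$sex %in% SEXES
  if (any(bad_sex))
    stop("invalid sex value(s): ",
         paste(unique(animals$sex[bad_sex]), collapse = ", "))
  mixed <- tapply(animals$sex, animals$pen_id,
                  function(s) length(unique(s)) > 1)
  if (any(mixed))
    stop("pens are not single-sex: ",
         paste(names(mixed)[mixed], collapse = ", "))
  neg <- c("initial_bw_kg", "final_bw_kg", "backtest_1", "backtest_2")
  for (col in neg)
    if (any(animals[[col]] < 0, na.rm = TRUE))
      stop("negative values in ", col)
  # mean backtest score used downstream; kept alongside the two replicates
  animals$backtest_mean <- rowMeans(animals[c("backtest_1", "backtest_2")])
  rownames(animals) <- NULL
  animals
}

validate_interactions <- function(interactions, animals) {
  miss <- setdiff(INTER_COLS, names(interactions))
  if (length(miss))
    stop("interactions table lacks columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(interactions)[INTER_COLS]
  if (nrow(x) == 0) {
    rownames(x) <- NULL
    return(x)
  }
  for (col in c("pen_id", "actor_id", "receiver_id", "behavior", "outcome"))
    x[[col]] <- as.character(x[[col]])
  for (col in c("t_start_s", "duration_s")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (anyNA(v))
      stop("malformed ", col, " at row(s) ",
           paste(which(is.na(v)), collapse = ", "))
    x[[col]] <- v
  }
  fail <- function(rows, what)
    stop(what, " at row(s) ", paste(rows, collapse = ", "))
  if (any(bad <- x$t_start_s < 0)) fail(which(bad), "negative t_start_s")
  if (any(bad <- x$duration_s <= 0)) fail(which(bad), "non-positive duration_s")
  if (any(bad <- !x$behavior %in% BEHAVIORS))
    fail(which(bad), "unknown behavior")
  if (any(bad <- !x$outcome %in% OUTCOMES))
    fail(which(bad), "unknown outcome")
  if (any(bad <- x$actor_id == x$receiver_id))
    fail(which(bad), "actor_id equals receiver_id")
  known <- animals$animal_id
  if (any(bad <- !(x$actor_id %in% known & x$receiver_id %in% known)))
    fail(which(bad), "interaction references unknown animal")
  pen_of <- stats::setNames(animals$pen_id, animals$animal_id)
  if (any(bad <- pen_of[x$actor_id] != x$pen_id |
                 pen_of[x$receiver_id] != x$pen_id))
    fail(which(bad), "animal does not belong to the stated pen")
  # stable sort: ties on t_start_s keep input order (radix sort is stable)
  x <- x[order(x$t_start_s, method = "radix"), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read an interaction log and animal metadata from CSV files
#'
#' Expects UTF-8 comma-delimited files with header rows. Times are seconds
#' since mixing. Any interaction row with a missing required field, an
#' unknown animal, or `actor_id == receiver_id` is rejected with its row
#' number; missing optional metadata (weights, backtest counts) is kept as
#' `NA` and propagated.
#'
#' @param interactions_path path to the interaction CSV
#'   (`pen_id,t_start_s,duration_s,actor_id,receiver_id,behavior,outcome`).
#' @param animals_path path to the animal metadata CSV
#'   (`animal_id,pen_id,sex,litter_id,parity,sire_id,initial_bw_kg,final_bw_kg,backtest_1,backtest_2`).
#' @return A validated [agon_dataset()].
#' @export
read_interactions <- function(interactions_path, animals_path) {
  for (p in c(interactions_path, animals_path))
    if (!file.exists(p)) stop("file not found: ", p)
  animals <- utils::read.csv(animals_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  interactions <- utils::read.csv(interactions_path,
                                  stringsAsFactors = FALSE,
                                  colClasses = "character")
  agon_dataset(animals, interactions)
}

#' Write a dataset back to CSV files
#'
#' Inverse of [read_interactions()]: writing and re-reading reproduces the
#' records field-for-field.
#'
#' @param dataset an [agon_dataset()].
#' @param interactions_path,animals_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_interactions <- function(dataset, interactions_path, animals_path) {
  stopifnot(inherits(dataset, "agon_dataset"))
  utils::write.csv(dataset$interactions[INTER_COLS], interactions_path,
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$animals[ANIMAL_COLS], animals_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(interactions_path, animals_path))
}

#' Average daily gain over the observation window
#'
#' Body-weight change per day, `(final - initial) / days`; may be negative.
#' Animals with a missing weight get `NA` and are excluded from downstream
#' statistics.
#'
#' @param animals animal metadata table (as in [agon_dataset()]).
#' @param days length of the window in days; default 3 (the 72 h window).
#' @return Named numeric vector of kg/day, one element per animal.
#' @export
compute_adg <- function(animals, days = 3) {
  stopifnot(is.numeric(days), days > 0)
  stats::setNames((animals$final_bw_kg - animals$initial_bw_kg) / days,
                  animals$animal_id)
}

pen_members <- function(animals, pen_id) {
  ids <- animals$animal_id[animals$pen_id == pen_id]
  if (!length(ids)) stop("pen has no animals: ", pen_id)
  sort(ids)
}
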