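#' Construct a ranked screen
#'
#' A `ranked_screen` holds one target's ordered virtual-screening outcome:
#' every library compound with its docking score, active/decoy label and
#' 1-based rank (rank 1 = best). It is the substrate of all performance
#' metrics. Use [rank_compounds()] to build one from raw scores; this
#' constructor expects entries already ordered by rank.
#'
#' @param target_id Single string identifying the target.
#' @param entries Data frame with columns `compound_id`, `score`,
#'   `is_active` (logical), ordered from best to worst.
#' @return An object of class `ranked_screen`: the entries plus derived
#'   counts `N` (library size), `n` (actives) and `R_a = n/N`.
#' @export
ranked_screen <- function(target_id, entries) {
  stopifnot(is.character(target_id), length(target_id) == 1L)
  req <- c("compound_id", "score", "is_active")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols))
    stop("entries lack column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(entries$compound_id))
    stop("duplicate compound_id within target '", target_id, "'")
  N <- nrow(entries)
  n <- sum(entries$is_active)
  if (n < 1L || n >= N)
    stop("target '", target_id, "' needs at least one active and one decoy ",
         "(n = ", n, ", N = ", N, ")")
  out <- list(
    target_id = target_id,
    entries = data.frame(compound_id = as.character(entries$compound_id),
                         score = as.numeric(entries$score),
                         is_active = as.logical(entries$is_active),
                         rank = seq_len(N),
                         stringsAsFactors = FALSE),
    N = N, n = n, R_a = n / N
  )
  class(out) <- "ranked_screen"
  out
}

#' @export
print.ranked_screen <- function(x, ...) {
  cat("<ranked_screen> target:", x$target_id,
      "| N =", x$N, "| actives =", x$n,
      sprintf("(R_a = %.4f)\n", x$R_a))
  invisible(x)
}

#' Ranks of the active compounds
#'
#' @param screen A [ranked_screen()].
#' @return Integer vector of 1-based ranks of the actives.
#' @export
active_ranks <- function(screen) {
  stopifnot(inherits(screen, "ranked_screen"))
  screen$entries$rank[screen$entries$is_active]
}

#' Rank scored compounds into a screen
#'
#' Orders compounds by docking score and assigns ranks 1..N. By default a
#' higher score is better; set `ascending = TRUE` for energy-like scores
#' where lower is better. Score ties are broken by `tie_policy`:
#' `"stable"` keeps the input order, `"pessimistic"` places actives last
#' within each tie block and `"optimistic"` places them first — the two
#' extremes bound the metric uncertainty introduced by ties.
#'
#' @param target_id Target identifier.
#' @param compound_id Character vector of compound identifiers.
#' @param score Numeric docking scores (no NA/NaN).
#' @param is_active Logical labels.
#' @param ascending If `TRUE`, lower scores rank better.
#' @param tie_policy One of `"stable"`, `"pessimistic"`, `"optimistic"`.
#' @return A [ranked_screen()].
#' @export
rank_compounds <- function(target_id, compound_id, score, is_active,
                           ascending = FALSE,
                           tie_policy = c("stable", "pessimistic", "optimistic")) {
  tie_policy <- match.arg(tie_policy)
  if (!length(score)) stop("empty entry list")
  bad <- is.na(score) | is.nan(score) | is.infinite(score)
  if (any(bad))
    stop("non-finite score for compound(s): ",
         paste(compound_id[bad], collapse = ", "))
  is_active <- as.logical(is_active)
  key <- if (ascending) score else -score
  tie_key <- switch(tie_policy,
    stable      = seq_along(score),
    pessimistic = as.integer(is_active),   # actives after decoys in ties
    optimistic  = as.integer(!is_active))
  ord <- order(key, tie_key, method = "radix")
  ranked_screen(target_id, data.frame(
    compound_id = compound_id[ord], score = score[ord],
    is_active = is_active[ord], stringsAsFactors = FALSE))
}

#' Read a collection of ranked screens from CSV
#'
#' Expects columns `target_id`, `compound_id`, `score`, `is_active`; rows
#' for one target may appear in any order and are ranked by score
#' (descending unless `ascending`). Each target must have at least one
#' active and one decoy and unique compound ids.
#'
#' @param path CSV file path.
#' @inheritParams rank_compounds
#' @return Named list of [ranked_screen()] objects, one per target.
#' @export
read_ranked_screens <- function(path, ascending = FALSE,
                                tie_policy = "stable") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("target_id", "compound_id", "score", "is_active")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df$is_active <- parse_flag(df$is_active)
  split_df <- split(df, df$target_id)
  screens <- lapply(split_df, function(d)
    rank_compounds(d$target_id[1], d$compound_id, d$score, d$is_active,
                   ascending = ascending, tie_policy = tie_policy))
  screens[unique(df$target_id)]
}

#' Write a collection of ranked screens to CSV
#'
#' @param screens Named list of [ranked_screen()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranked_screens <- function(screens, path) {
  rows <- lapply(screens, function(s)
    data.frame(target_id = s$target_id, s$entries[c("compound_id", "score",
                                                    "is_active")],
               stringsAsFactors = FALSE))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}
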