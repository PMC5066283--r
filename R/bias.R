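#' Normalized actives-minus-decoys property difference (Delta-P)
#'
#' For one property P and each target,
#' `Delta-P = (P_actives - P_decoys) / (max(P_actives) - min(P_actives))`,
#' where the numerator uses the target's own group means and the
#' denominator is the range of the per-target ACTIVES means across the
#' analyzed collection — one shared denominator per property, recomputed
#' for every collection.
#'
#' @param tables Long property table over >= 2 targets (rows
#'   `target_id`, `property`, `actives_mean`, `decoys_mean`), e.g. rbind
#'   of [property_table()] outputs.
#' @param property One of [screen_properties].
#' @return Named numeric vector of Delta-P per target.
#' @export
normalized_property_difference <- function(tables, property) {
  d <- tables[tables$property == property, , drop = FALSE]
  if (!nrow(d)) stop("no rows for property '", property, "'")
  if (length(unique(d$target_id)) < 2L)
    stop("need at least two targets to normalize property '", property, "'")
  rng <- max(d$actives_mean) - min(d$actives_mean)
  if (rng == 0)
    stop("zero actives-mean range for property '", property,
         "': Delta-P undefined")
  setNames((d$actives_mean - d$decoys_mean) / rng, d$target_id)
}

#' Per-target Delta-P matrix over the nine properties
#'
#' @inheritParams normalized_property_difference
#' @return Data frame: `target_id` plus one `dP_<property>` column per
#'   property.
#' @export
delta_p_matrix <- function(tables) {
  props <- unique(tables$property)
  cols <- lapply(props, function(p) normalized_property_difference(tables, p))
  ids <- names(cols[[1]])
  out <- data.frame(target_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(props))
    out[[paste0("dP_", props[i])]] <- unname(cols[[i]][ids])
  out
}

#' Overall chemical-library bias statistic S
#'
#' `S = sum_i |Delta-P_i|` over the nine properties: 0 means a perfectly
#' property-matched library, larger values mean stronger construction
#' bias.
#'
#' @param delta_p Numeric vector of exactly nine Delta-P values.
#' @return Nonnegative real.
#' @export
bias_sum <- function(delta_p) {
  delta_p <- unlist(delta_p)
  if (length(delta_p) != 9L)
    stop("S needs exactly nine Delta-P entries, got ", length(delta_p))
  if (anyNA(delta_p)) stop("missing Delta-P value")
  sum(abs(delta_p))
}

#' Build per-target bias profiles
#'
#' Combines the Delta-P matrix, its absolute sum S and the fingerprint
#' similarity summaries into one profile row per target.
#'
#' @param tables Long property table (see
#'   [normalized_property_difference()]).
#' @param similarities Optional data frame `target_id`, `sim_act_act`,
#'   `sim_cryst_act`.
#' @return Data frame: `target_id`, `dP_*` columns, `S`, and similarity
#'   columns (NA when not supplied).
#' @export
bias_profiles <- function(tables, similarities = NULL) {
  dp <- delta_p_matrix(tables)
  dp$S <- apply(dp[grep("^dP_", names(dp))], 1, bias_sum)
  if (!is.null(similarities)) {
    i <- match(dp$target_id, similarities$target_id)
    dp$sim_act_act <- similarities$sim_act_act[i]
    dp$sim_cryst_act <- similarities$sim_cryst_act[i]
  } else {
    dp$sim_act_act <- NA_real_
    dp$sim_cryst_act <- NA_real_
  }
  dp
}

#' Mean and median of S over a collection
#'
#' @param profiles Data frame with an `S` column (see [bias_profiles()]),
#'   or a numeric vector of S values.
#' @return List with `mean` and `median`.
#' @export
collection_bias_stats <- function(profiles) {
  s <- if (is.data.frame(profiles)) profiles$S else as.numeric(profiles)
  if (!length(s)) stop("no S values")
  list(mean = mean(s), median = median(s))
}

#' Pearson correlation with Student t test
#'
#' Sample Pearson coefficient r, its t statistic
#' `t = r sqrt(n-2) / sqrt(1-r^2)` and the two-sided p-value from the t
#' distribution with n-2 degrees of freedom, plus the significance tier:
#' `significant` when p <= 1e-4, `questionable` when 1e-4 < p <= 1e-2,
#' `none` otherwise. No multiple-testing correction is applied; the
#' stringent significant tier is the stand-in for one.
#'
#' @param x,y Numeric vectors of equal length n >= 3, non-constant, no
#'   missing values.
#' @param names Optional length-2 character vector naming the variables.
#' @return A `correlation_result`: list with `var_x`, `var_y`, `r`, `t`,
#'   `p`, `tier`, `n`.
#' @export
pearson_with_pvalue <- function(x, y, names = c("x", "y")) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing or NaN values")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector")
  r <- cor(x, y)
  t_stat <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  structure(list(var_x = names[1], var_y = names[2], r = r, t = t_stat,
                 p = p, tier = correlation_tier(p), n = n),
            class = "correlation_result")
}

#' Significance tier of a correlation p-value
#'
#' @param p P-value(s).
#' @return `"significant"` (p <= 1e-4), `"questionable"`
#'   (1e-4 < p <= 1e-2) or `"none"`.
#' @export
correlation_tier <- function(p) {
  ifelse(p <= 1e-4, "significant", ifelse(p <= 1e-2, "questionable", "none"))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s ~ %s: r = %.3f, t = %.2f, p = %.3g (%s), n = %d\n",
              x$var_x, x$var_y, x$r, x$t, x$p, x$tier, x$n))
  invisible(x)
}

#' Correlation screen of program performance against covariates
#'
#' One tiered Pearson correlation per (program, covariate) pair, aligned
#' by target id. `exclude_targets` supports leave-one-family-out
#' re-screening (the t test then uses the reduced n).
#'
#' @param bedrocs Data frame with `target_id` plus one numeric column per
#'   program (per-target BEDROC scores).
#' @param covariates Data frame with `target_id` plus one numeric column
#'   per covariate (cavity statistics, per-group property means,
#'   similarity summaries, ...).
#' @param exclude_targets Optional target ids to drop before correlating.
#' @return Data frame: `program`, `covariate`, `r`, `t`, `p`, `tier`, `n`.
#' @export
correlation_screen <- function(bedrocs, covariates, exclude_targets = NULL) {
  if (!setequal(bedrocs$target_id, covariates$target_id))
    stop("bedrocs and covariates cover different target sets")
  keep <- setdiff(bedrocs$target_id, exclude_targets)
  b <- bedrocs[match(keep, bedrocs$target_id), , drop = FALSE]
  cv <- covariates[match(keep, covariates$target_id), , drop = FALSE]
  progs <- setdiff(names(b), "target_id")
  covs <- setdiff(names(cv), "target_id")
  rows <- list()
  for (pg in progs) for (co in covs) {
    res <- pearson_with_pvalue(b[[pg]], cv[[co]], names = c(pg, co))
    rows[[length(rows) + 1L]] <- data.frame(
      program = pg, covariate = co, r = res$r, t = res$t, p = res$p,
      tier = res$tier, n = res$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Select the unbiased target subset
#'
#' Targets whose chemical library shows no exploitable construction bias:
#' S strictly below `S_threshold` (default: the analyzed collection's own
#' mean S) AND Sim2D_cryst-act strictly below `sim_threshold` (default
#' 0.1; fingerprint-dialect dependent).
#'
#' @param profiles Data frame from [bias_profiles()] (needs `S` and
#'   `sim_cryst_act`).
#' @param S_threshold Bias-sum threshold; `NULL` means `mean(profiles$S)`.
#' @param sim_threshold Crystal-similarity threshold.
#' @return Character vector of selected target ids, with the thresholds
#'   attached as attributes `S_threshold` and `sim_threshold`.
#' @export
select_unbiased <- function(profiles, S_threshold = NULL, sim_threshold = 0.1) {
  if (anyNA(profiles$sim_cryst_act))
    stop("sim_cryst_act missing for: ",
         paste(profiles$target_id[is.na(profiles$sim_cryst_act)],
               collapse = ", "))
  S_threshold <- S_threshold %||% mean(profiles$S)
  sel <- profiles$target_id[profiles$S < S_threshold &
                              profiles$sim_cryst_act < sim_threshold]
  structure(sel, S_threshold = S_threshold, sim_threshold = sim_threshold)
}

#' Success rates on the full set and the unbiased subset
#'
#' For every program, the count and percentage of targets with
#' BEDROC > threshold, over all targets and over the unbiased subset.
#' Display percentages are rounded to whole numbers; the raw fractions
#' are retained.
#'
#' @param bedrocs Data frame with `target_id` plus one column per program.
#' @param unbiased_targets Character vector of unbiased target ids (must
#'   be a subset of the full target set and non-empty).
#' @param threshold Success threshold.
#' @return A `benchmark_summary`: list with `threshold`, `n_full`,
#'   `n_unbiased`, and a `programs` data frame (`program`, `full_count`,
#'   `full_fraction`, `full_percent`, `unbiased_count`,
#'   `unbiased_fraction`, `unbiased_percent`).
#' @export
success_rate_report <- function(bedrocs, unbiased_targets, threshold = 0.5) {
  full <- bedrocs$target_id
  if (!length(unbiased_targets)) stop("empty unbiased subset")
  if (!all(unbiased_targets %in% full))
    stop("unbiased subset is not a subset of the full target set")
  progs <- setdiff(names(bedrocs), "target_id")
  sub <- bedrocs[bedrocs$target_id %in% unbiased_targets, , drop = FALSE]
  rows <- lapply(progs, function(pg) {
    fc <- sum(success(bedrocs[[pg]], threshold))
    uc <- sum(success(sub[[pg]], threshold))
    data.frame(program = pg,
               full_count = fc, full_fraction = fc / length(full),
               full_percent = round_half_up(100 * fc / length(full)),
               unbiased_count = uc,
               unbiased_fraction = uc / nrow(sub),
               unbiased_percent = round_half_up(100 * uc / nrow(sub)),
               stringsAsFactors = FALSE)
  })
  structure(list(threshold = threshold, n_full = length(full),
                 n_unbiased = nrow(sub),
                 programs = do.call(rbind, rows)),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("<benchmark_summary> BEDROC >", x$threshold, "|", x$n_full,
      "targets, unbiased subset of", x$n_unbiased, "\n")
  p <- x$programs
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-10s full: %d/%d (%d%%)   unbiased: %d/%d (%d%%)\n",
                p$program[i], p$full_count[i], x$n_full, p$full_percent[i],
                p$unbiased_count[i], x$n_unbiased, p$unbiased_percent[i]))
  invisible(x)
}
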