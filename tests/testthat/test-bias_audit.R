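prop_table_row <- function(target, act, dec, property = "MW") {
  data.frame(target_id = target, property = property,
             actives_mean = act, decoys_mean = dec,
             stringsAsFactors = FALSE)
}

test_that("Delta-P normalizes by the collection's actives-mean range", {
  tabs <- rbind(prop_table_row("t1", 6, 6.5),
                prop_table_row("t2", 8, 8),
                prop_table_row("t3", 10, 8))
  dp <- normalized_property_difference(tabs, "MW")
  expect_equal(dp[["t3"]], (10 - 8) / (10 - 6))
  expect_equal(dp[["t2"]], 0)                     # matched groups
  # swapping the group roles negates the numerator only
  swapped <- tabs
  swapped$actives_mean <- tabs$decoys_mean
  swapped$decoys_mean <- tabs$actives_mean
  rng_swapped <- max(swapped$actives_mean) - min(swapped$actives_mean)
  dp_sw <- normalized_property_difference(swapped, "MW")
  expect_equal(dp_sw[["t3"]] * rng_swapped, -(10 - 8))

  flat <- rbind(prop_table_row("t1", 5, 4), prop_table_row("t2", 5, 6))
  expect_error(normalized_property_difference(flat, "MW"), "MW")
  expect_error(normalized_property_difference(tabs[1, ], "MW"), "two targets")
})

test_that("S is the absolute sum of exactly nine Delta-P values", {
  expect_equal(bias_sum(rep(0, 9)), 0)
  dp <- c(0.1, -0.2, 0, 0, 0, 0, 0, 0, 0.3)
  expect_equal(bias_sum(dp), 0.6)
  signs <- sample(c(-1, 1), 9, replace = TRUE)
  expect_equal(bias_sum(dp * signs), 0.6)
  expect_error(bias_sum(dp[-1]), "nine")
  expect_error(bias_sum(c(dp[-1], NA)), "missing")
})

test_that("collection bias statistics use mean and midpoint median", {
  st <- collection_bias_stats(c(0.2, 0.8, 1.4))
  expect_equal(st$mean, 0.8)
  expect_equal(st$median, 0.8)
  one <- collection_bias_stats(0.37)
  expect_equal(one$mean, 0.37)
  expect_equal(one$median, 0.37)
  expect_equal(collection_bias_stats(c(0.2, 0.4, 0.6, 1.0))$median, 0.5)
})

test_that("pearson_with_pvalue matches the printed benchmark p-values", {
  # r = 0.29 at n = 102 -> p = 3e-3 to one significant figure
  make_r <- function(r_target, n = 102) {
    # construct two vectors with exactly the requested correlation
    x <- scale(seq_len(n))[, 1]
    e <- scale(stats::residuals(stats::lm(rnorm(n) ~ x)))[, 1]
    y <- r_target * x + sqrt(1 - r_target^2) * e
    list(x = x, y = y)
  }
  set.seed(2)
  v <- make_r(0.29)
  res <- pearson_with_pvalue(v$x, v$y)
  expect_equal(res$r, 0.29, tolerance = 1e-10)
  expect_equal(signif(res$p, 1), 3e-3)
  expect_equal(res$tier, "questionable")

  v2 <- make_r(0.39)
  res2 <- pearson_with_pvalue(v2$x, v2$y)
  expect_lt(res2$p, 1e-4)
  expect_equal(res2$tier, "significant")
})

test_that("pearson_with_pvalue agrees with the stock correlation test", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    res <- pearson_with_pvalue(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(pearson_with_pvalue(1:5, (1:5) * 2)$r, 1)
  expect_equal(pearson_with_pvalue(1:5, (1:5) * 2)$tier, "significant")
  expect_error(pearson_with_pvalue(1:5, rep(1, 5)), "constant")
  expect_error(pearson_with_pvalue(1:5, c(1, 2, NA, 4, 5)), "missing")
  expect_error(pearson_with_pvalue(1:2, 1:2), "n >= 3")
})

test_that("tier boundaries are closed exactly as specified", {
  expect_equal(correlation_tier(1e-4), "significant")
  expect_equal(correlation_tier(1e-4 + 1e-12), "questionable")
  expect_equal(correlation_tier(1e-2), "questionable")
  expect_equal(correlation_tier(0.010001), "none")
})

test_that("correlation screen aligns targets and supports exclusions", {
  set.seed(30)
  n <- 40
  ids <- sprintf("T%02d", 1:n)
  bed <- data.frame(target_id = ids, progA = runif(n))
  cov <- data.frame(target_id = sample(ids),        # shuffled on purpose
                    mirror = NA_real_, noise = rnorm(n))
  cov$mirror <- bed$progA[match(cov$target_id, bed$target_id)]
  res <- correlation_screen(bed, cov)
  expect_equal(res$r[res$covariate == "mirror"], 1)
  expect_equal(res$n, rep(n, 2))

  res2 <- correlation_screen(bed, cov, exclude_targets = ids[1:5])
  expect_equal(unique(res2$n), n - 5)
  expect_error(correlation_screen(bed, cov[-1, ]), "different target sets")
})

test_that("excluding a constructed confounded family shrinks the correlation", {
  # one "family" of 10 targets carries both high scores and a high
  # covariate; outside it the two are unrelated
  set.seed(31)
  n <- 40
  fam <- rep(c(TRUE, FALSE), c(10, 30))
  cov_val <- rnorm(n) + ifelse(fam, 4, 0)
  score <- runif(n, 0, 0.4) + ifelse(fam, 0.5, 0)
  bed <- data.frame(target_id = sprintf("T%02d", 1:n), prog = score)
  cov <- data.frame(target_id = sprintf("T%02d", 1:n), hbd_dec = cov_val)
  full <- correlation_screen(bed, cov)
  reduced <- correlation_screen(bed, cov,
                                exclude_targets = bed$target_id[fam])
  expect_lt(abs(reduced$r), abs(full$r))
  expect_equal(reduced$n, 30)
})

test_that("unbiased selection applies strict thresholds", {
  prof <- data.frame(target_id = paste0("t", 1:5),
                     S = c(0, 0.86, 0.87, 1.2, 0.5),
                     sim_cryst_act = c(0, 0.05, 0.05, 0.01, 0.1))
  sel <- select_unbiased(prof, S_threshold = 0.87, sim_threshold = 0.1)
  expect_setequal(sel, c("t1", "t2"))          # t3 at S threshold excluded,
                                               # t5 at sim threshold excluded
  # default threshold is the collection's own mean S
  sel2 <- select_unbiased(prof, sim_threshold = 1)
  expect_equal(attr(sel2, "S_threshold"), mean(prof$S))
  # monotone: raising either threshold never shrinks the subset
  for (s_thr in c(0.5, 0.9, 2)) for (sim_thr in c(0.02, 0.12)) {
    lo <- select_unbiased(prof, s_thr, sim_thr)
    hi <- select_unbiased(prof, s_thr + 0.5, sim_thr + 0.1)
    expect_true(all(lo %in% hi))
  }
  prof$sim_cryst_act[2] <- NA
  expect_error(select_unbiased(prof), "t2")
})

test_that("bias profiles assemble Delta-P, S and similarities", {
  set.seed(32)
  tabs <- do.call(rbind, lapply(1:4, function(t)
    gen_property_tables(drift_spec(10 + t, 1, ifelse(
      screen_properties == "PSA", 1, 0),
      n_actives = 300, n_decoys = 300, seed = t),
      target_id = paste0("T", t))$table))
  sims <- data.frame(target_id = paste0("T", 1:4),
                     sim_act_act = c(0.3, 0.1, 0.2, 0.05),
                     sim_cryst_act = c(0.2, 0.01, 0.15, 0.02))
  prof <- bias_profiles(tabs, sims)
  expect_named(prof, c("target_id", paste0("dP_", screen_properties),
                       "S", "sim_act_act", "sim_cryst_act"))
  expect_equal(prof$S,
               rowSums(abs(prof[paste0("dP_", screen_properties)])))
  expect_true(all(prof$S > 0))
  expect_equal(prof$sim_cryst_act, sims$sim_cryst_act)
})

test_that("injected drift dominates the recovered Delta-P", {
  reps <- 30
  wins <- vapply(1:reps, function(rep) {
    tabs <- do.call(rbind, lapply(1:5, function(t)
      gen_property_tables(drift_spec(
        20 + 4 * t, 2, ifelse(screen_properties == "HBD", 2, 0),
        n_actives = 1000, n_decoys = 1000, seed = 500 * rep + t),
        target_id = paste0("T", t))$table))
    dp <- delta_p_matrix(tabs)
    m <- colMeans(abs(dp[-1]))
    names(which.max(m)) == "dP_HBD"
  }, NA)
  expect_gte(mean(wins), 0.95)
})

test_that("success rates reproduce the printed percentage arithmetic", {
  ids <- sprintf("T%03d", 1:102)
  scores <- rep(0.2, 102)
  scores[1:30] <- 0.9                      # 30 successes of 102
  bed <- data.frame(target_id = ids, glide_like = scores)
  sub <- ids[c(1:5, 60:101)]               # 47 targets, 5 successes
  rep_ <- success_rate_report(bed, sub)
  expect_equal(rep_$programs$full_count, 30)
  expect_equal(rep_$programs$full_percent, 29)
  expect_equal(rep_$n_unbiased, 47)
  expect_equal(rep_$programs$unbiased_count, 5)
  expect_equal(rep_$programs$unbiased_percent, 11)

  all_hit <- data.frame(target_id = ids, p = rep(1.0, 102))
  rep2 <- success_rate_report(all_hit, ids[1:10])
  expect_equal(rep2$programs$full_percent, 100)
  expect_equal(rep2$programs$unbiased_percent, 100)

  expect_error(success_rate_report(bed, character(0)), "empty")
  expect_error(success_rate_report(bed, c("T001", "nope")), "subset")
})

test_that("bias-coupled collections lose success rate on the unbiased subset", {
  drops <- vapply(1:20, function(rep) {
    data <- gen_benchmark_collection(n_targets = 16, seed = 7000 + rep,
                                     n_prop_actives = 150L,
                                     n_prop_decoys = 600L)
    bed <- data.frame(target_id = names(data$screens[[1]]))
    for (pg in names(data$screens))
      bed[[pg]] <- vapply(data$screens[[pg]], function(s)
        suppressWarnings(bedroc(s, 80.5)), 0)
    prof <- bias_profiles(data$property_tables, data$similarities)
    sel <- select_unbiased(prof)
    if (!length(sel)) return(TRUE)           # nothing survives: trivially lower
    rep_ <- success_rate_report(bed, sel)
    all(rep_$programs$unbiased_fraction <= rep_$programs$full_fraction)
  }, NA)
  expect_gte(mean(drops), 0.95)
})
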