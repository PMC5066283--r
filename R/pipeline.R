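# Per-property base scales used by the synthetic benchmark collection:
# plausible medians for drug-like screening libraries (MW in g/mol, PSA in
# A^2, counts for the rest), the spread of per-target library means, and
# the within-library standard deviation.
.property_scales <- data.frame(
  property = c("MW", "AlogP", "Estate", "PSA", "HBA", "HBD", "RC", "RB", "EC"),
  base   = c(350, 3.0, 10, 80, 5, 2, 3, 6, 2),
  spread = c(60, 0.8, 2.5, 20, 1.2, 0.7, 0.8, 1.5, 0.6),
  sigma  = c(80, 1.2, 3.0, 30, 2.0, 1.2, 1.1, 2.5, 1.0),
  stringsAsFactors = FALSE)

#' Generate a coupled synthetic benchmark collection
#'
#' Emulates a multi-target screening benchmark in which measured program
#' performance is driven by chemical-library construction bias: for each
#' target, a bias level is drawn; biased targets receive a property drift
#' (on PSA, HBD and EC) and a tighter fingerprint family, and each
#' program's early-enrichment rate lambda grows with the bias it is
#' "sensitive" to. The first program couples to crystal-ligand similarity,
#' the others to the property drift, so that removing biased targets
#' lowers every program's success rate — the ground truth the bias audit
#' should recover.
#'
#' @param n_targets Number of targets.
#' @param n_compounds,n_actives Screen shape per target (default 510/10,
#'   i.e. 50 decoys per active).
#' @param programs Character vector of program names.
#' @param bias_fraction Fraction of targets built with biased libraries.
#' @param lambda_base Baseline enrichment rate for unbiased targets.
#' @param coupling Additional lambda per unit of injected bias.
#' @param n_prop_actives,n_prop_decoys Library sizes for the property
#'   records.
#' @param n_fp_actives Fingerprints per family.
#' @param seed Master seed; all per-target streams derive from it.
#' @return List: `screens` (per program: named list of ranked screens),
#'   `property_tables` (long data frame), `similarities`, `cavities`,
#'   and `truth` (per-target injected bias levels and lambdas).
#' @export
gen_benchmark_collection <- function(n_targets = 20L, n_compounds = 510L,
                                     n_actives = 10L,
                                     programs = c("dockA", "dockB"),
                                     bias_fraction = 0.5,
                                     lambda_base = 1.5, coupling = 25,
                                     n_prop_actives = 200L,
                                     n_prop_decoys = 2000L,
                                     n_fp_actives = 12L, seed = 1L) {
  ids <- sprintf("T%03d", seq_len(n_targets))
  drifted <- c("PSA", "HBD", "EC")
  sc <- .property_scales
  truth <- with_seed(child_seed(seed, 0L), data.frame(
    target_id = ids,
    biased = runif(n_targets) < bias_fraction,
    bias_level = runif(n_targets, 0.6, 1.4),
    stringsAsFactors = FALSE))
  truth$bias_level[!truth$biased] <- 0

  tables <- list(); sims <- list(); cavities <- list()
  screens <- lapply(programs, function(p) list())
  names(screens) <- programs
  for (i in seq_len(n_targets)) {
    s_i <- child_seed(seed, i)
    base_i <- with_seed(child_seed(s_i, 1L),
                        rnorm(9, sc$base, sc$spread))
    drift_i <- ifelse(sc$property %in% drifted,
                      truth$bias_level[i] * sc$sigma, 0)
    pt <- gen_property_tables(
      drift_spec(base_i, sc$sigma, drift_i, n_prop_actives, n_prop_decoys,
                 seed = child_seed(s_i, 2L)),
      target_id = ids[i])
    tables[[i]] <- pt$table
    # sparse bit patterns: biased families share a common core (high
    # Tanimoto, like congeneric actives), unbiased ones are independent
    fam <- gen_fingerprint_family(family_spec(
      n_fp_actives, n_bits = 512L,
      core_density = if (truth$biased[i]) 0.025 else 0,
      flip_rate = if (truth$biased[i]) 0.03 else 0.03,
      include_crystal = TRUE, seed = child_seed(s_i, 3L)))
    sims[[i]] <- data.frame(
      target_id = ids[i],
      sim_act_act = mean_pairwise_similarity(fam$actives),
      sim_cryst_act = mean_similarity_to_reference(fam$actives, fam$crystal),
      stringsAsFactors = FALSE)
    cf <- with_seed(child_seed(s_i, 4L), runif(1, 0.5, 0.9))
    n_surf <- with_seed(child_seed(s_i, 7L), sample(80:180, 1))
    cav <- gen_cavity(n_surface = n_surf, n_far = 60L, carbon_fraction = cf,
                      seed = child_seed(s_i, 5L))
    cav$exposure <- with_seed(child_seed(s_i, 6L),
                              min(1, max(0, 1 - cf + rnorm(1, 0, 0.08))))
    cavities[[ids[i]]] <- cav
    for (k in seq_along(programs)) {
      sim_bias <- max(0, sims[[i]]$sim_cryst_act - 0.1) * 10
      lam <- lambda_base + coupling *
        (if (k == 1) 0.3 * truth$bias_level[i] + 0.7 * sim_bias
         else truth$bias_level[i]) +
        with_seed(child_seed(s_i, 10L + k), abs(rnorm(1, 0, 2)))
      screens[[k]][[ids[i]]] <- gen_ranked_screen(
        screen_spec(n_compounds, n_actives, lam,
                    seed = child_seed(s_i, 20L + k)),
        target_id = ids[i])
    }
  }
  list(screens = screens,
       property_tables = do.call(rbind, tables),
       similarities = do.call(rbind, sims),
       cavities = cavities,
       truth = truth)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synthetic benchmark audit.
#'
#' @param out_dir Output directory (`NULL` = nothing written).
#' @param n_targets,programs,bias_fraction Passed to
#'   [gen_benchmark_collection()].
#' @param alphas BEDROC alphas; the first is the primary one used for
#'   success rates and correlations.
#' @param percentiles Docking-enrichment percentiles (fractions).
#' @param success_threshold BEDROC success cut (strict >).
#' @param S_threshold Bias-sum cut (`NULL` = collection mean).
#' @param sim_threshold Crystal-similarity cut.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = NULL, n_targets = 20L,
                            programs = c("dockA", "dockB"),
                            bias_fraction = 0.5,
                            alphas = bedroc_alphas[c("0.02", "0.005", "0.08")],
                            percentiles = c(0.005, 0.02, 0.08),
                            success_threshold = 0.5, S_threshold = NULL,
                            sim_threshold = 0.1, seed = 1L) {
  stopifnot(all(alphas > 0), all(percentiles > 0 & percentiles <= 1))
  structure(list(out_dir = out_dir, n_targets = as.integer(n_targets),
                 programs = programs, bias_fraction = bias_fraction,
                 alphas = alphas, percentiles = percentiles,
                 success_threshold = success_threshold,
                 S_threshold = S_threshold, sim_threshold = sim_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic benchmark audit
#'
#' Generates a coupled benchmark collection, computes per-target metrics
#' for every program, builds bias profiles and the tiered correlation
#' screen, selects the unbiased subset and reports success rates before
#' and after bias removal. Deterministic under a fixed config; when
#' `out_dir` is set, every intermediate table is written as CSV together
#' with a JSON manifest recording the configuration and its hash.
#'
#' @param config A [pipeline_config()].
#' @return List: `metrics` (per program), `bedrocs`, `profiles`,
#'   `correlations`, `cavity_table`, `unbiased`, `net_balance`,
#'   `net_balance_success`, `summary` and `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- gen_benchmark_collection(
    n_targets = config$n_targets, programs = config$programs,
    bias_fraction = config$bias_fraction, seed = config$seed)
  primary <- config$alphas[[1]]
  metrics <- lapply(data$screens, metrics_table,
                    alphas = config$alphas, percentiles = config$percentiles)
  bed_col <- paste0("BEDROC_", unname(primary))
  bedrocs <- data.frame(target_id = metrics[[1]]$target_id,
                        stringsAsFactors = FALSE)
  for (pg in config$programs) bedrocs[[pg]] <- metrics[[pg]][[bed_col]]
  profiles <- bias_profiles(data$property_tables, data$similarities)
  cav <- cavity_table(data$cavities)
  act_means <- stats::reshape(
    data$property_tables[c("target_id", "property", "actives_mean")],
    idvar = "target_id", timevar = "property", direction = "wide")
  names(act_means) <- sub("^actives_mean\\.", "act_", names(act_means))
  dec_means <- stats::reshape(
    data$property_tables[c("target_id", "property", "decoys_mean")],
    idvar = "target_id", timevar = "property", direction = "wide")
  names(dec_means) <- sub("^decoys_mean\\.", "dec_", names(dec_means))
  covariates <- Reduce(function(a, b) merge(a, b, by = "target_id"),
                       list(cav[c("target_id", "FCA", "one_minus_FCA",
                                  "surface_atom_count", "exposure")],
                            act_means, dec_means,
                            data$similarities))
  correlations <- correlation_screen(bedrocs, covariates)
  scores <- lapply(config$programs, function(pg)
    setNames(bedrocs[[pg]], bedrocs$target_id))
  names(scores) <- config$programs
  unbiased <- select_unbiased(profiles, S_threshold = config$S_threshold,
                              sim_threshold = config$sim_threshold)
  summary <- success_rate_report(bedrocs, unbiased,
                                 threshold = config$success_threshold)
  result <- list(metrics = metrics, bedrocs = bedrocs, profiles = profiles,
                 correlations = correlations, cavity_table = cav,
                 unbiased = unbiased,
                 net_balance = net_balance_matrix(scores),
                 net_balance_success = net_balance_matrix(
                   scores, restrict_to_success = TRUE,
                   threshold = config$success_threshold),
                 summary = summary, truth = data$truth)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config, data)
  result
}

write_pipeline_outputs <- function(result, config, data) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  for (pg in config$programs) {
    write_ranked_screens(data$screens[[pg]],
                         out(paste0("screens_", pg, ".csv")))
    write.csv(result$metrics[[pg]], out(paste0("metrics_", pg, ".csv")),
              row.names = FALSE)
  }
  write.csv(result$bedrocs, out("bedrocs.csv"), row.names = FALSE)
  write.csv(result$profiles, out("bias_profiles.csv"), row.names = FALSE)
  write.csv(result$correlations, out("correlations.csv"), row.names = FALSE)
  write.csv(result$cavity_table, out("cavity_table.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$net_balance), out("net_balance.csv"))
  cfg <- unclass(config)
  cfg$alphas <- unname(cfg$alphas)
  manifest <- list(
    package = "vsbench",
    version = as.character(utils::packageVersion("vsbench")),
    config = cfg,
    config_hash = {
      h <- fnv1a_32(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
                                     digits = NA))
      sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
    },
    thresholds = list(success = config$success_threshold,
                      S = attr(result$unbiased, "S_threshold"),
                      sim = attr(result$unbiased, "sim_threshold")),
    fingerprint_dialect = "synthetic-core/1;bits=512",
    outputs = list.files(config$out_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  jsonlite::write_json(
    list(threshold = result$summary$threshold,
         n_full = result$summary$n_full,
         n_unbiased = result$summary$n_unbiased,
         programs = result$summary$programs),
    out("summary.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Render a human-readable benchmark report
#'
#' Markdown summary of full-set versus unbiased-subset success rates and
#' the pairwise net-balance matrices. Regeneration from the same result
#' is idempotent.
#'
#' @param result Output of [run_pipeline()], or any list with a
#'   `summary` ([success_rate_report()]) and optional `net_balance`
#'   matrices.
#' @param path Optional file to write the report to.
#' @return Character vector of markdown lines, invisibly.
#' @export
render_report <- function(result, path = NULL) {
  s <- result$summary
  lines <- c("# Virtual-screening benchmark audit", "")
  if (!is.null(s)) {
    lines <- c(lines,
      sprintf("Success = BEDROC > %s. Full set: %d targets; unbiased subset: %d.",
              format(s$threshold), s$n_full, s$n_unbiased), "",
      "| program | full | full % | unbiased | unbiased % |",
      "|---|---|---|---|---|")
    p <- s$programs
    for (i in seq_len(NROW(p)))
      lines <- c(lines, sprintf("| %s | %d/%d | %d%% | %d/%d | %d%% |",
                                p$program[i], p$full_count[i], s$n_full,
                                p$full_percent[i], p$unbiased_count[i],
                                s$n_unbiased, p$unbiased_percent[i]))
    lines <- c(lines, "")
  }
  for (nm in c("net_balance", "net_balance_success")) {
    m <- result[[nm]]
    if (is.null(m)) next
    lines <- c(lines,
               paste0("## ", if (nm == "net_balance") "Net balance (all targets)"
                      else "Net balance (successes only)"), "",
               paste0("| a \\\\ b | ", paste(colnames(m), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(m) + 1), collapse = "|"), "|"))
    for (i in seq_len(nrow(m)))
      lines <- c(lines, paste0("| ", rownames(m)[i], " | ",
                               paste(sprintf("%+.3f", m[i, ]), collapse = " | "),
                               " |"))
    lines <- c(lines, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
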