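#' Specification of a synthetic ranked screen
#'
#' Describes one target's simulated screening outcome: library size, number
#' of actives and an early-enrichment rate `enrichment_rate` (lambda). The
#' normalized ranks of the actives follow a truncated-exponential law with
#' rate lambda, mirroring BEDROC's exponential weighting: lambda = 0 is the
#' uniform null (a program ranking at random), large lambda pushes all
#' actives to the very top. Defaults follow the benchmark-library
#' convention of 50 decoys per active (about 2% actives).
#'
#' @param n_compounds Library size N.
#' @param n_actives Number of actives n (1 <= n < N).
#' @param enrichment_rate Nonnegative rate lambda.
#' @param seed Integer RNG seed.
#' @return A `screen_spec` object.
#' @export
screen_spec <- function(n_compounds, n_actives = max(1L, round(n_compounds / 51)),
                        enrichment_rate = 0, seed = 1L) {
  if (n_compounds < 2L || n_actives < 1L)
    stop("need n_compounds >= 2 and n_actives >= 1")
  if (n_actives > n_compounds - 1L)
    stop("invalid spec: n_actives must satisfy n_actives < n_compounds")
  if (enrichment_rate < 0) stop("enrichment_rate must be >= 0")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_actives = as.integer(n_actives),
                 enrichment_rate = enrichment_rate,
                 seed = as.integer(seed)),
            class = "screen_spec")
}

#' Generate a synthetic ranked screen
#'
#' Draws the n active ranks without replacement from the discretized
#' truncated-exponential law with weight exp(-lambda * k / N) on rank k
#' (Gumbel top-n weighted sampling, numerically stable for any lambda).
#' Decoys fill the remaining ranks; scores are a strictly decreasing
#' sequence consistent with the ranks. Deterministic under a fixed seed.
#'
#' @param spec A [screen_spec()].
#' @param target_id Target identifier for the generated screen.
#' @return A [ranked_screen()].
#' @export
gen_ranked_screen <- function(spec, target_id = "T1") {
  stopifnot(inherits(spec, "screen_spec"))
  N <- spec$n_compounds; n <- spec$n_actives
  with_seed(spec$seed, {
    # Efraimidis-Spirakis: top-n of log w_k + Gumbel noise, log w_k = -lambda k/N
    keys <- -spec$enrichment_rate * seq_len(N) / N -
      log(-log(runif(N)))
    act <- sort(order(keys, decreasing = TRUE)[seq_len(n)])
    gaps <- abs(rnorm(N, mean = 1, sd = 0.2)) + 1e-6
    scores <- rev(cumsum(rev(gaps)))          # strictly decreasing, rank 1 highest
    ranked_screen(target_id, data.frame(
      compound_id = sprintf("%s_c%05d", target_id, seq_len(N)),
      score = scores,
      is_active = seq_len(N) %in% act,
      stringsAsFactors = FALSE))
  })
}

#' Generate a collection of synthetic screens
#'
#' @param specs Named list of [screen_spec()] objects; names are the
#'   target ids and must be unique.
#' @return Named list of [ranked_screen()] objects.
#' @export
gen_screen_collection <- function(specs) {
  if (!length(specs)) stop("empty spec list")
  ids <- names(specs)
  if (is.null(ids) || any(ids == "")) stop("specs must be named by target id")
  if (anyDuplicated(ids))
    stop("duplicate target ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- lapply(ids, function(id) gen_ranked_screen(specs[[id]], id))
  names(out) <- ids
  out
}

#' Helper: per-target screen specs with derived seeds
#'
#' Builds `n_targets` identical specs whose RNG streams are derived from a
#' master seed, so adding targets never perturbs earlier ones.
#'
#' @inheritParams screen_spec
#' @param n_targets Number of targets.
#' @param enrichment_rate Scalar or length-`n_targets` vector of lambdas.
#' @param prefix Target-id prefix.
#' @return Named list of [screen_spec()] objects.
#' @export
make_screen_specs <- function(n_targets, n_compounds = 510L,
                              n_actives = 10L, enrichment_rate = 0,
                              seed = 1L, prefix = "T") {
  lam <- rep_len(enrichment_rate, n_targets)
  specs <- lapply(seq_len(n_targets), function(i)
    screen_spec(n_compounds, n_actives, lam[i], child_seed(seed, i)))
  names(specs) <- sprintf("%s%03d", prefix, seq_len(n_targets))
  specs
}

#' Specification of a drifted property table
#'
#' Describes one target's chemical library in property space: for each of
#' the nine properties, actives are drawn from Normal(base + drift, sd)
#' and decoys from Normal(base, sd). A positive drift reproduces the
#' systematic actives-above-decoys shift seen in benchmark libraries.
#'
#' @param base_mean,base_sd,drift Numeric vectors over the nine
#'   [screen_properties] (recycled if scalar). All `base_sd` must be > 0.
#' @param n_actives,n_decoys Group sizes.
#' @param seed Integer RNG seed.
#' @param correlation Optional 9x9 positive-definite correlation matrix for
#'   the property noise; default identity (independent properties).
#' @return A `drift_spec` object.
#' @export
drift_spec <- function(base_mean, base_sd, drift = 0,
                       n_actives = 200L, n_decoys = 10000L, seed = 1L,
                       correlation = NULL) {
  p <- length(screen_properties)
  base_mean <- setNames(rep_len(base_mean, p), screen_properties)
  base_sd <- setNames(rep_len(base_sd, p), screen_properties)
  drift <- setNames(rep_len(drift, p), screen_properties)
  if (any(base_sd <= 0)) stop("standard deviations must be > 0")
  if (!is.null(correlation)) {
    stopifnot(is.matrix(correlation), dim(correlation) == c(p, p))
  }
  structure(list(base_mean = base_mean, base_sd = base_sd, drift = drift,
                 n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 seed = as.integer(seed), correlation = correlation),
            class = "drift_spec")
}

#' Generate per-compound property records and their summary table
#'
#' @param spec A [drift_spec()].
#' @param target_id Target identifier.
#' @return List with `records` (per-compound data frame: `compound_id`,
#'   `group`, one column per property) and `table` (long property table:
#'   `target_id`, `property`, `actives_mean`, `decoys_mean` holding the
#'   realized group means).
#' @export
gen_property_tables <- function(spec, target_id = "T1") {
  stopifnot(inherits(spec, "drift_spec"))
  p <- length(screen_properties)
  with_seed(spec$seed, {
    draw <- function(nrow, mean_vec) {
      z <- matrix(rnorm(nrow * p), nrow, p)
      if (!is.null(spec$correlation)) z <- z %*% chol(spec$correlation)
      m <- sweep(z, 2, spec$base_sd, `*`)
      m <- sweep(m, 2, mean_vec, `+`)
      colnames(m) <- screen_properties
      m
    }
    act <- draw(spec$n_actives, spec$base_mean + spec$drift)
    dec <- draw(spec$n_decoys, spec$base_mean)
    records <- data.frame(
      compound_id = c(sprintf("%s_a%05d", target_id, seq_len(spec$n_actives)),
                      sprintf("%s_d%05d", target_id, seq_len(spec$n_decoys))),
      group = rep(c("active", "decoy"), c(spec$n_actives, spec$n_decoys)),
      rbind(act, dec), stringsAsFactors = FALSE)
    table <- data.frame(target_id = target_id, property = screen_properties,
                        actives_mean = colMeans(act),
                        decoys_mean = colMeans(dec),
                        stringsAsFactors = FALSE, row.names = NULL)
    list(records = records, table = table)
  })
}

#' Specification of a synthetic fingerprint family
#'
#' A family of actives is modelled as a shared random core pattern (each
#' bit set with probability `core_density`) XORed with independent per-bit
#' noise at `flip_rate`; the optional crystal-ligand fingerprint is drawn
#' from the same core. `flip_rate = 0` gives identical fingerprints
#' (pairwise Tanimoto 1); `flip_rate = 0.5` destroys all family structure.
#'
#' @param n_actives Number of fingerprints in the family.
#' @param n_bits Fingerprint length (multiple of 8).
#' @param core_density Fraction of core bits set, in \[0, 1\].
#' @param flip_rate Per-bit noise probability, in \[0, 1\].
#' @param include_crystal Also generate a crystal-ligand fingerprint.
#' @param seed Integer RNG seed.
#' @return A `family_spec` object.
#' @export
family_spec <- function(n_actives, n_bits = 1024L, core_density = 0.2,
                        flip_rate = 0.1, include_crystal = FALSE, seed = 1L) {
  if (core_density < 0 || core_density > 1 || flip_rate < 0 || flip_rate > 1)
    stop("core_density and flip_rate must lie in [0, 1]")
  if (n_bits < 8L || n_bits %% 8L != 0L)
    stop("n_bits must be a positive multiple of 8")
  structure(list(n_actives = as.integer(n_actives),
                 n_bits = as.integer(n_bits),
                 core_density = core_density, flip_rate = flip_rate,
                 include_crystal = isTRUE(include_crystal),
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a synthetic fingerprint family
#'
#' @param spec A [family_spec()].
#' @return List with `actives` (list of [fingerprint()] objects) and
#'   `crystal` (a fingerprint or `NULL`).
#' @export
gen_fingerprint_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    core <- runif(spec$n_bits) < spec$core_density
    dialect <- sprintf("synthetic-core/1;bits=%d", spec$n_bits)
    make_fp <- function() {
      noise <- runif(spec$n_bits) < spec$flip_rate
      fingerprint(xor(core, noise), dialect = dialect)
    }
    actives <- lapply(seq_len(spec$n_actives), function(i) make_fp())
    crystal <- if (spec$include_crystal) make_fp() else NULL
    list(actives = actives, crystal = crystal)
  })
}

#' Generate a synthetic binding-site cavity
#'
#' Builds a probe-point cloud (the protomol stand-in) and places
#' `n_surface` heavy atoms strictly within `cutoff` of at least one probe
#' and `n_far` atoms strictly farther than `cutoff` from every probe.
#' Surface atoms are carbon with probability `carbon_fraction`, so the
#' expected hydrophobicity (FCA) of the generated cavity equals
#' `carbon_fraction`.
#'
#' @param n_surface,n_far Atom counts (>= 0).
#' @param carbon_fraction Probability a surface atom is carbon, in \[0, 1\].
#' @param seed Integer RNG seed.
#' @param cutoff Contact cutoff in Angstroms (default 4).
#' @param n_probes Number of probe points.
#' @return A [cavity_model()].
#' @export
gen_cavity <- function(n_surface, n_far = 0L, carbon_fraction = 0.7,
                       seed = 1L, cutoff = 4, n_probes = 25L) {
  if (n_surface < 0L || n_far < 0L) stop("counts must be >= 0")
  if (carbon_fraction < 0 || carbon_fraction > 1)
    stop("carbon_fraction must lie in [0, 1]")
  with_seed(seed, {
    probes <- matrix(rnorm(3 * n_probes, sd = 3), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
    centroid <- colMeans(probes)
    r_max <- max(sqrt(rowSums(sweep(probes, 2, centroid)^2)))
    rand_dir <- function(k) {
      v <- matrix(rnorm(3 * k), ncol = 3)
      v / sqrt(rowSums(v^2))
    }
    surf <- if (n_surface > 0) {
      anchor <- probes[sample.int(n_probes, n_surface, replace = TRUE), ,
                       drop = FALSE]
      anchor + rand_dir(n_surface) * runif(n_surface, 0, cutoff * 0.999)
    } else matrix(numeric(0), ncol = 3)
    far <- if (n_far > 0) {
      centroid_m <- matrix(centroid, n_far, 3, byrow = TRUE)
      centroid_m + rand_dir(n_far) *
        (r_max + cutoff + runif(n_far, 0.5, 8))
    } else matrix(numeric(0), ncol = 3)
    elements <- c(
      ifelse(runif(n_surface) < carbon_fraction, "C",
             sample(c("N", "O", "S"), n_surface, replace = TRUE)),
      sample(c("C", "N", "O", "S"), n_far, replace = TRUE))
    coords <- rbind(surf, far)
    atoms <- data.frame(id = seq_len(n_surface + n_far),
                        element = elements,
                        x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        stringsAsFactors = FALSE)
    cavity_model(atoms, probes, cutoff = cutoff)
  })
}
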