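## Synthetic 450K-like data generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## bimodal beta-value background (most probe means below 0.2 or above 0.8),
## two probe chemistries related by a quadratic, additive logit-scale batch
## effects, strong case hypomethylation at designated "IFN-like" probes, and
## compositional probes whose bulk values are fraction-weighted sums of
## cell-subtype profiles. A truth record stores every planted effect so
## recovery can be tested.

#' Specify a cell-subtype mixture
#'
#' Holds subtype fractions per group and per-subtype mean methylation
#' profiles at a set of compositional probes. Profiles are probes-by-subtype
#' matrices; `control_profiles` and `case_profiles` may differ (intrinsic
#' within-subtype effects) and the fraction vectors may differ
#' (compositional effects).
#'
#' @param subtype_names Character vector of subtype labels.
#' @param control_fractions,case_fractions Non-negative vectors summing to 1
#'   (within 1e-9), one entry per subtype.
#' @param control_profiles,case_profiles Numeric matrices (probes x subtypes)
#'   of mean methylation in \[0, 1\]; rownames are probe IDs.
#' @return A `mixture_spec` object.
#' @export
mixture_spec <- function(subtype_names, control_fractions, case_fractions,
                         control_profiles, case_profiles = control_profiles) {
  k <- length(subtype_names)
  control_profiles <- as.matrix(control_profiles)
  case_profiles <- as.matrix(case_profiles)
  if (length(control_fractions) != k || length(case_fractions) != k ||
      ncol(control_profiles) != k || ncol(case_profiles) != k) {
    stop_invalid("fractions and profile columns must match the number of subtypes")
  }
  for (f in list(control_fractions, case_fractions)) {
    if (any(f < 0)) stop_invalid("subtype fractions must be non-negative")
    if (abs(sum(f) - 1) > 1e-9) stop_invalid("subtype fractions must sum to 1 (within 1e-9)")
  }
  for (p in list(control_profiles, case_profiles)) {
    if (any(p < 0 | p > 1)) stop_invalid("subtype profiles must lie in [0, 1]")
  }
  if (!identical(dim(control_profiles), dim(case_profiles))) {
    stop_invalid("control and case profiles must have identical dimensions")
  }
  colnames(control_profiles) <- colnames(case_profiles) <- subtype_names
  structure(
    list(subtype_names = subtype_names,
         control_fractions = setNames(as.numeric(control_fractions), subtype_names),
         case_fractions = setNames(as.numeric(case_fractions), subtype_names),
         control_profiles = control_profiles,
         case_profiles = case_profiles),
    class = "mixture_spec")
}

# default CD4+ subtype mixture: a shift of the naive/memory balance in cases
# with subtype-specific (marker-like) methylation patterns at each
# compositional probe; the marker subtype is more often the one expanding in
# cases so mild compositional effects skew toward hypermethylation.
default_mixture <- function(n_probes, marker_high = c(0.6, 0.9),
                            marker_low = c(0.1, 0.4),
                            marker_weights = c(naive = 0.2, memory = 0.7, regulatory = 0.1)) {
  subtypes <- c("naive", "memory", "regulatory")
  if (n_probes == 0) {
    prof <- matrix(numeric(0), nrow = 0, ncol = 3,
                   dimnames = list(NULL, subtypes))
    return(mixture_spec(subtypes, c(0.45, 0.35, 0.20), c(0.33, 0.47, 0.20),
                        prof, prof))
  }
  marker <- sample(subtypes, n_probes, replace = TRUE,
                   prob = marker_weights[subtypes])
  hi <- runif(n_probes, marker_high[1], marker_high[2])
  lo <- runif(n_probes, marker_low[1], marker_low[2])
  prof <- matrix(lo, nrow = n_probes, ncol = 3,
                 dimnames = list(NULL, subtypes))
  for (k in subtypes) prof[marker == k, k] <- hi[marker == k]
  attr(prof, "marker_subtype") <- marker
  mixture_spec(subtypes, c(0.45, 0.35, 0.20), c(0.33, 0.47, 0.20), prof, prof)
}

#' Configure a synthetic 450K-like dataset
#'
#' Defaults mirror the cohort structure the pipeline is designed for: 49
#' cases and 58 controls on 12-sample arrays (batches), ~72% Infinium II
#' probes, strong case hypomethylation (10-40 percentage points) at a small
#' set of IFN-like probes, and mild compositional effects generated from a
#' CD4+ subtype mixture. Probe counts are desk-scale.
#'
#' @param n_probes Total probe count.
#' @param n_cases,n_controls Group sizes.
#' @param fraction_chemII Proportion of Infinium II probes among non-pair
#'   probes.
#' @param n_batches Number of batches; samples are assigned case/control
#'   balanced in chunks of up to 12.
#' @param batch_shift_sd SD of the additive logit-scale batch shift.
#' @param n_ifn_probes Number of IFN-like strong-effect probes.
#' @param ifn_delta_range Range of case hypomethylation magnitudes
#'   (proportion units) at IFN-like probes.
#' @param n_compositional_probes Number of mixture-driven probes.
#' @param mixture Optional `mixture_spec` with `n_compositional_probes`
#'   profile rows; a default CD4+ mixture is generated when `NULL`.
#' @param n_chemistry_pairs Number of Infinium I/II probe pairs placed <50 bp
#'   apart with shared latent methylation (supports the chemistry fit).
#' @param n_x_probes Probes placed on chromosome X (sex-dependent shift).
#' @param n_blacklist,n_snp_flagged Background probes flagged in the
#'   manifest.
#' @param noise_sd Within-group truncated-normal beta noise SD.
#' @param detection_fail_rate Fraction of cells given detection p > 0.01.
#' @param seed Integer seed; required (the generator refuses to run
#'   unseeded).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_probes = 2000,
                              n_cases = 49, n_controls = 58,
                              fraction_chemII = 0.72,
                              n_batches = NULL,
                              batch_shift_sd = 0.3,
                              n_ifn_probes = 30,
                              ifn_delta_range = c(0.10, 0.40),
                              n_compositional_probes = 200,
                              mixture = NULL,
                              n_chemistry_pairs = 100,
                              n_x_probes = 0,
                              n_blacklist = 0,
                              n_snp_flagged = 0,
                              noise_sd = 0.05,
                              detection_fail_rate = 0.002,
                              seed = NULL) {
  n_samples <- n_cases + n_controls
  if (is.null(n_batches)) n_batches <- max(1L, ceiling(n_samples / 12))
  cfg <- list(n_probes = n_probes, n_cases = n_cases, n_controls = n_controls,
              fraction_chemII = fraction_chemII, n_batches = n_batches,
              batch_shift_sd = batch_shift_sd, n_ifn_probes = n_ifn_probes,
              ifn_delta_range = ifn_delta_range,
              n_compositional_probes = n_compositional_probes,
              mixture = mixture, n_chemistry_pairs = n_chemistry_pairs,
              n_x_probes = n_x_probes, n_blacklist = n_blacklist,
              n_snp_flagged = n_snp_flagged, noise_sd = noise_sd,
              detection_fail_rate = detection_fail_rate, seed = seed)
  counts <- c("n_probes", "n_cases", "n_controls", "n_batches", "n_ifn_probes",
              "n_compositional_probes", "n_chemistry_pairs", "n_x_probes",
              "n_blacklist", "n_snp_flagged")
  for (nm in counts) {
    if (cfg[[nm]] < 0) stop_invalid(sprintf("`%s` must be >= 0", nm))
  }
  if (fraction_chemII < 0 || fraction_chemII > 1) {
    stop_invalid("`fraction_chemII` must lie in [0, 1]")
  }
  if (any(ifn_delta_range < 0 | ifn_delta_range > 1)) {
    stop_invalid("`ifn_delta_range` must lie in [0, 1]")
  }
  n_special <- n_ifn_probes + n_compositional_probes + 2 * n_chemistry_pairs +
    n_x_probes
  if (n_special > n_probes) {
    stop_invalid(sprintf(
      "infeasible config: %d special probes requested but only %d probes total",
      n_special, n_probes))
  }
  structure(cfg, class = "simulation_config")
}

# bimodal background probe means per the array's beta-value distribution:
# low and high modes plus a small intermediate component
draw_background_means <- function(n) {
  comp <- sample(c("low", "high", "mid"), n, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  m <- numeric(n)
  m[comp == "low"] <- rbeta(sum(comp == "low"), 1, 18)
  m[comp == "high"] <- rbeta(sum(comp == "high"), 18, 1)
  m[comp == "mid"] <- runif(sum(comp == "mid"), 0.2, 0.8)
  m
}

#' Simulate a 450K-like dataset
#'
#' Generates the beta matrix, detection p-value matrix, probe manifest and
#' sample sheet for a case/control methylation study, plus a truth record of
#' every planted effect. Background probe means are bimodal; IFN-like probes
#' are hypomethylated in cases; compositional probe values are
#' fraction-weighted sums of subtype profiles; batch shifts act additively on
#' the logit scale; Infinium II probes are distorted by the inverse of the
#' chemistry-harmonization quadratic; a small fraction of detection p-values
#' exceeds 0.01.
#'
#' @param config A [simulation_config()].
#' @return List with elements `beta`, `detection`, `manifest`, `samples`,
#'   `truth`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$seed)) stop_invalid("simulate_dataset() requires `seed` in the config")
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_probes
  n_samp <- cfg$n_cases + cfg$n_controls
  probe_ids <- sprintf("cg%07d", seq_len(n))

  ## --- sample sheet: cases/controls interleaved so batches are balanced ---
  disease <- character(0)
  nc <- cfg$n_cases; nk <- cfg$n_controls
  while (nc + nk > 0) {
    if (nc >= nk && nc > 0) { disease <- c(disease, "case"); nc <- nc - 1 }
    else { disease <- c(disease, "control"); nk <- nk - 1 }
  }
  samples <- tibble(
    sample_id = sprintf("S%03d", seq_len(n_samp)),
    disease = disease,
    activity = ifelse(disease == "case",
                      rep_len(c("flare", "quiescent"), n_samp), "none"),
    age = round(pmin(pmax(rnorm(n_samp, 45, 12), 18), 80), 1),
    sex = sample(c("F", "M"), n_samp, replace = TRUE, prob = c(0.9, 0.1)),
    ethnicity = sample(c("EA", "AA"), n_samp, replace = TRUE),
    cell_type = "CD4",
    batch_id = sprintf("B%02d", rep(seq_len(cfg$n_batches),
                                    each = ceiling(n_samp / cfg$n_batches))[seq_len(n_samp)])
  )
  is_case <- samples$disease == "case"

  ## --- probe roles and manifest ---
  role <- rep("background", n)
  idx <- 1L
  take <- function(k) {
    out <- seq.int(idx, length.out = k)
    idx <<- idx + k
    out
  }
  ifn_idx <- take(cfg$n_ifn_probes)
  comp_idx <- take(cfg$n_compositional_probes)
  pairI_idx <- take(cfg$n_chemistry_pairs)
  pairII_idx <- take(cfg$n_chemistry_pairs)
  x_idx <- take(cfg$n_x_probes)
  role[ifn_idx] <- "ifn"
  role[comp_idx] <- "compositional"
  role[pairI_idx] <- "pair_I"
  role[pairII_idx] <- "pair_II"
  role[x_idx] <- "x_background"

  chemistry <- ifelse(runif(n) < cfg$fraction_chemII, "II", "I")
  chemistry[pairI_idx] <- "I"
  chemistry[pairII_idx] <- "II"

  chromosome <- paste0("chr", rep_len(1:22, n))
  chromosome[x_idx] <- "chrX"
  position <- 10000L * seq_len(n)  # >=10 kb apart: no accidental <50 bp pairs
  # paired probes share a chromosome and sit 30 bp apart
  chromosome[pairII_idx] <- chromosome[pairI_idx]
  position[pairII_idx] <- position[pairI_idx] + 30L

  blacklist_flag <- rep(FALSE, n)
  snp_flag <- rep(FALSE, n)
  bg_pool <- which(role == "background")
  if (cfg$n_blacklist > 0) {
    blacklist_flag[sample(bg_pool, cfg$n_blacklist)] <- TRUE
  }
  if (cfg$n_snp_flagged > 0) {
    snp_flag[sample(setdiff(bg_pool, which(blacklist_flag)), cfg$n_snp_flagged)] <- TRUE
  }
  manifest <- tibble(probe_id = probe_ids, chemistry = chemistry,
                     chromosome = chromosome, position = position,
                     blacklist_flag = blacklist_flag, snp_flag = snp_flag)

  ## --- latent per-probe, per-group means ---
  ctrl_mean <- draw_background_means(n)
  case_mean <- ctrl_mean

  # shared latent means for chemistry pairs (<50 bp: near-identical)
  pair_means <- draw_background_means(cfg$n_chemistry_pairs)
  ctrl_mean[pairI_idx] <- case_mean[pairI_idx] <- pair_means
  ctrl_mean[pairII_idx] <- case_mean[pairII_idx] <- pair_means

  # IFN-like probes: hypomethylated in cases by delta in the configured range
  ifn_delta <- runif(cfg$n_ifn_probes, cfg$ifn_delta_range[1], cfg$ifn_delta_range[2])
  ctrl_mean[ifn_idx] <- runif(cfg$n_ifn_probes, 0.55, 0.92)
  case_mean[ifn_idx] <- ctrl_mean[ifn_idx] - ifn_delta

  # compositional probes: fraction-weighted sums of subtype profiles
  mixture <- cfg$mixture %||% default_mixture(cfg$n_compositional_probes)
  if (nrow(mixture$control_profiles) != cfg$n_compositional_probes) {
    stop_invalid("mixture profiles must have n_compositional_probes rows")
  }
  if (cfg$n_compositional_probes > 0) {
    rownames(mixture$control_profiles) <- probe_ids[comp_idx]
    rownames(mixture$case_profiles) <- probe_ids[comp_idx]
    ctrl_mean[comp_idx] <- as.numeric(mixture$control_profiles %*% mixture$control_fractions)
    case_mean[comp_idx] <- as.numeric(mixture$case_profiles %*% mixture$case_fractions)
  }

  true_delta <- case_mean - ctrl_mean

  ## --- sample-level values: mean + truncated-normal noise ---
  mean_mat <- matrix(ctrl_mean, n, n_samp)
  mean_mat[, is_case] <- case_mean
  beta <- matrix(rtruncnorm01(n * n_samp, as.vector(mean_mat), cfg$noise_sd),
                 n, n_samp, dimnames = list(probe_ids, samples$sample_id))

  # sex effect on chrX so X must be normalized/tested separately
  if (cfg$n_x_probes > 0) {
    male <- samples$sex == "M"
    if (any(male)) {
      beta[x_idx, male] <- clip01(plogis(logit_clamped(beta[x_idx, male, drop = FALSE]) - 0.8))
    }
  }

  ## --- batch shifts: additive on the logit scale ---
  batch_levels <- sort(unique(samples$batch_id))
  batch_shift <- setNames(rnorm(length(batch_levels), 0, cfg$batch_shift_sd),
                          batch_levels)
  if (cfg$batch_shift_sd > 0 && length(batch_levels) > 1) {
    shift_per_sample <- batch_shift[samples$batch_id]
    beta <- clip01(plogis(sweep(logit_clamped(beta), 2, shift_per_sample, `+`)))
  }

  ## --- Infinium II distortion: inverse of the harmonization quadratic ---
  fit <- published_chemistry_fit()
  ii <- chemistry == "II"
  if (any(ii)) beta[ii, ] <- invert_chemistry(fit, beta[ii, , drop = FALSE])

  ## --- detection p-values ---
  det <- matrix(runif(n * n_samp, 0, 0.005), n, n_samp,
                dimnames = dimnames(beta))
  if (cfg$detection_fail_rate > 0) {
    fail <- runif(n * n_samp) < cfg$detection_fail_rate
    det[fail] <- runif(sum(fail), 0.011, 1)
  }

  truth <- list(
    probes = tibble(probe_id = probe_ids, role = role, chemistry = chemistry,
                    latent_ctrl_mean = ctrl_mean, latent_case_mean = case_mean,
                    true_delta = true_delta),
    mixture = mixture,
    batch_shifts = tibble(batch_id = batch_levels, shift = unname(batch_shift)),
    chemistry_fit = fit,
    config = cfg
  )
  list(beta = beta, detection = det, manifest = manifest, samples = samples,
       truth = truth)
}

#' Simulate sorted cell-subtype datasets
#'
#' Produces, for each subtype in the truth record's mixture, a beta matrix
#' and sample sheet in which intrinsic (IFN-like) case effects persist at
#' full amplitude while compositional effects vanish: every sorted subtype
#' carries its own methylation profile, identical across disease groups.
#' Values are on the normalized (post batch/chemistry correction) scale.
#'
#' @param config The [simulation_config()] used for the bulk dataset.
#' @param truth Truth record from [simulate_dataset()].
#' @param n_cases,n_controls Sorted-cohort group sizes (typically smaller
#'   than the bulk cohort).
#' @return Named list (one element per subtype) of lists with `beta` and
#'   `samples`.
#' @export
simulate_sorted_subsets <- function(config, truth, n_cases = 20, n_controls = 15) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$seed)) stop_invalid("simulate_sorted_subsets() requires `seed` in the config")
  with_seed(config$seed + 1L, {
    pr <- truth$probes
    n <- nrow(pr)
    n_samp <- n_cases + n_controls
    mixture <- truth$mixture
    out <- list()
    for (k in mixture$subtype_names) {
      ctrl_mean <- pr$latent_ctrl_mean
      case_mean <- pr$latent_case_mean
      comp <- pr$role == "compositional"
      if (any(comp)) {
        # the sorted subtype shows its own profile in both groups
        ctrl_mean[comp] <- mixture$control_profiles[, k]
        case_mean[comp] <- mixture$case_profiles[, k]
      }
      samples <- tibble(
        sample_id = sprintf("V%s%03d", toupper(substr(k, 1, 1)), seq_len(n_samp)),
        disease = rep(c("case", "control"), c(n_cases, n_controls)),
        activity = ifelse(rep(c(TRUE, FALSE), c(n_cases, n_controls)),
                          rep_len(c("flare", "quiescent"), n_samp), "none"),
        age = round(pmin(pmax(rnorm(n_samp, 45, 12), 18), 80), 1),
        sex = sample(c("F", "M"), n_samp, replace = TRUE, prob = c(0.9, 0.1)),
        ethnicity = sample(c("EA", "AA"), n_samp, replace = TRUE),
        cell_type = paste0("CD4_", k),
        batch_id = "B01")
      mean_mat <- matrix(ctrl_mean, n, n_samp)
      mean_mat[, samples$disease == "case"] <- case_mean
      beta <- matrix(rtruncnorm01(n * n_samp, as.vector(mean_mat), config$noise_sd),
                     n, n_samp, dimnames = list(pr$probe_id, samples$sample_id))
      out[[k]] <- list(beta = beta, samples = samples)
    }
    out
  })
}
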