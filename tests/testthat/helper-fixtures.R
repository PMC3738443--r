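# Fixture builders shared across test files. Everything is generated in code.

make_beta <- function(values, probe_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  probe_ids <- probe_ids %||% sprintf("cg%04d", seq_len(nrow(values)))
  sample_ids <- sample_ids %||% sprintf("S%03d", seq_len(ncol(values)))
  beta_matrix(values, probe_ids = probe_ids, sample_ids = sample_ids)
}

make_samples <- function(n_cases, n_controls, n_batches = 1,
                         sex = NULL, ethnicity = NULL, age = NULL) {
  n <- n_cases + n_controls
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    disease = rep(c("case", "control"), c(n_cases, n_controls)),
    activity = c(rep_len(c("flare", "quiescent"), n_cases), rep("none", n_controls)),
    # periodic patterns chosen to avoid confounding with the disease blocks
    # or with batch assignment (periods 7 and 5 vs at most 3 batches)
    age = age %||% rep_len(c(35, 50, 42, 61, 28, 47, 55), n),
    sex = sex %||% rep_len(c("F", "F", "F", "M"), n),
    ethnicity = ethnicity %||% rep_len(c("EA", "AA", "EA", "EA", "AA"), n),
    cell_type = "CD4",
    batch_id = sprintf("B%02d", rep_len(seq_len(n_batches), n))
  )
}

make_manifest <- function(probe_ids, chemistry = "II", chromosome = "chr1",
                          position = NULL, blacklist = FALSE, snp = FALSE) {
  n <- length(probe_ids)
  tibble::tibble(
    probe_id = probe_ids,
    chemistry = rep_len(chemistry, n),
    chromosome = rep_len(chromosome, n),
    position = as.integer(position %||% (1000L * seq_len(n))),
    blacklist_flag = rep_len(blacklist, n),
    snp_flag = rep_len(snp, n)
  )
}

# a null study: no planted effects, one batch, no detection failures
null_sim_config <- function(n_probes, n_cases, n_controls, seed,
                            noise_sd = 0.05) {
  simulation_config(
    n_probes = n_probes, n_cases = n_cases, n_controls = n_controls,
    n_batches = 1, batch_shift_sd = 0, n_ifn_probes = 0,
    n_compositional_probes = 0, n_chemistry_pairs = 0,
    detection_fail_rate = 0, noise_sd = noise_sd, seed = seed)
}

# random mixture specs for property-style tests
random_mixture_spec <- function(n_probes = 5, n_subtypes = 3) {
  f1 <- runif(n_subtypes); f1 <- f1 / sum(f1)
  f2 <- runif(n_subtypes); f2 <- f2 / sum(f2)
  mixture_spec(
    subtype_names = paste0("sub", seq_len(n_subtypes)),
    control_fractions = f1, case_fractions = f2,
    control_profiles = matrix(runif(n_probes * n_subtypes), n_probes),
    case_profiles = matrix(runif(n_probes * n_subtypes), n_probes))
}

# brute-force Benjamini-Hochberg step-up from its definition:
# q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j, capped at 1
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# brute-force one-sided Fisher p: hypergeometric upper tail by enumeration
fisher_greater_brute <- function(hits_top, n_top, hits_bg, n_bg) {
  # drawing n_top probes from n_bg of which hits_bg are hits
  k_max <- min(n_top, hits_bg)
  ks <- hits_top:k_max
  sum(vapply(ks, function(k) {
    exp(lchoose(hits_bg, k) + lchoose(n_bg - hits_bg, n_top - k) -
          lchoose(n_bg, n_top))
  }, numeric(1)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
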