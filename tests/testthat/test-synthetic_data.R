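test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(n_probes = 300, n_cases = 10, n_controls = 10,
                           n_ifn_probes = 5, n_compositional_probes = 20,
                           n_chemistry_pairs = 10, seed = 123)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$beta, b$beta)
  expect_identical(a$detection, b$detection)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$samples, b$samples)
  unseeded <- simulation_config(n_probes = 10, n_ifn_probes = 0,
                                n_compositional_probes = 0,
                                n_chemistry_pairs = 0, seed = NULL)
  expect_error(simulate_dataset(unseeded), "seed",
               class = "methylewas_validation_error")
})

test_that("background probe means are bimodal (most outside the 20-80% band)", {
  cfg <- simulation_config(n_probes = 3000, n_cases = 20, n_controls = 20,
                           n_ifn_probes = 0, n_compositional_probes = 0,
                           n_chemistry_pairs = 0, seed = 99)
  sim <- simulate_dataset(cfg)
  pm <- rowMeans(sim$beta, na.rm = TRUE)
  expect_gt(mean(pm < 0.2 | pm > 0.8), 0.70)
})

test_that("infeasible configs are rejected", {
  expect_error(simulation_config(n_probes = 10, n_ifn_probes = 20,
                                 n_compositional_probes = 0,
                                 n_chemistry_pairs = 0, seed = 1),
               "infeasible", class = "methylewas_validation_error")
  expect_error(simulation_config(n_probes = 10, fraction_chemII = 1.5, seed = 1),
               class = "methylewas_validation_error")
})

test_that("a null configuration yields uniform association p-values", {
  cfg <- null_sim_config(n_probes = 2000, n_cases = 25, n_controls = 25, seed = 21)
  sim <- simulate_dataset(cfg)
  tab <- run_association(sim$beta, sim$samples, contrast_spec(),
                         manifest = sim$manifest)
  expect_gt(stats::ks.test(tab$p_value, "punif")$p.value, 0.01)
  expect_lt(abs(mean(tab$p_value < 0.05) - 0.05), 0.02)
})

test_that("bulk compositional means follow the mixture arithmetic in the truth record", {
  cfg <- simulation_config(n_probes = 500, n_cases = 30, n_controls = 30,
                           n_ifn_probes = 0, n_compositional_probes = 100,
                           n_chemistry_pairs = 0, n_batches = 1,
                           batch_shift_sd = 0, fraction_chemII = 0,
                           noise_sd = 0.03, detection_fail_rate = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$probes
  comp <- tr$probe_id[tr$role == "compositional"]
  expected_ctrl <- mixture_bulk_profile(sim$truth$mixture, "control")$bulk_mean
  ctrl_cols <- sim$samples$sample_id[sim$samples$disease == "control"]
  observed <- rowMeans(sim$beta[comp, ctrl_cols])
  # truth record stores the same quantity
  expect_equal(tr$latent_ctrl_mean[tr$role == "compositional"], expected_ctrl,
               tolerance = 1e-12)
  # observed means agree within noise tolerance (se ~ noise_sd/sqrt(n))
  expect_lt(max(abs(observed - expected_ctrl)), 4 * 0.03 / sqrt(30) + 0.01)
})

test_that("identical fractions across groups give zero bulk delta at compositional probes", {
  prof <- matrix(c(0.8, 0.3), 1, 2)  # subtype profiles differ by 0.5
  spec <- mixture_spec(c("a", "b"), c(0.8, 0.2), c(0.8, 0.2), prof, prof)
  cfg <- simulation_config(n_probes = 10, n_cases = 5, n_controls = 5,
                           n_ifn_probes = 0, n_compositional_probes = 1,
                           n_chemistry_pairs = 0, mixture = spec, seed = 3)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$probes
  expect_equal(tr$true_delta[tr$role == "compositional"], 0)
})

test_that("a 50% subtype difference in a 20% subtype yields a 10% bulk delta", {
  ctrl_prof <- matrix(c(0.7, 0.7), 1, 2)
  case_prof <- matrix(c(0.7, 0.2), 1, 2)  # subtype b drops by 0.5 in cases
  spec <- mixture_spec(c("a", "b"), c(0.8, 0.2), c(0.8, 0.2),
                       ctrl_prof, case_prof)
  cfg <- simulation_config(n_probes = 10, n_cases = 5, n_controls = 5,
                           n_ifn_probes = 0, n_compositional_probes = 1,
                           n_chemistry_pairs = 0, mixture = spec, seed = 3)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$probes
  expect_equal(tr$true_delta[tr$role == "compositional"], -0.10, tolerance = 1e-12)
})

test_that("sorted subsets keep intrinsic effects and cancel compositional ones", {
  cfg <- simulation_config(n_probes = 300, n_cases = 30, n_controls = 30,
                           n_ifn_probes = 20, n_compositional_probes = 50,
                           n_chemistry_pairs = 0, n_batches = 1,
                           batch_shift_sd = 0, fraction_chemII = 0,
                           noise_sd = 0, detection_fail_rate = 0, seed = 17)
  sim <- simulate_dataset(cfg)
  subs <- simulate_sorted_subsets(cfg, sim$truth, n_cases = 10, n_controls = 10)
  expect_named(subs, sim$truth$mixture$subtype_names)
  tr <- sim$truth$probes
  for (k in names(subs)) {
    s <- subs[[k]]
    case_cols <- s$samples$sample_id[s$samples$disease == "case"]
    ctrl_cols <- s$samples$sample_id[s$samples$disease == "control"]
    d <- rowMeans(s$beta[, case_cols]) - rowMeans(s$beta[, ctrl_cols])
    # zero-noise run: intrinsic deltas exact, compositional deltas exactly 0
    expect_equal(d[tr$role == "ifn"],
                 setNames(tr$true_delta[tr$role == "ifn"],
                          tr$probe_id[tr$role == "ifn"]),
                 tolerance = 1e-12)
    expect_equal(unname(d[tr$role == "compositional"]),
                 rep(0, sum(tr$role == "compositional")), tolerance = 1e-12)
    # zero-noise subtype values equal the subtype profile in both groups
    comp_ids <- tr$probe_id[tr$role == "compositional"]
    expect_equal(unname(s$beta[comp_ids, ctrl_cols[1]]),
                 unname(sim$truth$mixture$control_profiles[, k]), tolerance = 1e-12)
  }
})

test_that("mixture_spec enforces its invariants", {
  prof <- matrix(0.5, 2, 2)
  expect_error(mixture_spec(c("a", "b"), c(0.6, 0.5), c(0.5, 0.5), prof, prof),
               "sum to 1", class = "methylewas_validation_error")
  expect_error(mixture_spec(c("a", "b"), c(0.5, 0.5), c(0.5, 0.5),
                            matrix(1.5, 2, 2), prof),
               class = "methylewas_validation_error")
})
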