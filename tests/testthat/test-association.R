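test_that("per-CpG OLS matches a probe-by-probe lm oracle, with missing data", {
  set.seed(12)
  n <- 50; ns <- 24
  ss <- make_samples(12, 12)
  beta <- matrix(runif(n * ns, 0.2, 0.8), n, ns)
  beta[sample(length(beta), 60)] <- NA  # scattered missingness patterns
  beta <- make_beta(beta)
  tab <- run_association(beta, ss, contrast_spec())

  for (i in c(1, 7, 23, 50)) {
    df <- data.frame(y = beta[i, ], group = as.integer(ss$disease == "case"),
                     age = ss$age, sex = ss$sex, ethnicity = ss$ethnicity)
    fit <- summary(lm(y ~ group + age + sex + ethnicity, data = df))
    expect_equal(tab$delta[i], unname(coef(fit)["group", "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(tab$p_value[i], unname(coef(fit)["group", "Pr(>|t|)"]),
                 tolerance = 1e-10)
    expect_identical(tab$n_used[i], sum(!is.na(beta[i, ])))
  }
})

test_that("degenerate probes are reported, not dropped", {
  ss <- make_samples(5, 5)
  beta <- make_beta(rbind(rep(0.5, 10),            # constant response
                          c(runif(10)),            # ordinary probe
                          rep(NA_real_, 10)))      # fully missing
  set.seed(1)
  tab <- run_association(beta, ss, contrast_spec(covariates = character(0)))
  expect_equal(tab$delta[1], 0)
  expect_true(is.na(tab$p_value[1]))
  expect_identical(tab$n_used[3], 0L)
  expect_true(is.na(tab$delta[3]))
  expect_error(run_association(beta, make_samples(2, 8), contrast_spec()),
               ">= 3", class = "methylewas_validation_error")
})

test_that("null data give nominal type-I error and uniform p-values", {
  cfg <- null_sim_config(n_probes = 2000, n_cases = 30, n_controls = 30, seed = 77)
  sim <- simulate_dataset(cfg)
  tab <- run_association(sim$beta, sim$samples, contrast_spec(),
                         manifest = sim$manifest)
  expect_lt(abs(mean(tab$p_value < 0.05) - 0.05), 0.015)
  expect_gt(stats::ks.test(tab$p_value, "punif")$p.value, 0.01)
})

test_that("a planted hypomethylation effect is recovered by the delta estimate", {
  set.seed(13)
  ns <- 80
  ss <- make_samples(40, 40)
  mu <- rep(0.7, 100)
  beta <- matrix(pmin(pmax(mu + rnorm(100 * ns, 0, 0.05), 0), 1), 100, ns)
  beta[1:20, ss$disease == "case"] <- beta[1:20, ss$disease == "case"] - 0.30
  beta <- make_beta(pmin(pmax(beta, 0), 1))
  tab <- run_association(beta, ss, contrast_spec())
  err <- abs(tab$delta[1:20] + 0.30)
  expect_lt(abs(mean(tab$delta[1:20]) + 0.30), 0.01)
  expect_gte(mean(err < 0.03), 0.9)
  expect_true(all(tab$tier[1:20] == "highly_significant"))
})

test_that("adding a pure-noise covariate barely moves the deltas", {
  set.seed(14)
  ns <- 60
  ss <- make_samples(30, 30, n_batches = 1)
  ss$age <- runif(ns, 20, 70)  # age independent of everything
  beta <- make_beta(matrix(pmin(pmax(rnorm(200 * ns, 0.5, 0.05), 0), 1), 200, ns))
  t0 <- run_association(beta, ss, contrast_spec(covariates = character(0)))
  t1 <- run_association(beta, ss, contrast_spec(covariates = "age"))
  expect_lt(max(abs(t0$delta - t1$delta)), 0.01)
})

test_that("X-chromosome scope restricts to females and X probes", {
  set.seed(15)
  ss <- make_samples(20, 20)
  manifest <- make_manifest(sprintf("cg%04d", 1:100),
                            chromosome = c(rep("chr1", 80), rep("chrX", 20)))
  beta <- make_beta(matrix(runif(100 * 40, 0.2, 0.8), 100, 40),
                    probe_ids = manifest$probe_id)
  ctr <- contrast_spec(chromosome_scope = "X")
  expect_false("sex" %in% ctr$covariates)
  tab <- run_association(beta, ss, ctr, manifest = manifest)
  expect_identical(nrow(tab), 20L)
  expect_true(all(tab$n_used == sum(ss$sex == "F")))
})

test_that("flare vs quiescent contrast is null when effects are activity-independent", {
  set.seed(16)
  ns <- 60
  ss <- make_samples(40, 20)
  beta <- matrix(runif(500 * ns, 0.3, 0.7), 500, ns)
  # disease effect present, identical in flare and quiescent patients
  beta[1:50, ss$disease == "case"] <- beta[1:50, ss$disease == "case"] - 0.2
  beta <- make_beta(pmin(pmax(beta, 0), 1))
  tab <- run_association(beta, ss, contrast_spec(predictor = "activity"))
  expect_gt(stats::ks.test(tab$p_value, "punif")$p.value, 0.01)
})

test_that("BH q-values equal the hand-worked example and the brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))

  set.seed(17)
  for (m in c(1, 10, 317, 1000)) {
    p <- runif(m)^2
    expect_equal(bh_fdr(p), bh_brute_force(p), tolerance = 1e-12)
  }
})

test_that("the FDR-target p threshold is the largest passing p", {
  p <- c(1e-6, 1e-5, 1e-4, 0.2, 0.5, 0.9)
  tab <- tibble::tibble(probe_id = letters[1:6], delta = 0, p_value = p,
                        q_value = bh_fdr(p), n_used = 10L, tier = "ns")
  expect_equal(tier_thresholds(tab, 0.01), 1e-4)
  tab_hi <- tab; tab_hi$q_value <- rep(0.5, 6)
  expect_true(is.na(tier_thresholds(tab_hi, 0.01)))
})

test_that("exhaustive permutation p equals an independent enumeration oracle", {
  set.seed(18)
  beta <- make_beta(matrix(runif(48), 8, 6))
  ss <- make_samples(3, 3)
  pp <- permutation_pvalues(beta, ss, contrast_spec(covariates = character(0)),
                            exhaustive = TRUE)
  expect_identical(unique(pp$n_perm), 20L)
  combos <- utils::combn(6, 3)
  for (i in seq_len(nrow(beta))) {
    t_of <- function(lab) abs(summary(lm(beta[i, ] ~ lab))$coefficients[2, 3])
    t_obs <- t_of(as.integer(ss$disease == "case"))
    ts <- apply(combos, 2, function(cc) {
      lab <- integer(6); lab[cc] <- 1L; t_of(lab)
    })
    expect_equal(pp$p_empirical[i], mean(ts >= t_obs - 1e-12))
  }
  # observed statistic 0 (identical group patterns) -> empirical p = 1
  flat <- make_beta(matrix(rep(c(0.4, 0.5, 0.6), 2), 1, 6, byrow = TRUE))
  ppf <- permutation_pvalues(flat, ss, contrast_spec(covariates = character(0)),
                             exhaustive = TRUE)
  expect_equal(ppf$p_empirical[1], 1)
})

test_that("permutation and parametric p-values agree under the null", {
  cfg <- null_sim_config(n_probes = 600, n_cases = 15, n_controls = 15, seed = 19)
  sim <- simulate_dataset(cfg)
  ctr <- contrast_spec(covariates = character(0))
  tab <- run_association(sim$beta, sim$samples, ctr, manifest = sim$manifest)
  perm <- permutation_pvalues(sim$beta, sim$samples, ctr, n_perm = 300, seed = 20)
  expect_gt(cor(tab$p_value, perm$p_empirical, method = "spearman"), 0.95)
})
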