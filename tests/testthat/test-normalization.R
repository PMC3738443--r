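# helper: manifest of n I/II pairs 30 bp apart plus the matching 2-sample
# beta matrix whose type II values are `x` and type I values are `y`
pair_fixture <- function(x, y) {
  n <- length(x)
  ids_I <- sprintf("pI%04d", seq_len(n))
  ids_II <- sprintf("pII%04d", seq_len(n))
  manifest <- tibble::tibble(
    probe_id = c(ids_I, ids_II),
    chemistry = rep(c("I", "II"), each = n),
    chromosome = "chr1",
    position = as.integer(c(1000 * seq_len(n), 1000 * seq_len(n) + 30)),
    blacklist_flag = FALSE, snp_flag = FALSE)
  beta <- make_beta(cbind(c(y, x), c(y, x)), probe_ids = c(ids_I, ids_II))
  list(beta = beta, manifest = manifest)
}

test_that("an identity relationship between chemistries is recovered exactly", {
  x <- seq(0.01, 0.99, length.out = 200)
  fx <- pair_fixture(x, x)
  fit <- fit_chemistry_correction(fx$beta, fx$manifest)
  expect_equal(fit$c0, 0, tolerance = 1e-10)
  expect_equal(fit$c1, 1, tolerance = 1e-10)
  expect_equal(fit$c2, 0, tolerance = 1e-10)
  expect_identical(fit$n_pairs, 200L)
  # identity fit leaves values untouched
  corrected <- apply_chemistry_correction(fx$beta, fx$manifest,
                                          chemistry_fit(0, 1, 0))
  expect_equal(corrected, fx$beta)
})

test_that("noise-free pairs generated from the packaged quadratic recover it", {
  pub <- published_chemistry_fit()
  # keep the response inside [0,1]: the raw quadratic reaches 1 near x = 0.95
  x <- seq(0, 0.95, length.out = 300)
  fx <- pair_fixture(x, predict_chemistry(pub, x, clip = FALSE))
  fit <- fit_chemistry_correction(fx$beta, fx$manifest)
  expect_equal(fit$c0, pub$c0, tolerance = 1e-6)
  expect_equal(fit$c1, pub$c1, tolerance = 1e-6)
  expect_equal(fit$c2, pub$c2, tolerance = 1e-6)
})

test_that("noisy pairs recover the generating coefficients within 0.01", {
  set.seed(41)
  pub <- published_chemistry_fit()
  # range chosen so noise never pushes the response outside [0,1]
  x <- runif(5000, 0.02, 0.95)
  y <- predict_chemistry(pub, x, clip = FALSE) + rnorm(5000, 0, 0.01)
  fx <- pair_fixture(x, pmin(pmax(y, 0), 1))
  fit <- fit_chemistry_correction(fx$beta, fx$manifest)
  expect_lt(abs(fit$c0 - pub$c0), 0.01)
  expect_lt(abs(fit$c1 - pub$c1), 0.01)
  expect_lt(abs(fit$c2 - pub$c2), 0.01)
})

test_that("pairing respects the distance cutoff and the minimum pair count", {
  fx <- pair_fixture(seq(0.1, 0.9, length.out = 30), seq(0.1, 0.9, length.out = 30))
  expect_error(fit_chemistry_correction(fx$beta, fx$manifest, min_pairs = 50),
               "pairs", class = "methylewas_validation_error")
  # probes 60 bp apart are not paired at the default 50 bp cutoff
  far <- fx$manifest
  far$position[far$chemistry == "II"] <- far$position[far$chemistry == "I"] + 60L
  expect_error(fit_chemistry_correction(fx$beta, far, min_pairs = 1),
               class = "methylewas_validation_error")
})

test_that("applying the correction transforms only type II probes and clips", {
  pub <- published_chemistry_fit()
  manifest <- make_manifest(c("a", "b", "c"), chemistry = c("I", "II", "II"))
  beta <- make_beta(matrix(c(0.4, 0, 1, 0.4, 0.5, NA), 3, 2),
                    probe_ids = c("a", "b", "c"))
  out <- apply_chemistry_correction(beta, manifest, pub)
  expect_equal(out["a", ], beta["a", ])                       # type I untouched
  expect_equal(unname(out["b", "S001"]), 0.001514)            # published value at 0
  expect_equal(unname(out["c", "S001"]), 1)                   # 1.074914 clipped
  expect_true(is.na(out["c", "S002"]))                        # NA stays NA
  # raw (unclipped) polynomial value at beta = 1
  expect_equal(predict_chemistry(pub, 1, clip = FALSE), 1.074914,
               tolerance = 1e-12)
})

test_that("the packaged quadratic is monotone non-decreasing on [0, 1]", {
  pub <- published_chemistry_fit()
  b <- seq(0, 1, length.out = 101)
  expect_true(all(pub$c1 + 2 * pub$c2 * b >= 0))
  expect_true(all(diff(predict_chemistry(pub, b)) >= 0))
  # generator distortion is the numeric inverse of the correction
  expect_equal(predict_chemistry(pub, invert_chemistry(pub, c(0.1, 0.5, 0.9)),
                                 clip = FALSE),
               c(0.1, 0.5, 0.9), tolerance = 1e-10)
})

test_that("a single batch passes through unchanged", {
  set.seed(5)
  beta <- make_beta(matrix(runif(200), 20, 10))
  ss <- make_samples(5, 5, n_batches = 1)
  out <- batch_adjust(beta, ss, batch_adjust_config(mode = "parametric"))
  expect_identical(out, beta)
})

test_that("the EB adjustment matches the reference ComBat implementation", {
  set.seed(6)
  n <- 300; ns <- 30
  ss <- make_samples(15, 15, n_batches = 3)
  mu <- runif(n, 0.3, 0.7)
  beta <- make_beta(matrix(pmin(pmax(mu + rnorm(n * ns, 0, 0.05), 0.01), 0.99), n, ns))
  off <- c(B01 = 0.04, B02 = -0.03, B03 = 0)
  beta <- make_beta(pmin(pmax(sweep(beta, 2, off[ss$batch_id], `+`), 0.01), 0.99),
                    probe_ids = rownames(beta), sample_ids = colnames(beta))
  ours <- batch_adjust(beta, ss, batch_adjust_config(mode = "parametric"),
                       covariates = c("disease", "age", "sex", "ethnicity"))
  mod <- stats::model.matrix(~ disease + age + sex + ethnicity, data = ss)
  ref <- sva::ComBat(beta, batch = ss$batch_id, mod = mod, par.prior = TRUE)
  expect_lt(max(abs(ours - pmin(pmax(ref, 0), 1))), 1e-5)
})

test_that("additive batch shifts are removed without attenuating a disease effect", {
  set.seed(8)
  n <- 600; ns <- 40
  ss <- make_samples(20, 20, n_batches = 2)
  mu <- runif(n, 0.25, 0.75)
  beta <- matrix(pmin(pmax(mu + rnorm(n * ns, 0, 0.05), 0), 1), n, ns)
  off <- c(B01 = 0.05, B02 = -0.05)
  beta <- sweep(beta, 2, off[ss$batch_id], `+`)
  planted <- 1:60
  beta[planted, ss$disease == "case"] <- beta[planted, ss$disease == "case"] - 0.2
  beta <- make_beta(pmin(pmax(beta, 0), 1))
  adj <- batch_adjust(beta, ss, batch_adjust_config(mode = "nonparametric", seed = 4))
  # batch-driven inflation is gone: no excess of small batch p-values
  batch_p <- apply(adj, 1, function(y) {
    stats::t.test(y[ss$batch_id == "B01"], y[ss$batch_id == "B02"])$p.value
  })
  expect_lte(mean(batch_p < 0.05), 0.05)
  expect_gt(stats::ks.test(batch_p, "punif", alternative = "greater")$p.value, 0.01)
  # the planted effect survives adjustment
  tab <- run_association(adj, ss, contrast_spec())
  expect_lt(abs(mean(tab$delta[planted]) + 0.2), 0.02)
  # and no disease signal is introduced at null probes
  null_p <- tab$p_value[-planted]
  expect_lt(mean(null_p < 0.05, na.rm = TRUE), 0.08)
})

test_that("subsetted adjustment agrees with a single full run", {
  set.seed(9)
  n <- 800; ns <- 36
  ss <- make_samples(18, 18, n_batches = 3)
  mu <- runif(n, 0.3, 0.7)
  beta <- matrix(pmin(pmax(mu + rnorm(n * ns, 0, 0.05), 0), 1), n, ns)
  off <- c(B01 = 0.04, B02 = -0.02, B03 = 0.01)
  beta <- make_beta(pmin(pmax(sweep(beta, 2, off[ss$batch_id], `+`), 0), 1))
  full <- batch_adjust(beta, ss, batch_adjust_config(mode = "parametric",
                                                     seed = 2, subset_size = 10^6))
  subs <- batch_adjust(beta, ss, batch_adjust_config(mode = "parametric",
                                                     seed = 2, subset_size = 200))
  expect_lt(mean(abs(full - subs)), 1e-3)
})

test_that("chemistries and chromosome X are adjusted in separate groups", {
  set.seed(10)
  n <- 200; ns <- 24
  ss <- make_samples(12, 12, n_batches = 2)
  manifest <- make_manifest(sprintf("cg%04d", 1:n),
                            chemistry = rep(c("I", "II"), n / 2),
                            chromosome = c(rep("chr1", 160), rep("chrX", 40)))
  beta <- make_beta(matrix(runif(n * ns, 0.2, 0.8), n, ns))
  out <- batch_adjust(beta, ss, batch_adjust_config(mode = "parametric"),
                      manifest = manifest)
  expect_identical(dim(out), dim(beta))
  expect_true(all(out >= 0 & out <= 1, na.rm = TRUE))
  # NA cells stay NA and others are adjusted
  beta_na <- beta; beta_na[1, 1] <- NA
  out_na <- batch_adjust(beta_na, ss, batch_adjust_config(mode = "parametric"),
                         manifest = manifest)
  expect_true(is.na(out_na[1, 1]))
  # a batch with a single sample is passed through with a warning
  ss1 <- ss; ss1$batch_id[1] <- "B99"
  expect_warning(
    batch_adjust(beta, ss1, batch_adjust_config(mode = "parametric")),
    "passed through")
})
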