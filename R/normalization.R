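## Cross-chemistry harmonization and empirical-Bayes batch adjustment.
##
## Infinium II beta scores are mapped toward the Infinium I scale by a
## quadratic b' = c0 + c1*b + c2*b^2 fitted from I/II probe pairs located
## within 50 bp of each other (where latent methylation is locally shared).
## Batch adjustment moderates per-CpG, per-batch location and scale toward
## common values by empirical-Bayes shrinkage, run independently on random
## non-overlapping CpG subsets, separately per chemistry, and separately by
## sex on chromosome X.

# ---------------------------------------------------------------------------
# chemistry harmonization
# ---------------------------------------------------------------------------

#' Construct a chemistry-harmonization fit
#'
#' Represents the quadratic mapping `b' = c0 + c1*b + c2*b^2` applied to
#' Infinium II beta scores to put them on the Infinium I scale.
#'
#' @param c0,c1,c2 Polynomial coefficients.
#' @param n_pairs Number of I/II probe pairs used in the fit (NA for a fit
#'   supplied externally).
#' @param max_pair_distance Maximum pair distance in bp used in the fit.
#' @return A `chemistry_fit` object.
#' @export
chemistry_fit <- function(c0, c1, c2, n_pairs = NA_integer_,
                          max_pair_distance = NA_integer_) {
  structure(list(c0 = c0, c1 = c1, c2 = c2, n_pairs = n_pairs,
                 max_pair_distance = max_pair_distance),
            class = "chemistry_fit")
}

#' The published chemistry-harmonization coefficients
#'
#' Loads the packaged coefficients (0.001514, 0.3323, 0.7411) for the
#' Infinium II -> I quadratic from the constants file shipped with the
#' package.
#'
#' @return A `chemistry_fit`.
#' @export
published_chemistry_fit <- function() {
  path <- system.file("extdata", "chemistry_coefficients.tsv",
                      package = "methylewas", mustWork = TRUE)
  co <- readr::read_tsv(path, col_types = "ddd", progress = FALSE)
  chemistry_fit(co$c0[1], co$c1[1], co$c2[1])
}

#' @export
print.chemistry_fit <- function(x, ...) {
  cat(sprintf("chemistry fit: b' = %.6g + %.6g*b + %.6g*b^2", x$c0, x$c1, x$c2))
  if (!is.na(x$n_pairs)) cat(sprintf("  (%d pairs, <%d bp)", x$n_pairs, x$max_pair_distance))
  cat("\n")
  invisible(x)
}

#' Tidy a chemistry fit
#' @param x A `chemistry_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient.
#' @method tidy chemistry_fit
#' @export
tidy.chemistry_fit <- function(x, ...) {
  tibble(term = c("c0", "c1", "c2"), estimate = c(x$c0, x$c1, x$c2))
}

#' @rdname tidy.chemistry_fit
#' @method glance chemistry_fit
#' @export
glance.chemistry_fit <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, max_pair_distance = x$max_pair_distance)
}

#' Evaluate the chemistry-harmonization quadratic
#'
#' @param fit A `chemistry_fit`.
#' @param beta Numeric vector/matrix of type II beta scores.
#' @param clip Clip the corrected values to \[0, 1\] (the raw polynomial
#'   exceeds 1 at beta = 1)? Set `FALSE` to obtain the raw polynomial value.
#' @return Corrected values, same shape as `beta`.
#' @export
predict_chemistry <- function(fit, beta, clip = TRUE) {
  out <- fit$c0 + fit$c1 * beta + fit$c2 * beta^2
  if (clip) out <- clip01(out)
  out
}

#' Invert the chemistry-harmonization quadratic
#'
#' Maps Infinium I-scale values back to the raw Infinium II scale (used by
#' the synthetic-data generator to distort type II probes). Solves
#' `c0 + c1*x + c2*x^2 = y` for x on \[0, 1\].
#'
#' @param fit A `chemistry_fit`.
#' @param y Values on the type I scale.
#' @return Raw type II values, clipped to \[0, 1\]; `NA` stays `NA`.
#' @export
invert_chemistry <- function(fit, y) {
  if (abs(fit$c2) < 1e-12) {
    return(clip01((y - fit$c0) / fit$c1))
  }
  disc <- pmax(fit$c1^2 + 4 * fit$c2 * (y - fit$c0), 0)
  clip01((-fit$c1 + sqrt(disc)) / (2 * fit$c2))
}

# I/II probe pairs within `max_distance_bp` on the same chromosome; each
# unordered pair used once, probes may appear in several pairs
find_chemistry_pairs <- function(manifest, max_distance_bp = 50) {
  out <- list()
  for (chrom in unique(manifest$chromosome)) {
    m <- manifest[manifest$chromosome == chrom, ]
    mi <- m[m$chemistry == "I", ]
    mii <- m[m$chemistry == "II", ]
    if (!nrow(mi) || !nrow(mii)) next
    ord <- order(mii$position)
    pos2 <- mii$position[ord]
    id2 <- mii$probe_id[ord]
    lo <- findInterval(mi$position - max_distance_bp, pos2) + 1L
    hi <- findInterval(mi$position + max_distance_bp - 1L, pos2)
    keep <- which(hi >= lo)
    for (i in keep) {
      js <- lo[i]:hi[i]
      js <- js[abs(pos2[js] - mi$position[i]) < max_distance_bp]
      if (length(js)) {
        out[[length(out) + 1L]] <- tibble(probe_I = mi$probe_id[i],
                                          probe_II = id2[js])
      }
    }
  }
  if (!length(out)) return(tibble(probe_I = character(), probe_II = character()))
  list_rbind(out)
}

#' Fit the Infinium II -> I harmonization quadratic from proximal probe pairs
#'
#' Pairs every Infinium I probe with every Infinium II probe located within
#' `max_distance_bp` on the same chromosome, computes per-probe mean beta
#' scores across samples, and least-squares fits
#' `mean_I = c0 + c1*mean_II + c2*mean_II^2`.
#'
#' @param beta Beta matrix (pre-harmonization).
#' @param manifest Probe manifest with chemistries and positions.
#' @param max_distance_bp Maximum pair distance (strict; default 50).
#' @param min_pairs Minimum number of pairs required (default 50).
#' @return A `chemistry_fit`.
#' @export
fit_chemistry_correction <- function(beta, manifest, max_distance_bp = 50,
                                     min_pairs = 50) {
  pairs <- find_chemistry_pairs(
    manifest[manifest$probe_id %in% rownames(beta), ], max_distance_bp)
  if (nrow(pairs) < min_pairs) {
    stop_invalid(sprintf(
      "only %d I/II probe pairs within %d bp (need >= %d); increase the distance or probe count",
      nrow(pairs), max_distance_bp, min_pairs))
  }
  means <- rowMeans(beta, na.rm = TRUE)
  x <- means[pairs$probe_II]
  y <- means[pairs$probe_I]
  ok <- is.finite(x) & is.finite(y)
  fit <- lm(y ~ x + I(x^2), data = data.frame(x = x[ok], y = y[ok]))
  co <- unname(coef(fit))
  chemistry_fit(co[1], co[2], co[3], n_pairs = sum(ok),
                max_pair_distance = max_distance_bp)
}

#' Apply chemistry harmonization to Infinium II probes
#'
#' Type II probe values are transformed by the fitted quadratic and clipped
#' to \[0, 1\]; type I probes and missing entries are untouched.
#'
#' @param beta Beta matrix.
#' @param manifest Probe manifest.
#' @param fit A `chemistry_fit` (e.g. [published_chemistry_fit()]).
#' @return Corrected beta matrix.
#' @export
apply_chemistry_correction <- function(beta, manifest, fit) {
  info <- manifest[match(rownames(beta), manifest$probe_id), ]
  if (anyNA(info$probe_id)) stop_invalid("some beta probes are absent from the manifest")
  ii <- info$chemistry == "II"
  if (any(ii)) {
    beta[ii, ] <- predict_chemistry(fit, beta[ii, , drop = FALSE], clip = TRUE)
  }
  beta
}

# ---------------------------------------------------------------------------
# empirical-Bayes batch adjustment
# ---------------------------------------------------------------------------

#' Configure batch adjustment
#'
#' @param subset_size Maximum CpGs adjusted per job; probes are partitioned
#'   into random non-overlapping subsets of at most this size (default
#'   20000).
#' @param mode `"nonparametric"` (default; Monte-Carlo weighting of
#'   empirical priors) or `"parametric"` (normal / inverse-gamma priors).
#' @param seed Integer seed for the random subsetting and the Monte-Carlo
#'   draws; required when either is stochastic.
#' @param group_by_chemistry Adjust Infinium I and II probes separately?
#' @param split_x_by_sex Adjust chromosome X separately for males and
#'   females?
#' @param mc_draws Number of Monte-Carlo prior draws per batch in
#'   nonparametric mode.
#' @return A `batch_adjust_config` list.
#' @export
batch_adjust_config <- function(subset_size = 20000,
                                mode = c("nonparametric", "parametric"),
                                seed = NULL, group_by_chemistry = TRUE,
                                split_x_by_sex = TRUE, mc_draws = 1000) {
  if (subset_size < 1) stop_invalid("`subset_size` must be >= 1")
  structure(list(subset_size = subset_size, mode = match.arg(mode),
                 seed = seed, group_by_chemistry = group_by_chemistry,
                 split_x_by_sex = split_x_by_sex, mc_draws = mc_draws),
            class = "batch_adjust_config")
}

# covariate model matrix (intercept + protected covariates)
batch_model_matrix <- function(samples, covariates) {
  df <- as.data.frame(samples)
  for (cv in covariates) {
    if (!cv %in% names(df)) stop_invalid(sprintf("covariate '%s' missing from sample sheet", cv))
    if (anyNA(df[[cv]])) stop_invalid(sprintf("covariate '%s' has missing values", cv))
  }
  if (!length(covariates)) return(matrix(1, nrow(df), 1))
  # drop covariates that are constant in this sample subset (singular otherwise)
  keep <- covariates[vapply(covariates, function(cv) length(unique(df[[cv]])) > 1, logical(1))]
  if (!length(keep)) return(matrix(1, nrow(df), 1))
  stats::model.matrix(stats::reformulate(keep), data = df)
}

# core empirical-Bayes location/scale batch adjustment on one probe block.
# dat: probes x samples (may contain NA; NA cells are mean-imputed for the
# fit and re-masked afterwards), batch: factor, mod: covariate model matrix.
eb_batch_core <- function(dat, batch, mod, parametric = FALSE, mc_draws = 1000) {
  batch <- droplevels(as.factor(batch))
  n_batches <- nlevels(batch)
  small <- names(which(table(batch) < 2))
  adjust_cols <- !(batch %in% small)
  if (length(small)) {
    warn(sprintf("batch(es) with < 2 samples passed through unadjusted: %s",
                 paste(small, collapse = ", ")))
  }
  keep_levels <- setdiff(levels(batch), small)
  if (length(keep_levels) < 2) return(dat)

  na_mask <- is.na(dat)
  if (any(na_mask)) {
    rm <- rowMeans(dat, na.rm = TRUE)
    rm[!is.finite(rm)] <- 0.5
    dat[na_mask] <- rm[row(dat)[na_mask]]
  }

  work_cols <- which(adjust_cols)
  X <- dat[, work_cols, drop = FALSE]
  b <- droplevels(batch[work_cols])
  modw <- mod[work_cols, , drop = FALSE]
  nb <- nlevels(b)
  n <- ncol(X)
  batch_design <- stats::model.matrix(~ -1 + b)
  # the batch indicators span the intercept; drop constant covariate columns
  const_col <- apply(modw, 2, function(x) length(unique(x)) == 1)
  modw <- modw[, !const_col, drop = FALSE]
  design <- cbind(batch_design, modw)
  if (qr(design)$rank < ncol(design)) {
    stop_invalid("batch is confounded with the protected covariates")
  }
  n_i <- as.numeric(table(b))

  B_hat <- solve(crossprod(design), t(design) %*% t(X))
  grand_mean <- crossprod(n_i / n, B_hat[seq_len(nb), , drop = FALSE])
  var_pooled <- rowMeans((X - t(design %*% B_hat))^2)
  var_pooled[var_pooled < 1e-12] <- 1e-12

  stand_mean <- t(grand_mean) %*% t(rep(1, n))
  if (ncol(design) > nb) {
    tmp <- design
    tmp[, seq_len(nb)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (X - stand_mean) / sqrt(var_pooled)

  gamma_hat <- matrix(NA_real_, nb, nrow(X))
  delta_hat <- matrix(NA_real_, nb, nrow(X))
  for (i in seq_len(nb)) {
    cols <- b == levels(b)[i]
    gamma_hat[i, ] <- rowMeans(s_data[, cols, drop = FALSE])
    delta_hat[i, ] <- apply(s_data[, cols, drop = FALSE], 1, var)
  }
  delta_hat[!is.finite(delta_hat) | delta_hat < 1e-12] <- 1e-12

  gamma_star <- matrix(NA_real_, nb, nrow(X))
  delta_star <- matrix(NA_real_, nb, nrow(X))
  if (parametric) {
    for (i in seq_len(nb)) {
      g <- gamma_hat[i, ]; d <- delta_hat[i, ]
      g_bar <- mean(g); t2 <- max(var(g), 1e-12)
      m <- mean(d); s2 <- max(var(d), 1e-12)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      cols <- b == levels(b)[i]
      sd_cols <- s_data[, cols, drop = FALSE]
      ni <- sum(cols)
      g_old <- g; d_old <- d
      for (iter in seq_len(100)) {
        g_new <- (t2 * ni * g + d_old * g_bar) / (t2 * ni + d_old)
        sum2 <- rowSums((sd_cols - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (ni / 2 + a_prior - 1)
        if (max(abs(g_new - g_old) / abs(g_old + 1e-12),
                abs(d_new - d_old) / abs(d_old + 1e-12)) < 1e-4) {
          g_old <- g_new; d_old <- d_new
          break
        }
        g_old <- g_new; d_old <- d_new
      }
      gamma_star[i, ] <- g_old
      delta_star[i, ] <- d_old
    }
  } else {
    # nonparametric: Monte-Carlo integration over the empirical prior formed
    # by the other probes' per-batch estimates
    G <- nrow(X)
    for (i in seq_len(nb)) {
      cols <- b == levels(b)[i]
      sd_cols <- s_data[, cols, drop = FALSE]
      ni <- sum(cols)
      draws <- if (G - 1 > mc_draws) sample(G, mc_draws) else seq_len(G)
      g_d <- gamma_hat[i, draws]
      d_d <- delta_hat[i, draws]
      sum_x <- rowSums(sd_cols)
      sum_x2 <- rowSums(sd_cols^2)
      for (g in seq_len(G)) {
        use <- draws != g
        gd <- g_d[use]; dd <- d_d[use]
        ss <- sum_x2[g] - 2 * gd * sum_x[g] + ni * gd^2
        log_lh <- -ni / 2 * log(2 * pi * dd) - ss / (2 * dd)
        w <- exp(log_lh - max(log_lh))
        sw <- sum(w)
        gamma_star[i, g] <- sum(gd * w) / sw
        delta_star[i, g] <- sum(dd * w) / sw
      }
    }
  }

  bayes <- s_data
  for (i in seq_len(nb)) {
    cols <- b == levels(b)[i]
    bayes[, cols] <- (s_data[, cols, drop = FALSE] - gamma_star[i, ]) /
      sqrt(delta_star[i, ])
  }
  adjusted <- bayes * sqrt(var_pooled) + stand_mean
  dat[, work_cols] <- adjusted
  dat <- clip01(dat)
  dat[na_mask] <- NA_real_
  dat
}

#' Empirical-Bayes batch adjustment of a beta matrix
#'
#' Per-CpG, per-batch location and scale are moderated toward common values
#' by empirical-Bayes shrinkage while protecting disease and the listed
#' covariates. Probes are partitioned into random non-overlapping subsets of
#' at most `config$subset_size` and each subset is adjusted independently;
#' chemistries are adjusted separately (when a manifest is given) and
#' chromosome X is adjusted separately by sex. Output is clipped to
#' \[0, 1\]; missing cells stay missing. With fewer than two batches the
#' input is returned unchanged.
#'
#' @param beta Beta matrix.
#' @param samples Sample sheet covering every column of `beta`.
#' @param config A [batch_adjust_config()].
#' @param covariates Protected covariate columns of the sample sheet
#'   (default disease, age, sex, ethnicity).
#' @param manifest Optional probe manifest; required for chemistry grouping
#'   and X-by-sex splitting.
#' @return Adjusted beta matrix.
#' @export
batch_adjust <- function(beta, samples,
                         config = batch_adjust_config(),
                         covariates = c("disease", "age", "sex", "ethnicity"),
                         manifest = NULL) {
  validate_beta_matrix(beta)
  samples <- samples[match(colnames(beta), samples$sample_id), ]
  if (anyNA(samples$sample_id)) stop_invalid("sample sheet does not cover all beta columns")
  if (length(unique(samples$batch_id)) < 2) return(beta)
  needs_seed <- config$mode == "nonparametric" || config$subset_size < nrow(beta)
  if (needs_seed && is.null(config$seed)) {
    stop_invalid("batch_adjust() with random subsetting or nonparametric mode requires `seed` in the config")
  }

  probe_groups <- list(all = rownames(beta))
  if (!is.null(manifest)) {
    info <- manifest[match(rownames(beta), manifest$probe_id), ]
    is_x <- info$chromosome %in% c("chrX", "X")
    grp <- if (config$group_by_chemistry) info$chemistry else "all"
    key <- paste0(grp, ifelse(is_x, "_X", "_aut"))
    probe_groups <- split(rownames(beta), key)
  }

  with_seed(config$seed, {
    out <- beta
    for (grp_name in names(probe_groups)) {
      probes <- probe_groups[[grp_name]]
      on_x <- endsWith(grp_name, "_X")
      sample_splits <- list(colnames(beta))
      if (on_x && config$split_x_by_sex && length(unique(samples$sex)) > 1) {
        sample_splits <- split(samples$sample_id, samples$sex)
      }
      n_subsets <- ceiling(length(probes) / config$subset_size)
      subset_id <- sample(rep(seq_len(n_subsets), length.out = length(probes)))
      for (cols in sample_splits) {
        sub_samples <- samples[match(cols, samples$sample_id), ]
        if (length(unique(sub_samples$batch_id)) < 2) next
        cvs <- covariates
        if (on_x) cvs <- setdiff(cvs, "sex")
        mod <- batch_model_matrix(sub_samples, cvs)
        for (s in seq_len(n_subsets)) {
          rows <- probes[subset_id == s]
          if (!length(rows)) next
          out[rows, cols] <- eb_batch_core(
            beta[rows, cols, drop = FALSE], sub_samples$batch_id, mod,
            parametric = config$mode == "parametric",
            mc_draws = config$mc_draws)
        }
      }
    }
    out
  })
}
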