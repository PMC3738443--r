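## Per-CpG covariate-adjusted linear association, permutation p-values, FDR.
##
## At each CpG, ordinary least squares of the beta value on a group
## indicator plus covariates (complete cases per CpG). The group-indicator
## coefficient is the covariate-adjusted case-minus-control methylation
## difference (delta; negative = hypomethylated in cases); its two-sided
## t-test gives the p-value. FDR is Benjamini-Hochberg.

#' Specify an association contrast
#'
#' @param predictor `"disease"` (case vs control) or `"activity"` (flare vs
#'   quiescent, among cases).
#' @param covariates Subset of `c("age", "sex", "ethnicity")`.
#' @param sample_filter Optional predicate `function(samples) -> logical`
#'   applied to the sample sheet before analysis (e.g. females only).
#' @param chromosome_scope `"autosomal"`, `"X"` or `"all"`. Scope `"X"`
#'   forces a females-only analysis and drops the sex covariate.
#' @return A `contrast_spec` object.
#' @export
contrast_spec <- function(predictor = c("disease", "activity"),
                          covariates = c("age", "sex", "ethnicity"),
                          sample_filter = NULL,
                          chromosome_scope = c("autosomal", "X", "all")) {
  predictor <- match.arg(predictor)
  chromosome_scope <- match.arg(chromosome_scope)
  bad_cov <- setdiff(covariates, c("age", "sex", "ethnicity"))
  if (length(bad_cov)) {
    stop_invalid(paste0("unknown covariate(s): ", paste(bad_cov, collapse = ", ")))
  }
  if (chromosome_scope == "X") covariates <- setdiff(covariates, "sex")
  structure(list(predictor = predictor, covariates = covariates,
                 sample_filter = sample_filter,
                 chromosome_scope = chromosome_scope),
            class = "contrast_spec")
}

# resolve samples and the 0/1 predictor for a contrast
contrast_samples <- function(samples, contrast) {
  keep <- rep(TRUE, nrow(samples))
  if (contrast$chromosome_scope == "X") keep <- keep & samples$sex == "F"
  if (!is.null(contrast$sample_filter)) {
    keep <- keep & contrast$sample_filter(samples)
  }
  s <- samples[keep, ]
  if (contrast$predictor == "disease") {
    s$.group <- as.integer(s$disease == "case")
  } else {
    s <- s[s$activity %in% c("flare", "quiescent"), ]
    s$.group <- as.integer(s$activity == "flare")
  }
  if (sum(s$.group == 1) < 3 || sum(s$.group == 0) < 3) {
    stop_invalid("each contrast group needs >= 3 samples")
  }
  s
}

# design matrix: intercept, group indicator, covariates (ethnicity as
# indicators with the most frequent level as reference)
contrast_design <- function(s, covariates) {
  X <- cbind(`(Intercept)` = 1, group = s$.group)
  if ("age" %in% covariates) {
    if (anyNA(s$age)) stop_invalid("covariate 'age' has missing values")
    X <- cbind(X, age = s$age)
  }
  if ("sex" %in% covariates && length(unique(s$sex)) > 1) {
    X <- cbind(X, sexM = as.integer(s$sex == "M"))
  }
  if ("ethnicity" %in% covariates) {
    if (anyNA(s$ethnicity)) stop_invalid("covariate 'ethnicity' has missing values")
    lv <- names(sort(table(s$ethnicity), decreasing = TRUE))
    for (l in lv[-1]) {
      X <- cbind(X, as.integer(s$ethnicity == l))
      colnames(X)[ncol(X)] <- paste0("ethnicity", l)
    }
  }
  X
}

# vectorised per-probe OLS grouped by missingness pattern; returns delta,
# se, t, p, n_used, df per probe
ols_by_pattern <- function(Y, X) {
  G <- nrow(Y)
  out <- tibble(delta = rep(NA_real_, G), se = NA_real_, t = NA_real_,
                p_value = NA_real_, n_used = 0L)
  miss <- is.na(Y)
  pattern <- apply(miss, 1, function(z) paste(which(z), collapse = ","))
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    drop_cols <- if (nzchar(pat)) as.integer(strsplit(pat, ",")[[1]]) else integer(0)
    use <- setdiff(seq_len(ncol(Y)), drop_cols)
    n <- length(use)
    out$n_used[rows] <- n
    if (n == 0) next
    Xs <- X[use, , drop = FALSE]
    # drop covariate columns that became constant in this subset
    const_col <- apply(Xs, 2, function(x) length(unique(x)) == 1)
    const_col[colnames(Xs) == "(Intercept)"] <- FALSE
    if (any(const_col[colnames(Xs) == "group"])) next  # one group left only
    Xs <- Xs[, !const_col, drop = FALSE]
    p <- ncol(Xs)
    if (n - p < 1 || qr(Xs)$rank < p) next
    XtX_inv <- solve(crossprod(Xs))
    Ys <- Y[rows, use, drop = FALSE]
    coefs <- XtX_inv %*% crossprod(Xs, t(Ys))            # p x G_pat
    fitted <- Xs %*% coefs
    resid <- t(Ys) - fitted
    rss <- colSums(resid^2)
    df <- n - p
    sigma2 <- rss / df
    d_idx <- which(colnames(Xs) == "group")
    delta <- coefs[d_idx, ]
    se <- sqrt(sigma2 * XtX_inv[d_idx, d_idx])
    tt <- delta / se
    pv <- 2 * pt(-abs(tt), df)
    # constant response / perfect fit: delta ~ 0, p undefined
    degenerate <- sigma2 < 1e-24
    pv[degenerate] <- NA_real_
    tt[degenerate] <- NA_real_
    out$delta[rows] <- delta
    out$se[rows] <- se
    out$t[rows] <- tt
    out$p_value[rows] <- pv
  }
  out
}

#' Per-CpG covariate-adjusted association
#'
#' @param beta Beta matrix (probes x samples).
#' @param samples Sample sheet covering the beta columns.
#' @param contrast A [contrast_spec()].
#' @param manifest Optional probe manifest; required to restrict probes when
#'   `chromosome_scope` is `"autosomal"` or `"X"` (without a manifest all
#'   probes are analyzed).
#' @return Association table: tibble with `probe_id`, `delta` (adjusted
#'   case-minus-control difference), `p_value`, `q_value` (BH), `n_used`,
#'   `tier` (`highly_significant` p < 1e-8; `moderately_significant`
#'   q < 0.01; else `ns`).
#' @export
run_association <- function(beta, samples, contrast = contrast_spec(),
                            manifest = NULL) {
  validate_beta_matrix(beta)
  s <- contrast_samples(samples[match(colnames(beta), samples$sample_id), ],
                        contrast)
  if (!is.null(manifest) && contrast$chromosome_scope != "all") {
    info <- manifest[match(rownames(beta), manifest$probe_id), ]
    on_x <- info$chromosome %in% c("chrX", "X")
    on_y <- info$chromosome %in% c("chrY", "Y")
    keep <- if (contrast$chromosome_scope == "X") on_x else !(on_x | on_y)
    beta <- beta[keep, , drop = FALSE]
  }
  Y <- beta[, s$sample_id, drop = FALSE]
  X <- contrast_design(s, contrast$covariates)
  fit <- ols_by_pattern(Y, X)
  tibble(probe_id = rownames(Y), delta = fit$delta, p_value = fit$p_value,
         n_used = fit$n_used) |>
    mutate(q_value = bh_fdr(.data$p_value),
           tier = dplyr::case_when(
             !is.na(.data$p_value) & .data$p_value < 1e-8 ~ "highly_significant",
             !is.na(.data$q_value) & .data$q_value < 0.01 ~ "moderately_significant",
             .default = "ns")) |>
    select("probe_id", "delta", "p_value", "q_value", "n_used", "tier")
}

# observed t statistics for a contrast (used by the permutation machinery)
assoc_tstats <- function(Y, X) ols_by_pattern(Y, X)$t

#' Permutation p-values for a contrast
#'
#' The group labels are permuted across the included samples and the
#' per-CpG t statistic recomputed; the empirical p-value is
#' `(1 + #{|t_perm| >= |t_obs|}) / (1 + n_perm)` (two-sided, add-one so no
#' p is zero). With `exhaustive = TRUE` all distinct label assignments are
#' enumerated and the exact permutation p `#{|t_perm| >= |t_obs|} / n_distinct`
#' is returned (the identity assignment is included in the count).
#'
#' @param beta Beta matrix.
#' @param samples Sample sheet.
#' @param contrast A [contrast_spec()].
#' @param n_perm Number of random permutations.
#' @param seed Integer seed (required unless exhaustive).
#' @param exhaustive Enumerate all distinct assignments instead of sampling
#'   (feasible only for small groups).
#' @return Tibble with `probe_id`, `t_observed`, `p_empirical`, `n_perm`.
#' @export
permutation_pvalues <- function(beta, samples, contrast = contrast_spec(),
                                n_perm = 1000, seed = NULL,
                                exhaustive = FALSE) {
  validate_beta_matrix(beta)
  s <- contrast_samples(samples[match(colnames(beta), samples$sample_id), ],
                        contrast)
  Y <- beta[, s$sample_id, drop = FALSE]
  X <- contrast_design(s, contrast$covariates)
  t_obs <- abs(assoc_tstats(Y, X))
  n <- nrow(s)
  g_idx <- which(colnames(X) == "group")

  perm_t <- function(labels) {
    Xp <- X
    Xp[, g_idx] <- labels
    abs(assoc_tstats(Y, Xp))
  }

  if (exhaustive) {
    combos <- utils::combn(n, sum(s$.group))
    n_distinct <- ncol(combos)
    if (n_distinct > 1e5) stop_invalid("too many assignments to enumerate; use random permutations")
    count <- rep(0L, nrow(Y))
    for (j in seq_len(n_distinct)) {
      lab <- integer(n)
      lab[combos[, j]] <- 1L
      tp <- perm_t(lab)
      count <- count + as.integer(!is.na(tp) & !is.na(t_obs) & tp >= t_obs - 1e-12)
    }
    p_emp <- count / n_distinct
    p_emp[is.na(t_obs)] <- NA_real_
    return(tibble(probe_id = rownames(Y), t_observed = t_obs,
                  p_empirical = p_emp, n_perm = n_distinct))
  }

  if (n_perm < 1) stop_invalid("`n_perm` must be >= 1")
  if (n_perm < 100) warn("n_perm < 100 gives coarse empirical p-value resolution")
  if (is.null(seed)) stop_invalid("random permutations require `seed`")
  with_seed(seed, {
    count <- rep(0L, nrow(Y))
    for (j in seq_len(n_perm)) {
      tp <- perm_t(sample(s$.group))
      count <- count + as.integer(!is.na(tp) & !is.na(t_obs) & tp >= t_obs - 1e-12)
    }
    p_emp <- (1 + count) / (1 + n_perm)
    p_emp[is.na(t_obs)] <- NA_real_
    tibble(probe_id = rownames(Y), t_observed = t_obs,
           p_empirical = p_emp, n_perm = n_perm)
  })
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH with monotonicity enforcement; missing p-values are propagated
#' and the number of tests is the number of non-missing p-values.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  q <- rep(NA_real_, length(p_values))
  if (any(ok)) q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}

#' Data-dependent p-value threshold achieving an FDR target
#'
#' Returns the largest p-value among rows with q below `fdr_target` -- the
#' per-table p cutoff corresponding to, e.g., FDR < 1%.
#'
#' @param table Association table with `p_value` and `q_value`.
#' @param fdr_target FDR target (default 0.01).
#' @return The threshold p-value, or `NA` if no row passes.
#' @export
tier_thresholds <- function(table, fdr_target = 0.01) {
  pass <- !is.na(table$q_value) & table$q_value < fdr_target
  if (!any(pass)) return(NA_real_)
  max(table$p_value[pass], na.rm = TRUE)
}
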