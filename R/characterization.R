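## Shape of the association signal: QQ data, hyper/hypomethylation
## directionality across p-value bins, the biphasic p-value band, and
## enrichment of intermediate methylation among significant CpGs.

#' Expected/observed quantiles for a QQ plot
#'
#' @param p_values Non-missing p-values.
#' @return Tibble with `expected` and `observed` -log10 quantiles, sorted by
#'   significance.
#' @export
qq_data <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop_invalid("no non-missing p-values")
  n <- length(p)
  tibble(expected = -log10((seq_len(n) - 0.5) / n),
         observed = -log10(sort(p)))
}

#' Hyper/hypomethylation directionality across p-value bins
#'
#' Counts hypermethylated (delta > 0) and hypomethylated (delta < 0) CpGs
#' within bins of -log10(p) and reports the log2 hyper:hypo ratio with a
#' +0.5 continuity correction on both counts.
#'
#' @param table Association table with `delta` and `p_value`.
#' @param bin_width Bin width on the -log10(p) axis (default 1.0).
#' @return Tibble with `bin_low`, `bin_high`, `n_hyper`, `n_hypo`,
#'   `log2_ratio`.
#' @export
directionality_profile <- function(table, bin_width = 1.0) {
  d <- table |> filter(!is.na(.data$p_value), !is.na(.data$delta))
  lp <- -log10(pmax(d$p_value, .Machine$double.xmin))
  n_bins <- max(1L, ceiling(max(lp, 0) / bin_width))
  bin <- pmin(floor(lp / bin_width), n_bins - 1L)
  tibble(bin = bin, delta = d$delta) |>
    summarise(n_hyper = sum(.data$delta > 0),
              n_hypo = sum(.data$delta < 0),
              .by = "bin") |>
    right_join(tibble(bin = 0:(n_bins - 1L)), by = "bin") |>
    arrange(.data$bin) |>
    mutate(n_hyper = coalesce(.data$n_hyper, 0L),
           n_hypo = coalesce(.data$n_hypo, 0L),
           bin_low = .data$bin * bin_width,
           bin_high = (.data$bin + 1L) * bin_width,
           log2_ratio = log2((.data$n_hyper + 0.5) / (.data$n_hypo + 0.5))) |>
    select("bin_low", "bin_high", "n_hyper", "n_hypo", "log2_ratio")
}

#' Probes inside the biphasic p-value band
#'
#' Selects probes with `p_low < p < p_high` (strict on both ends), the band
#' where a second, milder phenomenon overlaps the strong primary signal.
#'
#' @param table Association table.
#' @param p_low,p_high Band limits (defaults 1e-11 and 1e-8).
#' @return The subset of `table` inside the band.
#' @export
biphasic_band <- function(table, p_low = 1e-11, p_high = 1e-8) {
  table |> filter(!is.na(.data$p_value),
                  .data$p_value > p_low, .data$p_value < p_high)
}

#' Enrichment of intermediate methylation among significant CpGs
#'
#' Compares the fraction of significant CpGs whose control-group mean lies
#' in the intermediate band (default \[0.2, 0.8\]) against the array-wide
#' fraction, with an odds ratio and Fisher p-value. Array-wide probe means
#' are bimodal, so significant sets driven by cell-mixture effects stand out
#' by their intermediate means.
#'
#' @param table Association table (all analyzed probes).
#' @param beta Beta matrix.
#' @param control_samples Sample IDs of the control group.
#' @param band Intermediate-methylation band (inclusive).
#' @param significant_probes Probe IDs of the significant set; defaults to
#'   probes with tier != "ns" in `table`.
#' @return One-row tibble with both fractions, counts, odds ratio and
#'   Fisher p (`NA` odds ratio for an empty significant set).
#' @export
intermediate_methylation_enrichment <- function(table, beta, control_samples,
                                                band = c(0.2, 0.8),
                                                significant_probes = NULL) {
  if (!length(control_samples)) stop_invalid("control group is empty")
  if (is.null(significant_probes)) {
    significant_probes <- table$probe_id[table$tier != "ns"]
  }
  probes <- intersect(table$probe_id, rownames(beta))
  m <- rowMeans(beta[probes, control_samples, drop = FALSE], na.rm = TRUE)
  in_band <- m >= band[1] & m <= band[2]
  sig <- probes %in% significant_probes
  n_sig <- sum(sig)
  frac_all <- mean(in_band, na.rm = TRUE)
  if (n_sig == 0) {
    return(tibble(n_significant = 0L, frac_significant_in_band = NA_real_,
                  frac_array_in_band = frac_all, odds_ratio = NA_real_,
                  fisher_p = NA_real_))
  }
  frac_sig <- mean(in_band[sig], na.rm = TRUE)
  # odds of the significant-set fraction against the array-wide fraction
  # (a significant set equal to the whole array gives OR exactly 1)
  odds <- function(f) f / (1 - f)
  or <- odds(frac_sig) / odds(frac_all)
  fisher_p <- if (any(!sig)) {
    tab <- matrix(c(sum(in_band & sig), sum(!in_band & sig),
                    sum(in_band & !sig), sum(!in_band & !sig)), 2)
    fisher.test(tab)$p.value
  } else 1
  tibble(n_significant = n_sig, frac_significant_in_band = frac_sig,
         frac_array_in_band = frac_all,
         odds_ratio = or, fisher_p = fisher_p)
}

#' QQ plot of association p-values
#' @param p_values Vector of p-values (or an association table).
#' @return A ggplot.
#' @export
plot_qq <- function(p_values) {
  if (is.data.frame(p_values)) p_values <- p_values$p_value
  qq <- qq_data(p_values)
  ggplot2::ggplot(qq, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' Bar plot of the hyper:hypo directionality profile
#' @param profile Output of [directionality_profile()].
#' @return A ggplot.
#' @export
plot_directionality <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes((.data$bin_low + .data$bin_high) / 2, .data$log2_ratio)) +
    ggplot2::geom_col(width = 0.8 * (profile$bin_high - profile$bin_low)[1]) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(x = expression(-log[10](p) ~ bin),
                  y = expression(log[2] ~ "hyper : hypo ratio")) +
    ggplot2::theme_minimal()
}
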