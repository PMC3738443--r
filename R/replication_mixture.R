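## Cross-cohort replication statistics, sorted-subset attenuation, and the
## compositional mixture model.
##
## A bulk case-minus-control methylation difference at a probe measured in a
## mixed cell population splits exactly into a compositional part (subtype
## fractions changed) and an intrinsic part (within-subtype methylation
## changed):
##   bulk_delta = sum_k (f_k^case - f_k^ctrl) mu_k^case   (composition)
##              + sum_k  f_k^ctrl (mu_k^case - mu_k^ctrl) (intrinsic)

#' Cross-cohort replication statistics
#'
#' Over the probes present in both tables: the fraction whose validation
#' p-value is below `alpha`, and the squared Pearson correlation of the
#' per-CpG deltas across cohorts, overall and per stratum.
#'
#' @param initial,validation Association tables from two cohorts.
#' @param alpha Validation significance level (default 0.01).
#' @param strata Optional named list of probe-ID vectors (e.g. IFN vs
#'   non-IFN).
#' @return Tibble with `stratum`, `n_tested`, `fraction_replicated`,
#'   `delta_concordance_r2`.
#' @export
replication_stats <- function(initial, validation, alpha = 0.01, strata = NULL) {
  joined <- inner_join(
    initial |> select("probe_id", delta_initial = "delta", p_initial = "p_value"),
    validation |> select("probe_id", delta_validation = "delta",
                         p_validation = "p_value"),
    by = "probe_id")
  if (!nrow(joined)) stop_invalid("no probes shared between the two cohorts")
  one <- function(d, label) {
    ok_p <- !is.na(d$p_validation)
    ok_d <- !is.na(d$delta_initial) & !is.na(d$delta_validation)
    r2 <- if (sum(ok_d) >= 3) cor(d$delta_initial[ok_d], d$delta_validation[ok_d])^2
          else NA_real_
    tibble(stratum = label, n_tested = nrow(d),
           fraction_replicated = if (any(ok_p)) mean(d$p_validation[ok_p] < alpha) else NA_real_,
           delta_concordance_r2 = r2)
  }
  out <- list(one(joined, "all"))
  for (nm in names(strata)) {
    out[[length(out) + 1L]] <- one(joined[joined$probe_id %in% strata[[nm]], ], nm)
  }
  list_rbind(out)
}

#' Bulk methylation profile of a mixture
#'
#' The bulk mean at each probe is the fraction-weighted sum of the subtype
#' profiles for the requested group.
#'
#' @param spec A [mixture_spec()].
#' @param group `"control"` or `"case"`.
#' @return Tibble with `probe_id` and `bulk_mean`.
#' @export
mixture_bulk_profile <- function(spec, group = c("control", "case")) {
  stopifnot(inherits(spec, "mixture_spec"))
  group <- match.arg(group)
  f <- spec[[paste0(group, "_fractions")]]
  if (abs(sum(f) - 1) > 1e-9) stop_invalid("subtype fractions must sum to 1")
  prof <- spec[[paste0(group, "_profiles")]]
  tibble(probe_id = rownames(prof) %||% sprintf("probe_%d", seq_len(nrow(prof))),
         bulk_mean = as.numeric(prof %*% f))
}

#' Exact compositional/intrinsic decomposition of bulk deltas
#'
#' Splits each probe's bulk case-minus-control difference into a
#' composition component `sum_k (f_k^case - f_k^ctrl) mu_k^case` and an
#' intrinsic component `sum_k f_k^ctrl (mu_k^case - mu_k^ctrl)`; the two
#' components sum to the bulk delta exactly. A probe is classified as a pure
#' type when exactly one component reaches `dominance_share` of the bulk
#' delta's magnitude, otherwise `mixed`.
#'
#' @param spec A [mixture_spec()].
#' @param dominance_share Fraction of |bulk_delta| a component must reach to
#'   be called pure (default 0.8).
#' @return Tibble with `probe_id`, `bulk_delta`, `composition_component`,
#'   `intrinsic_component`, `classification`.
#' @export
decompose_bulk_delta <- function(spec, dominance_share = 0.8) {
  stopifnot(inherits(spec, "mixture_spec"))
  f_ctrl <- spec$control_fractions
  f_case <- spec$case_fractions
  comp <- as.numeric(spec$case_profiles %*% (f_case - f_ctrl))
  intr <- as.numeric((spec$case_profiles - spec$control_profiles) %*% f_ctrl)
  bulk <- as.numeric(spec$case_profiles %*% f_case -
                       spec$control_profiles %*% f_ctrl)
  eps <- 1e-12
  zero_bulk <- abs(bulk) < eps
  if (any(zero_bulk & (abs(comp) > 1e-9 | abs(intr) > 1e-9))) {
    warn("probe(s) with cancelling components: bulk delta ~ 0 but components nonzero; classified mixed")
  }
  comp_dom <- abs(comp) >= dominance_share * abs(bulk) & !zero_bulk
  intr_dom <- abs(intr) >= dominance_share * abs(bulk) & !zero_bulk
  classification <- dplyr::case_when(
    comp_dom & !intr_dom ~ "compositional",
    intr_dom & !comp_dom ~ "intrinsic",
    .default = "mixed")
  tibble(
    probe_id = rownames(spec$case_profiles) %||%
      sprintf("probe_%d", seq_along(bulk)),
    bulk_delta = bulk, composition_component = comp,
    intrinsic_component = intr, classification = classification)
}

#' Sorted-subset attenuation of bulk associations
#'
#' For probes shared between the bulk table and every sorted-subtype table:
#' the ratio of each subtype's delta to the bulk delta. Intrinsic effects
#' persist in purified subtypes (median ratio near 1) while compositional
#' effects vanish (ratios near 0). Stratum summaries report the fraction of
#' probes replicating at `alpha` and the delta-concordance r-squared per
#' subtype.
#'
#' @param bulk Association table from the mixed population.
#' @param subsets Named list of association tables, one per sorted subtype.
#' @param strata Optional named list of probe-ID vectors.
#' @param intrinsic_min Median ratio at or above which a probe is flagged
#'   intrinsic (default 0.7).
#' @param compositional_max Median ratio at or below which a probe is
#'   flagged compositional (default 0.3).
#' @param min_bulk_delta Bulk deltas below this magnitude are excluded from
#'   ratio statistics (unstable ratios; default 0.01).
#' @param alpha Replication significance level for the summaries.
#' @return An `attenuation_report`: list with a per-probe tibble (`probes`)
#'   and a per-subset/stratum summary tibble (`summary`).
#' @export
subset_attenuation <- function(bulk, subsets, strata = NULL,
                               intrinsic_min = 0.7, compositional_max = 0.3,
                               min_bulk_delta = 0.01, alpha = 0.01) {
  common <- Reduce(intersect, c(list(bulk$probe_id),
                                map(subsets, ~ .x$probe_id)))
  if (!length(common)) stop_invalid("no probes shared between bulk and subset tables")
  b <- bulk[match(common, bulk$probe_id), ]
  ratios <- map(subsets, function(tb) {
    tb$delta[match(common, tb$probe_id)] / b$delta
  })
  ratio_mat <- do.call(cbind, ratios)
  med_ratio <- apply(ratio_mat, 1, median, na.rm = TRUE)
  unstable <- is.na(b$delta) | abs(b$delta) < min_bulk_delta
  med_ratio[unstable] <- NA_real_
  flag <- dplyr::case_when(
    unstable ~ "unstable",
    med_ratio >= intrinsic_min ~ "intrinsic",
    med_ratio <= compositional_max ~ "compositional",
    .default = "indeterminate")
  probes <- tibble(probe_id = common, bulk_delta = b$delta,
                   median_ratio = med_ratio, flag = flag) |>
    bind_cols(as_tibble(setNames(as.data.frame(ratio_mat),
                                 paste0("ratio_", names(subsets)))))

  summaries <- imap(subsets, function(tb, nm) {
    replication_stats(b, tb, alpha = alpha, strata = strata) |>
      mutate(subset = nm, .before = 1)
  }) |> list_rbind()

  structure(list(probes = probes, summary = summaries),
            class = "attenuation_report")
}

#' @export
print.attenuation_report <- function(x, ...) {
  cat("Sorted-subset attenuation report\n")
  cat(sprintf("  probes: %d (%s)\n", nrow(x$probes),
              paste(sprintf("%s: %d", names(table(x$probes$flag)),
                            table(x$probes$flag)), collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' Tidy an attenuation report (per-probe rows)
#' @param x An `attenuation_report`.
#' @param ... Unused.
#' @method tidy attenuation_report
#' @export
tidy.attenuation_report <- function(x, ...) x$probes

#' @rdname tidy.attenuation_report
#' @method glance attenuation_report
#' @export
glance.attenuation_report <- function(x, ...) x$summary

#' Scatter plot of initial vs validation deltas
#' @param initial,validation Association tables.
#' @param highlight Optional probe IDs drawn in red (e.g. IFN probes).
#' @return A ggplot.
#' @export
plot_delta_concordance <- function(initial, validation, highlight = NULL) {
  d <- inner_join(initial |> select("probe_id", x = "delta"),
                  validation |> select("probe_id", y = "delta"),
                  by = "probe_id") |>
    mutate(highlighted = .data$probe_id %in% (highlight %||% character()))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$highlighted)) +
    ggplot2::geom_point(size = 0.7, show.legend = !is.null(highlight)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "initial-cohort delta", y = "validation-cohort delta",
                  colour = "highlighted") +
    ggplot2::theme_minimal()
}
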