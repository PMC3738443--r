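## Quality-control filtering cascade over beta and detection matrices.
##
## Fixed cascade order: detection-p masking -> sample missingness filter
## (computed over autosomal probes, before any probe removal) -> probe
## failure filter -> blacklist removal. Thresholds use strict inequalities
## ("greater than" / "more than"). No value is ever altered, only masked or
## removed, so the cascade is idempotent.

#' Mask beta values whose detection p-value exceeds a threshold
#'
#' Entries with detection p > `threshold` (default 0.01) are set to missing;
#' all other entries pass through unchanged.
#'
#' @param beta Beta matrix.
#' @param det Detection p-value matrix, shape-aligned with `beta`.
#' @param threshold Detection p-value cutoff (strict).
#' @return Beta matrix with failed cells set to `NA`.
#' @export
mask_by_detection <- function(beta, det, threshold = 0.01) {
  validate_beta_matrix(beta)
  validate_beta_matrix(det, what = "detection p-value")
  if (!identical(dim(beta), dim(det)) ||
      !identical(rownames(beta), rownames(det)) ||
      !identical(colnames(beta), colnames(det))) {
    stop_invalid("beta and detection matrices must be shape-aligned with identical dimnames")
  }
  beta[!is.na(det) & det > threshold] <- NA_real_
  beta
}

#' Identify autosomal probes in a manifest
#' @param manifest Probe manifest tibble.
#' @return Character vector of autosomal probe IDs.
#' @export
autosomal_probe_ids <- function(manifest) {
  sex_chroms <- c("chrX", "chrY", "X", "Y")
  manifest$probe_id[!manifest$chromosome %in% sex_chroms]
}

#' Remove samples with excessive missing data
#'
#' A sample is removed iff its missing fraction over the autosomal probes
#' present in `beta` is strictly greater than `max_missing_fraction`.
#'
#' @param beta Beta matrix (detection-masked).
#' @param max_missing_fraction Removal threshold (default 0.015).
#' @param autosomal_probes Probe IDs over which missingness is computed.
#' @return List with the filtered `beta` and a `removed` tibble
#'   (`sample_id`, `missing_fraction`).
#' @export
filter_samples <- function(beta, max_missing_fraction = 0.015,
                           autosomal_probes = rownames(beta)) {
  keep_probes <- intersect(rownames(beta), autosomal_probes)
  if (!length(keep_probes)) stop_invalid("no autosomal probes available for sample filtering")
  frac <- colMeans(is.na(beta[keep_probes, , drop = FALSE]))
  drop <- frac > max_missing_fraction
  list(
    beta = beta[, !drop, drop = FALSE],
    removed = tibble(sample_id = colnames(beta)[drop],
                     missing_fraction = unname(frac[drop]))
  )
}

#' Remove probes that failed in too many samples
#'
#' A probe is removed iff its missing fraction over the retained samples is
#' strictly greater than `max_fail_fraction`.
#'
#' @param beta Beta matrix (sample-filtered).
#' @param max_fail_fraction Removal threshold (default 0.10).
#' @return List with the filtered `beta` and a `removed` tibble
#'   (`probe_id`, `fail_fraction`).
#' @export
filter_probes <- function(beta, max_fail_fraction = 0.10) {
  frac <- rowMeans(is.na(beta))
  drop <- frac > max_fail_fraction
  list(
    beta = beta[!drop, , drop = FALSE],
    removed = tibble(probe_id = rownames(beta)[drop],
                     fail_fraction = unname(frac[drop]))
  )
}

#' Remove blacklisted probes; count (but keep) SNP-flagged probes
#'
#' Probes flagged as multi-mapping/mis-mapping in the manifest are removed.
#' Probes overlapping known SNPs are retained but counted, mirroring the
#' convention of flagging without filtering.
#'
#' @param beta Beta matrix.
#' @param manifest Probe manifest covering every probe in `beta`.
#' @return List with the filtered `beta`, `blacklist_removed` count and
#'   `snp_flagged` count.
#' @export
apply_blacklist <- function(beta, manifest) {
  missing_probes <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing_probes)) {
    stop_invalid(sprintf("%d probe(s) absent from manifest (e.g. %s)",
                         length(missing_probes), missing_probes[1]))
  }
  info <- manifest[match(rownames(beta), manifest$probe_id), ]
  drop <- info$blacklist_flag
  list(
    beta = beta[!drop, , drop = FALSE],
    blacklist_removed = sum(drop),
    snp_flagged = sum(info$snp_flag & !drop)
  )
}

#' Run the full QC cascade
#'
#' Detection mask, then sample filter (missingness over autosomal probes),
#' then probe filter, then blacklist removal.
#'
#' @param beta Beta matrix.
#' @param det Detection p-value matrix.
#' @param manifest Probe manifest.
#' @param det_threshold Detection p cutoff.
#' @param max_sample_missing Sample missing-fraction cutoff.
#' @param max_probe_fail Probe failure-fraction cutoff.
#' @return List with the filtered `beta` and a `report` of class
#'   `qc_report` (masked-cell count, removed samples/probes with their
#'   fractions, blacklist and SNP-flag counts).
#' @export
run_qc <- function(beta, det, manifest, det_threshold = 0.01,
                   max_sample_missing = 0.015, max_probe_fail = 0.10) {
  n_missing_before <- sum(is.na(beta))
  masked <- mask_by_detection(beta, det, det_threshold)
  masked_cells <- sum(is.na(masked)) - n_missing_before
  s <- filter_samples(masked, max_sample_missing,
                      autosomal_probes = autosomal_probe_ids(manifest))
  p <- filter_probes(s$beta, max_probe_fail)
  b <- apply_blacklist(p$beta, manifest)
  report <- structure(
    list(masked_cell_count = masked_cells,
         removed_samples = s$removed,
         removed_probes = p$removed,
         blacklist_removed = b$blacklist_removed,
         snp_flagged = b$snp_flagged,
         dim_in = dim(beta), dim_out = dim(b$beta)),
    class = "qc_report")
  list(beta = b$beta, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  input:  %d probes x %d samples\n", x$dim_in[1], x$dim_in[2]))
  cat(sprintf("  masked cells (detection p): %d\n", x$masked_cell_count))
  cat(sprintf("  samples removed (missingness): %d\n", nrow(x$removed_samples)))
  cat(sprintf("  probes removed (failure): %d\n", nrow(x$removed_probes)))
  cat(sprintf("  probes removed (blacklist): %d\n", x$blacklist_removed))
  cat(sprintf("  SNP-flagged probes retained: %d\n", x$snp_flagged))
  cat(sprintf("  output: %d probes x %d samples\n", x$dim_out[1], x$dim_out[2]))
  invisible(x)
}

#' Tidy a QC report into a one-row summary tibble
#' @param x A `qc_report`.
#' @param ... Unused.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble(masked_cell_count = x$masked_cell_count,
         n_samples_removed = nrow(x$removed_samples),
         n_probes_failed = nrow(x$removed_probes),
         blacklist_removed = x$blacklist_removed,
         snp_flagged = x$snp_flagged,
         n_probes_out = x$dim_out[1], n_samples_out = x$dim_out[2])
}
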