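## CpG-to-gene mapping, cross-cell-type gene classification, and gene-set
## enrichment by one-sided Fisher's exact test.

#' Map CpGs to nearby genes
#'
#' A probe is assigned to every gene whose interval, extended by `window_bp`
#' on both sides, contains the probe position. Probes may map to several
#' genes or to none. Gene intervals are 0-based half-open (BED convention);
#' probe positions are 1-based. Strand is ignored.
#'
#' @param manifest Probe manifest (`probe_id`, `chromosome`, `position`).
#' @param genes Gene annotation tibble from [read_bed()].
#' @param window_bp Window on each side of the gene body (default 5000).
#' @return Tibble with `probe_id`, `gene_symbol` (one row per mapping).
#' @export
map_cpgs_to_genes <- function(manifest, genes, window_bp = 5000) {
  shared <- intersect(unique(manifest$chromosome), unique(genes$chromosome))
  if (!length(shared)) {
    warn(sprintf("no shared chromosomes between manifest (%d probes) and annotation; nothing mapped",
                 nrow(manifest)))
    return(tibble(probe_id = character(), gene_symbol = character()))
  }
  unmapped_chroms <- setdiff(unique(manifest$chromosome), unique(genes$chromosome))
  if (length(unmapped_chroms)) {
    n_un <- sum(manifest$chromosome %in% unmapped_chroms)
    warn(sprintf("%d probe(s) on chromosome(s) absent from the gene annotation (%s)",
                 n_un, paste(head(unmapped_chroms, 3), collapse = ", ")))
  }
  # 0-based half-open [start - w, end + w) -> 1-based closed [start - w + 1, end + w]
  gene_gr <- GenomicRanges::GRanges(
    genes$chromosome,
    IRanges::IRanges(start = pmax(genes$start - window_bp + 1L, 1L),
                     end = genes$end + window_bp))
  probe_gr <- GenomicRanges::GRanges(
    manifest$chromosome,
    IRanges::IRanges(start = manifest$position, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(probe_gr, gene_gr))
  tibble(probe_id = manifest$probe_id[S4Vectors::queryHits(hits)],
         gene_symbol = genes$gene_symbol[S4Vectors::subjectHits(hits)]) |>
    distinct()
}

#' Classify genes by cross-cell-type significance
#'
#' Per gene and cell type, the best mapped CpG determines the status:
#' `highly` (best p < 1e-8), `moderate` (best q < 0.01), else `ns`.
#' Categories: `shared_all` (highly in every cell type), `shared_relaxed`
#' (highly in at least one and at least moderate in all others),
#' `cell_type_specific` (highly in exactly one, ns in all others), `none`
#' otherwise.
#'
#' @param tables Named list of association tables, one per cell type.
#' @param mapping Probe-to-gene mapping from [map_cpgs_to_genes()].
#' @return Tibble with `gene_symbol`, one `status_<cell_type>` column per
#'   cell type, and `category`.
#' @export
classify_genes <- function(tables, mapping) {
  if (!length(tables)) stop_invalid("need at least one cell type")
  if (is.null(names(tables))) names(tables) <- paste0("cell", seq_along(tables))
  status <- imap(tables, function(tb, ct) {
    tb |>
      inner_join(mapping, by = "probe_id") |>
      summarise(
        status = dplyr::case_when(
          any(!is.na(.data$p_value) & .data$p_value < 1e-8) ~ "highly",
          any(!is.na(.data$q_value) & .data$q_value < 0.01) ~ "moderate",
          .default = "ns"),
        .by = "gene_symbol") |>
      mutate(cell_type = ct)
  }) |> list_rbind()
  wide <- status |>
    pivot_wider(names_from = "cell_type", values_from = "status",
                names_prefix = "status_") |>
    mutate(across(starts_with("status_"), ~ coalesce(.x, "ns")))
  st <- as.matrix(wide[, paste0("status_", names(tables)), drop = FALSE])
  n_high <- rowSums(st == "highly")
  n_ns <- rowSums(st == "ns")
  k <- length(tables)
  wide$category <- dplyr::case_when(
    n_high == k ~ "shared_all",
    n_high >= 1 & n_ns == 0 ~ "shared_relaxed",
    n_high == 1 & n_ns == k - 1 ~ "cell_type_specific",
    .default = "none")
  wide
}

#' Rank the top-k probes of an association table
#'
#' Ranked by ascending p-value; ties broken by descending |delta|, then
#' lexicographic probe ID.
#'
#' @param table Association table.
#' @param k Number of probes (default 100).
#' @return Character vector of probe IDs.
#' @export
top_k_probes <- function(table, k = 100) {
  if (!nrow(table)) stop_invalid("association table is empty")
  if (k > nrow(table)) {
    warn(sprintf("k = %d exceeds table size %d; returning all probes", k, nrow(table)))
    k <- nrow(table)
  }
  table |>
    filter(!is.na(.data$p_value)) |>
    arrange(.data$p_value, dplyr::desc(abs(.data$delta)), .data$probe_id) |>
    head(k) |>
    pull("probe_id")
}

#' Gene-set enrichment of a top-probe list
#'
#' A probe "hits" a set if it maps to at least one member gene. Fold
#' enrichment is the hit fraction in the top list over the hit fraction in
#' the background (which includes the top list); significance is a
#' one-sided (enrichment) Fisher's exact test on top-vs-rest x hit-vs-nonhit.
#'
#' @param top_probes Character vector of top probe IDs.
#' @param mapping Probe-to-gene mapping.
#' @param gene_sets Long tibble (`set_name`, `gene_symbol`) from
#'   [read_gmt()], or a character vector of gene symbols (a single unnamed
#'   set).
#' @param background Character vector of all analyzable probe IDs (must
#'   include `top_probes`).
#' @return Tibble, one row per set: counts, `fold_enrichment` (`NA` when the
#'   background hit fraction is zero) and `fisher_p`.
#' @export
gene_set_enrichment <- function(top_probes, mapping, gene_sets, background) {
  if (!all(top_probes %in% background)) {
    stop_invalid("`background` must include every top probe")
  }
  if (is.character(gene_sets)) {
    gene_sets <- tibble(set_name = "set", gene_symbol = unique(gene_sets))
  }
  n_top <- length(top_probes)
  n_bg <- length(background)
  sets <- split(gene_sets$gene_symbol, gene_sets$set_name)
  imap(sets, function(set_genes, nm) {
    hit_probes <- unique(mapping$probe_id[mapping$gene_symbol %in% set_genes])
    hits_top <- sum(top_probes %in% hit_probes)
    hits_bg <- sum(background %in% hit_probes)
    rest_hits <- hits_bg - hits_top
    fold <- if (hits_bg == 0) NA_real_ else (hits_top / n_top) / (hits_bg / n_bg)
    tab <- matrix(c(hits_top, n_top - hits_top,
                    rest_hits, (n_bg - n_top) - rest_hits), 2, byrow = TRUE)
    p <- fisher.test(tab, alternative = "greater")$p.value
    tibble(set_name = nm, n_top = n_top, hits_top = hits_top,
           n_background = n_bg, hits_background = hits_bg,
           fold_enrichment = fold, fisher_p = p)
  }) |> list_rbind()
}
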