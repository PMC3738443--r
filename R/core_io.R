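## Data model and readers/writers for the tabular inputs and outputs.
##
## The probe-by-sample container for beta scores and detection p-values is a
## plain numeric matrix with probe IDs as rownames and sample IDs as colnames
## (the standard container for array methylation data). Everything else --
## manifests, sample sheets, gene annotation, gene sets -- is a tibble.

.na_tokens <- c("", "NA", "NaN")

#' Construct and validate a beta-score matrix
#'
#' A beta matrix is a numeric matrix of methylation proportions with unique
#' probe IDs as rownames and unique sample IDs as colnames. Non-missing
#' values must lie in \[0, 1\]. The same container (with the same constraints)
#' holds detection p-values.
#'
#' @param values Numeric matrix, probes in rows, samples in columns.
#' @param probe_ids,sample_ids Optional identifier vectors; taken from the
#'   dimnames of `values` when omitted.
#' @return The validated matrix (invisibly unchanged apart from dimnames).
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- probe_ids
  colnames(values) <- sample_ids
  validate_beta_matrix(values)
  values
}

#' @rdname beta_matrix
#' @param x Matrix to validate.
#' @param what Label used in error messages ("beta" or "detection p-value").
#' @export
validate_beta_matrix <- function(x, what = "beta") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid(sprintf("%s matrix must be a numeric matrix", what))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_invalid(sprintf("%s matrix must carry probe rownames and sample colnames", what))
  }
  if (anyDuplicated(rownames(x))) {
    stop_format(sprintf("duplicate probe IDs in %s matrix: %s", what,
                        paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    stop_format(sprintf("duplicate sample IDs in %s matrix: %s", what,
                        paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")))
  }
  bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop_invalid(sprintf(
      "%s value %.6g outside [0, 1] at probe '%s', sample '%s' (%d offending cell%s)",
      what, x[i, j], rownames(x)[i], colnames(x)[j], nrow(bad),
      if (nrow(bad) == 1) "" else "s"))
  }
  invisible(x)
}

# full-precision numeric formatting so write -> read round-trips bit-exactly
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read a beta-score (or detection p-value) matrix from TSV
#'
#' Expects a tab-delimited file with probe IDs in the first column and a
#' header row of sample IDs. Blank fields, `NA` and `NaN` are read as
#' missing. Values outside \[0, 1\] are rejected with the offending
#' probe/sample coordinates.
#'
#' @param path File path.
#' @param what Label used in validation messages.
#' @return Numeric matrix (probes x samples).
#' @export
read_beta_matrix <- function(path, what = "beta") {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) {
    stop_format("matrix file needs a probe ID column plus >=1 sample column")
  }
  # base parser: strtod round-trips doubles written at full precision exactly
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", na.strings = .na_tokens,
                      check.names = FALSE, quote = "",
                      colClasses = c("character",
                                     rep("numeric", length(header) - 1L))),
    error = function(e) stop_format(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e))))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  validate_beta_matrix(m, what = what)
  m
}

#' @rdname read_beta_matrix
#' @export
read_detection_matrix <- function(path) read_beta_matrix(path, what = "detection p-value")

#' Write a beta-score matrix as TSV
#'
#' Values are written at full double precision so a write/read round-trip is
#' the identity; missing entries are written as `NA`.
#'
#' @param x Beta matrix.
#' @param path Output path.
#' @param id_column Name of the probe ID column in the header.
#' @export
write_beta_matrix <- function(x, path, id_column = "probe_id") {
  validate_beta_matrix(x)
  chr <- matrix(.fmt_num(x), nrow = nrow(x))
  lines <- c(
    paste(c(id_column, colnames(x)), collapse = "\t"),
    paste(rownames(x), apply(chr, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe manifest
#'
#' TSV with columns `probe_id`, `chemistry` (I or II), `chromosome`,
#' `position` (1-based), and optional logical `blacklist_flag` / `snp_flag`
#' columns (absent columns default to `FALSE`).
#'
#' @param path File path.
#' @return Tibble with one row per probe.
#' @export
read_manifest <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), na = .na_tokens,
                        progress = FALSE)
  need <- c("probe_id", "chemistry", "chromosome", "position")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_format(paste0("manifest missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"blacklist_flag" %in% names(df)) df$blacklist_flag <- FALSE
  if (!"snp_flag" %in% names(df)) df$snp_flag <- FALSE
  df <- df |>
    mutate(
      probe_id = as.character(.data$probe_id),
      chemistry = as.character(.data$chemistry),
      chromosome = as.character(.data$chromosome),
      position = as.integer(.data$position),
      blacklist_flag = as.logical(.data$blacklist_flag),
      snp_flag = as.logical(.data$snp_flag)
    ) |>
    select(all_of(c(need, "blacklist_flag", "snp_flag")))
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest Manifest tibble to validate.
#' @export
validate_manifest <- function(manifest) {
  if (anyDuplicated(manifest$probe_id)) stop_format("duplicate probe IDs in manifest")
  bad_chem <- setdiff(unique(manifest$chemistry), c("I", "II"))
  if (length(bad_chem)) {
    stop_format(paste0("unknown chemistry code(s): ", paste(bad_chem, collapse = ", ")))
  }
  if (any(is.na(manifest$position) | manifest$position < 1)) {
    stop_format("manifest positions must be integers >= 1")
  }
  as_tibble(manifest)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `disease` (case/control), `activity`
#' (flare/quiescent/none), `age`, `sex` (F/M), `ethnicity`, `cell_type`,
#' `batch_id`.
#'
#' @param path File path.
#' @return Tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), na = .na_tokens,
                        progress = FALSE)
  need <- c("sample_id", "disease", "activity", "age", "sex", "ethnicity",
            "cell_type", "batch_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_format(paste0("sample sheet missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- df |>
    mutate(across(all_of(setdiff(need, "age")), as.character),
           age = as.numeric(.data$age)) |>
    select(all_of(need))
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param samples Sample-sheet tibble to validate.
#' @export
validate_sample_sheet <- function(samples) {
  if (anyDuplicated(samples$sample_id)) stop_format("duplicate sample IDs in sample sheet")
  if (!all(samples$disease %in% c("case", "control"))) {
    stop_format("disease must be 'case' or 'control'")
  }
  if (!all(samples$activity %in% c("flare", "quiescent", "none"))) {
    stop_format("activity must be 'flare', 'quiescent' or 'none'")
  }
  if (!all(samples$sex %in% c("F", "M"))) stop_format("sex must be 'F' or 'M'")
  if (any(is.na(samples$age) | samples$age <= 0)) stop_invalid("age must be > 0")
  if (any(is.na(samples$batch_id) | samples$batch_id == "")) {
    stop_invalid("every sample needs a batch_id")
  }
  as_tibble(samples)
}

#' Read gene sets from a GMT file
#'
#' One set per line: set name, description, then member gene symbols,
#' tab-separated. Returned in long form.
#'
#' @param path File path.
#' @return Tibble with columns `set_name`, `gene_symbol`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_format("empty GMT file")
  sets <- map(lines, function(ln) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) stop_format("GMT line needs name, description and >=1 gene")
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_format(sprintf("gene set '%s' is empty", fields[1]))
    tibble(set_name = fields[1], gene_symbol = genes)
  })
  list_rbind(sets)
}

#' Write gene sets to GMT
#' @param gene_sets Long tibble (`set_name`, `gene_symbol`).
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(gene_sets, path, description = ".") {
  lines <- gene_sets |>
    summarise(line = paste(c(.data$set_name[1], description, .data$gene_symbol),
                           collapse = "\t"),
              .by = "set_name") |>
    pull("line")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation from BED4+
#'
#' BED is already 0-based half-open; intervals are stored as-is (`start`,
#' `end` with `start < end`). Column 4 is taken as the gene symbol; column 6,
#' when present, as the strand (otherwise `*`). Strand is stored but ignored
#' by proximity computations.
#'
#' @param path File path.
#' @return Tibble with columns `gene_symbol`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) stop_format("empty BED file")
  rows <- map(lines, function(ln) {
    fields <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(fields) < 4) stop_format("BED line needs chrom, start, end, name")
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end)) stop_format(sprintf("malformed coordinates: '%s'", ln))
    tibble(gene_symbol = fields[4], chromosome = fields[1],
           start = start, end = end,
           strand = if (length(fields) >= 6) fields[6] else "*")
  })
  out <- list_rbind(rows)
  validate_gene_annotation(out)
}

#' @rdname read_bed
#' @param genes Gene-annotation tibble to validate.
#' @export
validate_gene_annotation <- function(genes) {
  if (any(genes$start >= genes$end)) {
    stop_invalid("gene intervals must satisfy start < end (0-based half-open)")
  }
  if (any(genes$start < 0)) stop_invalid("BED start must be >= 0")
  as_tibble(genes)
}

#' @rdname read_bed
#' @param path Output path.
#' @export
write_bed <- function(genes, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chromosome, genes$start,
                   genes$end, genes$gene_symbol, genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe blacklist (one probe ID per line)
#' @param path File path.
#' @return Character vector of probe IDs.
#' @export
read_blacklist <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}

#' Write a generic result tibble as TSV (stable column order, full precision)
#' @param x Tibble.
#' @param path Output path.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}
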