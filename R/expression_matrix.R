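# ExpressionMatrix: the normalized log2 probe-by-sample matrix plus the study
# design (sample sheet). Normalization (RMA-type background correction,
# quantile normalization) happens upstream; values arrive on the instrument
# log2 scale, which for the arrays modelled here spans 3 to 15.

INTENSITY_RANGE <- c(3, 15)

#' Construct an ExpressionMatrix
#'
#' Bundles a log2 probe-by-sample intensity matrix with its sample sheet and
#' validates the study-design invariants: unique probe and sample ids, no
#' missing values, intensities within the instrument range \[3, 15\], and a
#' resolvable matched-control group (within the same batch) for every treated
#' sample.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids); log2 intensities.
#' @param sample_sheet data frame with columns `sample_id`, `compound`
#'   (`"control"` for control samples), `replicate` (integer), `batch`
#'   (`"training"` or `"testing"`) and `control_group` (key linking treated
#'   samples to their matched controls).
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` and `sample_sheet` (rows ordered as the matrix columns).
#' @export
expression_matrix <- function(values, sample_sheet) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_format("`values` must carry probe ids (rownames) and sample ids (colnames)")
  need <- c("sample_id", "compound", "replicate", "batch", "control_group")
  miss <- setdiff(need, names(sample_sheet))
  if (length(miss))
    stop_format("sample sheet lacks column(s): %s", paste(miss, collapse = ", "))
  sample_sheet <- as.data.frame(sample_sheet, stringsAsFactors = FALSE)
  sample_sheet$sample_id <- as.character(sample_sheet$sample_id)

  if (anyDuplicated(rownames(values)))
    stop_format("duplicated probe ids")
  if (anyDuplicated(colnames(values)))
    stop_format("duplicated sample ids")
  if (anyDuplicated(sample_sheet$sample_id))
    stop_format("duplicated sample ids in sample sheet")
  if (!setequal(colnames(values), sample_sheet$sample_id))
    stop_format("sample sheet and matrix columns disagree: design error")
  sample_sheet <- sample_sheet[match(colnames(values), sample_sheet$sample_id), ,
                               drop = FALSE]
  rownames(sample_sheet) <- NULL
  if (anyNA(values))
    stop_format("missing values in expression matrix")
  if (min(values) < INTENSITY_RANGE[1] || max(values) > INTENSITY_RANGE[2])
    stop_format("intensities outside the log2 instrument range [%g, %g]",
                INTENSITY_RANGE[1], INTENSITY_RANGE[2])

  treated <- sample_sheet[sample_sheet$compound != "control", , drop = FALSE]
  ctrl <- sample_sheet[sample_sheet$compound == "control", , drop = FALSE]
  for (i in seq_len(nrow(treated))) {
    ok <- ctrl$control_group == treated$control_group[i] &
      ctrl$batch == treated$batch[i]
    if (!any(ok))
      stop_format(
        "design error: sample '%s' (group '%s', batch '%s') has no matched control",
        treated$sample_id[i], treated$control_group[i], treated$batch[i])
  }
  structure(list(values = values, sample_sheet = sample_sheet),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  sh <- x$sample_sheet
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  compounds: %s\n",
              paste(setdiff(unique(sh$compound), "control"), collapse = ", ")))
  cat(sprintf("  controls: %d in %d group(s); batches: %s\n",
              sum(sh$compound == "control"),
              length(unique(sh$control_group[sh$compound == "control"])),
              paste(unique(sh$batch), collapse = ", ")))
  invisible(x)
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix file is tab-separated with the probe id in the first column and
#' one column per sample; the sheet is tab-separated with columns
#' `sample_id`, `compound`, `replicate`, `batch`, `control_group`.
#'
#' @param path matrix TSV
#' @param sheet_path sample-sheet TSV
#' @return a validated [expression_matrix()]
#' @export
read_expression_matrix <- function(path, sheet_path) {
  tab <- read_tsv(path)
  if (ncol(tab) < 2) stop_format("matrix file needs a probe column plus samples")
  probes <- as.character(tab[[1]])
  if (anyDuplicated(probes)) stop_format("duplicated probe ids in %s", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  sheet <- read_tsv(sheet_path)
  expression_matrix(m, sheet)
}

#' Write an expression matrix and sample sheet to TSV files
#'
#' Intensities are written with 6 decimals; [read_expression_matrix()] on the
#' output reproduces the object to that precision.
#'
#' @param em an `ExpressionMatrix`
#' @param path matrix TSV destination
#' @param sheet_path sample-sheet TSV destination
#' @return invisibly, `path`
#' @export
write_expression_matrix <- function(em, path, sheet_path) {
  df <- data.frame(probe_id = rownames(em$values),
                   em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv6(df, path)
  write_tsv6(em$sample_sheet, sheet_path)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Tab-separated, columns `probe_id` and `gene` (optional `description`).
#' Probes with an empty or missing gene symbol are assigned the sentinel
#' `"unannotated"`; gene-level operations document how they treat it.
#'
#' @param path annotation TSV
#' @return data frame with columns `probe_id`, `gene` (and `description` if
#'   present)
#' @export
read_probe_annotation <- function(path) {
  ann <- read_tsv(path)
  if (!all(c("probe_id", "gene") %in% names(ann)))
    stop_format("annotation needs columns probe_id and gene")
  probe_annotation(ann$probe_id, ann$gene,
                   if ("description" %in% names(ann)) ann$description else NULL)
}

#' Construct a probe annotation table
#'
#' @param probe_id character vector of probe ids (unique)
#' @param gene character vector of gene symbols; `NA`/empty become
#'   `"unannotated"`
#' @param description optional character vector
#' @return data frame with class `ProbeAnnotation` prepended
#' @export
probe_annotation <- function(probe_id, gene, description = NULL) {
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) stop_format("duplicated probe ids in annotation")
  gene <- as.character(gene)
  gene[is.na(gene) | gene == ""] <- "unannotated"
  ann <- data.frame(probe_id = probe_id, gene = gene, stringsAsFactors = FALSE)
  if (!is.null(description)) ann$description <- as.character(description)
  class(ann) <- c("ProbeAnnotation", "data.frame")
  ann
}

# gene symbols for a probe vector, in probe order; unmapped -> "unannotated"
probe_genes <- function(probes, annotation) {
  g <- annotation$gene[match(probes, annotation$probe_id)]
  g[is.na(g)] <- "unannotated"
  g
}
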