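# Six-axis toxicity profiles. Each compound is summarised by the counts of
# up- and downregulated DEG and of enriched (filtered) GO terms and KEGG
# pathways per direction; axes are normalized to the study-wide maximum so
# every axis lies in [0, 1], and the ToxPi score is the weighted mean of the
# normalized axes with the GO and KEGG slices double-weighted relative to
# DEG (the two DEG slices then carry 20% of the total weight).

TOX_AXES <- c("deg_up", "deg_down", "go_up", "go_down", "kegg_up", "kegg_down")
TOXPI_WEIGHTS <- c(deg_up = 1, deg_down = 1, go_up = 2, go_down = 2,
                   kegg_up = 2, kegg_down = 2)

#' Build the raw and normalized toxicity-profile axes
#'
#' @param counts data frame with column `compound` and the six axis columns
#'   `deg_up`, `deg_down`, `go_up`, `go_down`, `kegg_up`, `kegg_down`
#'   (counts of DEG and of filtered enriched terms), all compounds processed
#'   with identical thresholds
#' @param norm_by `"axis"`: each of the six axes normalized to its own
#'   study-wide maximum (default); `"category"`: one maximum per category
#'   (DEG, GO, KEGG) shared by both directions
#' @return object of class `ToxProfile`: list with `raw` (the input),
#'   `maxima`, and `normalized` (compound x axis matrix in \[0, 1\]; axes
#'   with maximum 0 normalize to 0)
#' @export
build_axes <- function(counts, norm_by = c("axis", "category")) {
  norm_by <- match.arg(norm_by)
  miss <- setdiff(c("compound", TOX_AXES), names(counts))
  if (length(miss))
    stop_format("counts lack column(s): %s", paste(miss, collapse = ", "))
  raw <- as.matrix(counts[, TOX_AXES])
  rownames(raw) <- counts$compound
  if (norm_by == "axis") {
    maxima <- apply(raw, 2, max)
  } else {
    cat_max <- c(deg = max(raw[, c("deg_up", "deg_down")]),
                 go = max(raw[, c("go_up", "go_down")]),
                 kegg = max(raw[, c("kegg_up", "kegg_down")]))
    maxima <- cat_max[c("deg", "deg", "go", "go", "kegg", "kegg")]
    names(maxima) <- TOX_AXES
  }
  normalized <- sweep(raw, 2, ifelse(maxima > 0, maxima, 1), "/")
  normalized[, maxima == 0] <- 0
  structure(list(raw = counts, maxima = maxima, normalized = normalized,
                 norm_by = norm_by),
            class = "ToxProfile")
}

#' @export
print.ToxProfile <- function(x, ...) {
  cat(sprintf("ToxProfile: %d compounds x %d axes (normalized by %s maxima)\n",
              nrow(x$normalized), ncol(x$normalized), x$norm_by))
  print(round(x$normalized, 3))
  invisible(x)
}

#' ToxPi score of a profile
#'
#' Weighted mean of the normalized axes: `sum(w * norm) / sum(w)`. With the
#' default weights (1, 1, 2, 2, 2, 2) the two DEG axes carry 20% of the
#' total weight and GO/KEGG 80%.
#'
#' @param profile a `ToxProfile` (or a compound x axis matrix of normalized
#'   values)
#' @param weights axis weights, same length as the number of axes
#' @return named numeric vector of per-compound scores in \[0, 1\]
#' @export
toxpi_score <- function(profile, weights = TOXPI_WEIGHTS) {
  norm <- if (inherits(profile, "ToxProfile")) profile$normalized else profile
  if (length(weights) != ncol(norm))
    stop_format("need %d weights, got %d", ncol(norm), length(weights))
  drop(norm %*% weights) / sum(weights)
}

#' Distribution of enriched terms over superordinate process classes
#'
#' Tallies unique enriched terms per superordinate biological process class
#' (migration/adhesion, metabolism, differentiation, signalling, stress
#' response, other), the numbers shown in the ring summaries. Terms missing
#' from the mapping fall into `"other"`.
#'
#' @param rows enrichment rows (typically pooled elim results after
#'   [apply_report_filter()])
#' @param mapping data frame with columns `term_id` and `class`
#' @return list with `tally` (named integer vector over the six classes)
#'   and `terms` (list of term ids per class)
#' @export
superordinate_distribution <- function(rows, mapping) {
  terms <- unique(rows$term_id)
  cls <- mapping$class[match(terms, mapping$term_id)]
  cls[is.na(cls)] <- "other"
  cls[!cls %in% SUPERORDINATE_CLASSES] <- "other"
  tally <- vapply(SUPERORDINATE_CLASSES, function(cl) sum(cls == cl), integer(1))
  list(tally = tally,
       terms = setNames(lapply(SUPERORDINATE_CLASSES,
                               function(cl) terms[cls == cl]),
                        SUPERORDINATE_CLASSES))
}

#' Keyword-based default superordinate mapping
#'
#' Assigns terms to the six superordinate classes by keyword match on the
#' term name (e.g. "adhesion"/"migration" to migration/adhesion, "metabol"
#' to metabolism); anything unmatched goes to "other". A curated mapping
#' table is preferable when available — this default only stands in for one.
#'
#' @param term_ids character vector of term ids
#' @param term_names character vector of term names (same length)
#' @return data frame `term_id`, `class`
#' @export
default_superordinate_map <- function(term_ids, term_names) {
  patterns <- list(
    "migration/adhesion" = "migration|adhesion|motility|locomotion",
    "metabolism" = "metabol|biosynth|catabol|glycolysis|oxidation",
    "differentiation" = "differentiation|development|morphogenesis|fate",
    "signalling" = "signal|receptor|kinase|second messenger|cAMP|cGMP|calcium",
    "stress response" = "stress|death|apoptosis|inflammation|immune|wounding")
  cls <- rep("other", length(term_ids))
  for (cl in names(patterns)) {
    hit <- grepl(patterns[[cl]], term_names, ignore.case = TRUE) & cls == "other"
    cls[hit] <- cl
  }
  data.frame(term_id = term_ids, class = cls, stringsAsFactors = FALSE)
}

#' Polar coordinates for spider/ToxPi rendering
#'
#' Slice widths are proportional to the axis weights; the radius of each
#' slice is the normalized axis value. Coordinates of the slice midpoint are
#' exported for plotting; a unit profile with equal weights yields the
#' vertices of a regular polygon.
#'
#' @param profile a `ToxProfile`
#' @param weights axis weights (slice widths)
#' @param path optional JSON destination (written via jsonlite with full
#'   precision)
#' @return named list per compound of data frames `axis`, `weight`,
#'   `radius`, `angle_start`, `angle_mid`, `angle_end`, `x`, `y`
#' @export
export_radar <- function(profile, weights = TOXPI_WEIGHTS, path = NULL) {
  norm <- profile$normalized
  if (length(weights) != ncol(norm))
    stop_format("need %d weights, got %d", ncol(norm), length(weights))
  ang <- 2 * pi * c(0, cumsum(weights) / sum(weights))
  out <- lapply(rownames(norm), function(cmp) {
    r <- norm[cmp, ]
    mid <- (ang[-length(ang)] + ang[-1]) / 2
    data.frame(axis = colnames(norm), weight = unname(weights),
               radius = unname(r),
               angle_start = ang[-length(ang)], angle_mid = mid,
               angle_end = ang[-1],
               x = unname(r * cos(mid)), y = unname(r * sin(mid)),
               stringsAsFactors = FALSE)
  })
  names(out) <- rownames(norm)
  if (!is.null(path))
    jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  out
}
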