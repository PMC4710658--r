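# Candidate-biomarker selection and quality control.
#
# Two selection tracks: (1) the joint toxicant signature - genes called DEG
# (either direction) by at least four of the six compounds; (2) a scoring
# track - genes passing minimum data-quality criteria (|FC| >= 1.8, FDR
# p <= 0.05, control expression >= 5 on the 3-15 log2 scale) collect points
# for measurability, statistical power and biological relevance, and are
# shortlisted at a total score >= 3.
#
# Set quality is measured in separation units (SU): per compound, probes are
# scored with a two-sample T score (treatment vs matched controls), probes
# with no compound reaching p < 0.05 are dropped, |T| is averaged per gene,
# genes are rank-normalized per compound to r in [0, 1], the candidate set's
# mean rank per compound forms a six-vector, and SU is its Euclidean length:
#   SU = sqrt(rbar_GA^2 + rbar_TDF^2 + rbar_PBDE^2 + rbar_TSA^2
#             + rbar_VPA^2 + rbar_As2O3^2),  range 0 .. sqrt(6) ~ 2.449.
# The null distribution comes from bootstrapped random gene sets of the same
# size drawn from the filtered pool.

#' Joint toxicant signature
#'
#' Genes differentially expressed (in either direction — direction is
#' ignored for membership but reported per compound) in at least
#' `min_compounds` of the study compounds.
#'
#' @param deg_tables named list of `DEGTable`s, one per compound
#' @param min_compounds membership threshold (default 4)
#' @return data frame `gene`, `n_compounds`, plus one direction column per
#'   compound (`"up"`, `"down"`, `"mixed"` across probes, or `""`)
#' @export
joint_signature <- function(deg_tables, min_compounds = 4) {
  cmps <- names(deg_tables)
  per_gene_dir <- lapply(deg_tables, function(tab) {
    deg <- tab[tab$is_DEG & tab$gene != "unannotated", , drop = FALSE]
    if (nrow(deg) == 0) return(setNames(character(0), character(0)))
    dirs <- tapply(deg$direction, deg$gene, function(d) {
      u <- unique(d)
      if (length(u) == 1) u else "mixed"
    })
    setNames(as.character(dirs), names(dirs))
  })
  genes <- sort(unique(unlist(lapply(per_gene_dir, names), use.names = FALSE)))
  hits <- vapply(genes, function(g)
    sum(vapply(per_gene_dir, function(d) g %in% names(d), logical(1))),
    integer(1))
  keep <- genes[hits >= min_compounds]
  out <- data.frame(gene = keep,
                    n_compounds = hits[match(keep, genes)],
                    stringsAsFactors = FALSE)
  for (cmp in cmps) {
    d <- per_gene_dir[[cmp]]
    out[[cmp]] <- ifelse(keep %in% names(d), d[keep], "")
  }
  rownames(out) <- NULL
  out
}

#' Score genes as candidate biomarkers
#'
#' A gene enters scoring when, for at least one compound, a probe of that
#' gene passes the minimum criteria: DEG call (|FC| >= `fc` threshold and
#' adjusted p within the FDR gate, already encoded in `is_DEG`) and control
#' expression at least `expr_floor` (log2 fluorescence, above array noise).
#' Component scores (one point each, configurable cutoffs):
#' \itemize{
#'   \item expression level: qualifying probe's control expression at or
#'     above the median array level;
#'   \item confirmation: more than one probe set of the gene regulated in
#'     the same direction in some compound;
#'   \item related gene: another member of the gene's family present in the
#'     pooled DEG list;
#'   \item GO membership: gene occurs in a kept enriched GO term;
#'   \item KEGG membership: gene occurs in a kept enriched KEGG pathway;
#'   \item p strength: best adjusted p at or below `p_strength_cutoff`.
#' }
#' Genes absent from the family map receive a related-gene score of 0.
#'
#' @param deg_tables named list of `DEGTable`s
#' @param enriched_go,enriched_kegg enrichment rows after
#'   [apply_report_filter()] (data frame or list of them); their `genes`
#'   columns define membership
#' @param family_map data frame `gene`, `family` (optional)
#' @param expr_floor minimum control expression (default 5)
#' @param p_strength_cutoff adjusted-p cutoff for the statistical-power
#'   point (default 1e-4)
#' @return a `BiomarkerScoreCard` data frame: `gene`, the six component
#'   columns, `total`, `shortlisted` (total >= 3), `min_adj_p`,
#'   `n_compounds_deg`, `compounds`
#' @export
score_genes <- function(deg_tables, enriched_go = NULL, enriched_kegg = NULL,
                        family_map = NULL, expr_floor = 5,
                        p_strength_cutoff = 1e-4) {
  rows_of <- function(x) {
    if (is.null(x)) return(character(0))
    if (is.data.frame(x)) x <- list(x)
    unique(unlist(lapply(x, function(r)
      unlist(strsplit(r$genes[r$genes != ""], ",", fixed = TRUE),
             use.names = FALSE)), use.names = FALSE))
  }
  go_genes <- rows_of(enriched_go)
  kegg_genes <- rows_of(enriched_kegg)

  all_deg_genes <- unique(unlist(lapply(deg_tables, function(tab)
    tab$gene[tab$is_DEG & tab$gene != "unannotated"]), use.names = FALSE))

  # qualifying (gene, compound) rows: DEG probes above the expression floor
  qual <- do.call(rbind, lapply(names(deg_tables), function(cmp) {
    tab <- deg_tables[[cmp]]
    q <- tab[tab$is_DEG & tab$gene != "unannotated" &
               tab$ctrl_expr >= expr_floor, , drop = FALSE]
    if (nrow(q) == 0) return(NULL)
    q$compound <- cmp
    q$median_expr <- median(tab$ctrl_expr)
    q
  }))
  if (is.null(qual) || nrow(qual) == 0)
    return(empty_scorecard())

  genes <- sort(unique(qual$gene))
  fam <- if (is.null(family_map)) NULL else
    setNames(family_map$family, family_map$gene)

  score_one <- function(g) {
    qg <- qual[qual$gene == g, , drop = FALSE]
    expr_pt <- as.integer(any(qg$ctrl_expr >= qg$median_expr))
    confirm <- any(vapply(split(qg, qg$compound), function(sub)
      any(table(sub$direction) > 1), logical(1)))
    related <- 0L
    if (!is.null(fam) && g %in% names(fam)) {
      relatives <- names(fam)[fam == fam[[g]] & names(fam) != g]
      related <- as.integer(any(relatives %in% all_deg_genes))
    }
    data.frame(gene = g,
               expression_level = expr_pt,
               confirmation = as.integer(confirm),
               related_gene = related,
               go_member = as.integer(g %in% go_genes),
               kegg_member = as.integer(g %in% kegg_genes),
               p_strength = as.integer(min(qg$adj_p) <= p_strength_cutoff),
               min_adj_p = min(qg$adj_p),
               n_compounds_deg = length(unique(qg$compound)),
               compounds = paste(sort(unique(qg$compound)), collapse = ","),
               stringsAsFactors = FALSE)
  }
  card <- do.call(rbind, lapply(genes, score_one))
  comp_cols <- c("expression_level", "confirmation", "related_gene",
                 "go_member", "kegg_member", "p_strength")
  card$total <- rowSums(card[, comp_cols])
  card$shortlisted <- card$total >= 3
  card <- card[, c("gene", comp_cols, "total", "shortlisted", "min_adj_p",
                   "n_compounds_deg", "compounds")]
  class(card) <- unique(c("BiomarkerScoreCard", class(card)))
  card
}

empty_scorecard <- function() {
  card <- data.frame(gene = character(0), expression_level = integer(0),
                     confirmation = integer(0), related_gene = integer(0),
                     go_member = integer(0), kegg_member = integer(0),
                     p_strength = integer(0), total = numeric(0),
                     shortlisted = logical(0), min_adj_p = numeric(0),
                     n_compounds_deg = integer(0), compounds = character(0),
                     stringsAsFactors = FALSE)
  class(card) <- unique(c("BiomarkerScoreCard", class(card)))
  card
}

#' Deterministic final-panel selection
#'
#' Deterministic surrogate for the manual selection step of the original
#' procedure: per compound, shortlisted genes DEG for that compound are
#' ranked by (score descending, best adjusted p ascending, gene id
#' ascending) and taken up to `per_compound_max`; a compound with fewer than
#' `per_compound_min` eligible genes contributes all of them (with a
#' warning). The panel is the union of the per-compound picks and the joint
#' signature.
#'
#' @param scorecard a `BiomarkerScoreCard`
#' @param deg_tables named list of `DEGTable`s (defines per-compound DEG
#'   membership and p-values)
#' @param per_compound_min,per_compound_max panel size targets per compound
#'   (defaults 8 and 12)
#' @param joint optional [joint_signature()] output to merge in
#' @return list with `panel` (data frame `gene`, `origin` one of
#'   `"score"`, `"joint"`, `"both"`), and `per_compound` (list of gene
#'   vectors)
#' @export
select_final_panel <- function(scorecard, deg_tables,
                               per_compound_min = 8, per_compound_max = 12,
                               joint = NULL) {
  if (nrow(scorecard) == 0) stop_format("empty scorecard")
  short <- scorecard[scorecard$shortlisted, , drop = FALSE]
  per_compound <- list()
  for (cmp in names(deg_tables)) {
    tab <- deg_tables[[cmp]]
    deg_g <- unique(tab$gene[tab$is_DEG & tab$gene != "unannotated"])
    cand <- short[short$gene %in% deg_g, , drop = FALSE]
    if (nrow(cand) == 0) { per_compound[[cmp]] <- character(0); next }
    best_p <- vapply(cand$gene, function(g) {
      sub <- tab[tab$gene == g & tab$is_DEG, , drop = FALSE]
      min(sub$adj_p)
    }, numeric(1))
    ord <- order(-cand$total, best_p, cand$gene, method = "radix")
    take <- head(ord, per_compound_max)
    if (length(take) < per_compound_min)
      warning(sprintf("compound %s: only %d shortlisted gene(s) (target >= %d)",
                      cmp, length(take), per_compound_min))
    per_compound[[cmp]] <- cand$gene[take]
  }
  score_genes_sel <- sort(unique(unlist(per_compound, use.names = FALSE)))
  joint_genes <- if (is.null(joint)) character(0) else joint$gene
  panel_genes <- sort(union(score_genes_sel, joint_genes))
  origin <- ifelse(panel_genes %in% score_genes_sel &
                     panel_genes %in% joint_genes, "both",
                   ifelse(panel_genes %in% joint_genes, "joint", "score"))
  list(panel = data.frame(gene = panel_genes, origin = origin,
                          stringsAsFactors = FALSE),
       per_compound = per_compound)
}

#' SU value from mean normalized ranks
#'
#' Euclidean length of the per-compound mean-rank vector:
#' `sqrt(sum(rbar^2))`. For six compounds with every mean rank at its
#' maximum of 1 this attains `sqrt(6)`, about 2.45; it is 0 when all ranks
#' are 0.
#'
#' @param rbar numeric vector of per-compound mean normalized ranks in
#'   \[0, 1\]
#' @return the SU value
#' @export
su_from_ranks <- function(rbar) {
  if (any(rbar < 0 | rbar > 1)) stop_format("mean ranks must lie in [0, 1]")
  sqrt(sum(rbar^2))
}

# two-sample pooled-variance t per probe, one column per compound.
# var_equal = FALSE switches to Welch.
compound_t_scores <- function(em, var_equal = TRUE) {
  sh <- em$sample_sheet
  compounds <- setdiff(unique(sh$compound), "control")
  vals <- em$values
  tmat <- matrix(NA_real_, nrow(vals), length(compounds),
                 dimnames = list(rownames(vals), compounds))
  pmat <- tmat
  for (cmp in compounds) {
    trt_ids <- sh$sample_id[sh$compound == cmp]
    grp <- unique(sh$control_group[sh$compound == cmp])
    ctl_ids <- sh$sample_id[sh$compound == "control" & sh$control_group %in% grp]
    x <- vals[, trt_ids, drop = FALSE]
    y <- vals[, ctl_ids, drop = FALSE]
    n1 <- ncol(x); n2 <- ncol(y)
    if (n1 < 2 || n2 < 2)
      stop_format("compound %s: need >= 2 treated and control samples", cmp)
    m1 <- rowMeans(x); m2 <- rowMeans(y)
    v1 <- rowSums((x - m1)^2) / (n1 - 1)
    v2 <- rowSums((y - m2)^2) / (n2 - 1)
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      se <- sqrt(v1 / n1 + v2 / n2)
      df <- (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      df[!is.finite(df)] <- n1 + n2 - 2
    }
    tv <- ifelse(se > 0, (m1 - m2) / se,
                 ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
    tmat[, cmp] <- tv
    pmat[, cmp] <- 2 * pt(-abs(tv), df = df)
  }
  list(t = tmat, p = pmat)
}

#' Per-compound normalized gene ranks for the SU metric
#'
#' Computes the probe-level two-sample T scores (treatment vs matched
#' controls), keeps probes where at least one compound differs from control
#' at p < `p_filter` (raw p), averages |T| over the probes of each annotated
#' gene, and rank-normalizes genes per compound to r in \[0, 1\] (average
#' ranks for ties; r = 0 is the weakest separation, r = 1 the strongest).
#' Unannotated probes are excluded at the gene-averaging step.
#'
#' @param em an `ExpressionMatrix` (all replicates, treated and control)
#' @param annotation a `ProbeAnnotation`
#' @param p_filter probe-retention threshold (default 0.05, raw p)
#' @param var_equal pooled-variance T (default) or Welch
#' @return list with `r` (pool-genes x compounds matrix of normalized
#'   ranks), `mean_abs_t` (same shape), `pool` (gene ids) and `n_probes`
#'   (probes surviving the filter)
#' @export
su_ranks <- function(em, annotation, p_filter = 0.05, var_equal = TRUE) {
  ts <- compound_t_scores(em, var_equal = var_equal)
  keep <- apply(ts$p, 1, min) < p_filter
  probes <- rownames(ts$t)[keep]
  genes <- probe_genes(probes, annotation)
  ok <- genes != "unannotated"
  probes <- probes[ok]; genes <- genes[ok]
  if (length(probes) == 0)
    stop_format("no annotated probes pass the p < %g filter", p_filter)
  absT <- abs(ts$t[probes, , drop = FALSE])
  gmean <- rowsum(absT, genes)
  cnt <- table(genes)
  gmean <- gmean / as.vector(cnt[rownames(gmean)])
  G <- nrow(gmean)
  r <- apply(gmean, 2, function(v)
    if (G == 1) rep(1, G) else (rank(v, ties.method = "average") - 1) / (G - 1))
  rownames(r) <- rownames(gmean)
  list(r = r, mean_abs_t = gmean, pool = rownames(gmean),
       n_probes = length(probes))
}

#' Separation units of a candidate gene set
#'
#' @param candidate_genes character vector of gene ids
#' @param em an `ExpressionMatrix` (ignored if `ranks` supplied)
#' @param annotation a `ProbeAnnotation` (ignored if `ranks` supplied)
#' @param p_filter,var_equal see [su_ranks()]
#' @param ranks optional precomputed [su_ranks()] result
#' @return object of class `SeparationResult`: `su`, `rbar` (per-compound
#'   mean normalized rank), `genes`, `missing` (candidate genes outside the
#'   filtered pool, assigned r = 0), `n_pool`
#' @export
su_metric <- function(candidate_genes, em = NULL, annotation = NULL,
                      p_filter = 0.05, var_equal = TRUE, ranks = NULL) {
  ranks <- ranks %||% su_ranks(em, annotation, p_filter = p_filter,
                               var_equal = var_equal)
  candidate_genes <- unique(candidate_genes)
  present <- intersect(candidate_genes, ranks$pool)
  missing <- setdiff(candidate_genes, ranks$pool)
  if (length(missing))
    message(sprintf("%d candidate gene(s) outside the filtered pool get r = 0",
                    length(missing)))
  rmat <- matrix(0, length(candidate_genes), ncol(ranks$r),
                 dimnames = list(candidate_genes, colnames(ranks$r)))
  if (length(present)) rmat[present, ] <- ranks$r[present, , drop = FALSE]
  rbar <- colMeans(rmat)
  structure(list(su = su_from_ranks(rbar), rbar = rbar,
                 genes = candidate_genes, missing = missing,
                 n_pool = length(ranks$pool)),
            class = "SeparationResult")
}

#' @export
print.SeparationResult <- function(x, ...) {
  cat(sprintf("SeparationResult: SU = %.3f (range 0-%.2f) over %d genes\n",
              x$su, sqrt(length(x$rbar)), length(x$genes)))
  cat("  mean ranks:", paste(sprintf("%s=%.3f", names(x$rbar), x$rbar),
                             collapse = ", "), "\n")
  if (!is.null(x$null_mean))
    cat(sprintf("  bootstrap null: %.3f +/- %.3f (%d reps); percentile %.1f; z = %.2f\n",
                x$null_mean, x$null_sd, x$n_reps, x$percentile, x$z))
  invisible(x)
}

#' Bootstrap null distribution for the SU metric
#'
#' Draws `n_reps` random gene sets of size `set_size` (without replacement
#' within a set) from the filtered gene pool, computes each set's SU, and
#' places the candidate set in that null.
#'
#' @param candidate_genes candidate set
#' @param em,annotation,p_filter,var_equal,ranks see [su_metric()]
#' @param set_size null set size (default: size of the candidate set)
#' @param n_reps bootstrap replicates (default 10000; raise towards 1e6 for
#'   publication-scale nulls)
#' @param seed RNG seed
#' @return a `SeparationResult` with `null_mean`, `null_sd`, `null_su`,
#'   `percentile` (share of null SUs below the candidate, in %), `z`
#'   (standardized distance), `n_reps`, `seed`
#' @export
su_bootstrap <- function(candidate_genes, em = NULL, annotation = NULL,
                         set_size = NULL, n_reps = 10000, seed = 1L,
                         p_filter = 0.05, var_equal = TRUE, ranks = NULL) {
  ranks <- ranks %||% su_ranks(em, annotation, p_filter = p_filter,
                               var_equal = var_equal)
  set_size <- set_size %||% length(unique(candidate_genes))
  if (length(ranks$pool) < set_size)
    stop_format("filtered pool (%d genes) smaller than set size %d",
                length(ranks$pool), set_size)
  res <- su_metric(candidate_genes, ranks = ranks)
  set.seed(seed)
  G <- nrow(ranks$r)
  null_su <- vapply(seq_len(n_reps), function(i) {
    idx <- sample.int(G, set_size)
    su_from_ranks(colMeans(ranks$r[idx, , drop = FALSE]))
  }, numeric(1))
  res$null_su <- null_su
  res$null_mean <- mean(null_su)
  res$null_sd <- sd(null_su)
  res$percentile <- 100 * mean(null_su < res$su)
  res$z <- (res$su - res$null_mean) / res$null_sd
  res$n_reps <- n_reps
  res$seed <- as.integer(seed)
  res
}
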