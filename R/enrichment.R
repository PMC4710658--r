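# Over-representation analysis of DEG lists. Classic scoring tests every
# term independently with a one-sided Fisher (hypergeometric upper-tail)
# test; the elim variant walks the DAG from the deepest terms upward and,
# whenever a term comes out significant at the elim cutoff, removes its
# member genes from all ancestor terms before those are tested, so general
# terms are not carried by the signal of their specific children. BH
# adjustment is applied within one namespace and one direction, never
# across.

#' One-sided Fisher over-representation p-value
#'
#' Upper tail of the hypergeometric distribution: the probability of drawing
#' at least `overlap` term genes when `deg_size` genes are drawn from a
#' universe of `universe_size` containing `term_size` term genes. Vectorized
#' over all arguments.
#'
#' @param overlap observed DEG-in-term count
#' @param term_size term size within the universe
#' @param deg_size DEG list size
#' @param universe_size gene universe size
#' @return p-value(s)
#' @export
fisher_overrep_p <- function(overlap, term_size, deg_size, universe_size) {
  phyper(overlap - 1, term_size, universe_size - term_size, deg_size,
         lower.tail = FALSE)
}

fisher_one_sided <- fisher_overrep_p

enrichment_rows <- function(sets, deg, universe, namespace, method,
                            term_names = NULL) {
  N <- length(universe)
  n <- length(deg)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    hit <- intersect(members, deg)
    data.frame(term_id = id,
               name = (term_names[[id]] %||% id),
               namespace = namespace,
               size = length(members),
               overlap = length(hit),
               p = fisher_one_sided(length(hit), length(members), n, N),
               method = method,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out[, c("term_id", "name", "namespace", "size", "overlap", "p", "adj_p",
          "method", "genes")]
}

#' Classic Fisher over-representation analysis
#'
#' One-sided (over-representation) hypergeometric test of the DEG list
#' against every term of the chosen namespace; BH adjustment over the tested
#' terms.
#'
#' @param deg_genes character vector of DEG gene symbols
#' @param collection a `GeneSetCollection`
#' @param universe gene universe (default: the collection's); DEG genes
#'   outside the universe are dropped before testing
#' @param namespace `"flat"` or `"dag"`
#' @return data frame of `EnrichmentRow`s: `term_id`, `name`, `namespace`,
#'   `size`, `overlap`, `p`, `adj_p`, `method`, `genes`
#' @export
fisher_enrich <- function(deg_genes, collection, universe = NULL,
                          namespace = c("flat", "dag")) {
  namespace <- match.arg(namespace)
  universe <- unique(universe %||% collection$universe)
  if (length(universe) == 0) stop_format("empty gene universe")
  deg <- intersect(unique(deg_genes), universe)
  sets <- if (namespace == "flat") collection$flat else collection$dag
  nm <- if (namespace == "flat") collection$flat_names else collection$term_names
  enrichment_rows(sets, deg, universe, namespace, "classic", nm)
}

#' elim over-representation analysis on the DAG
#'
#' Terms are tested from the deepest DAG level upward (ties by term id).
#' When a term's raw one-sided Fisher p is at or below `elim_cutoff`, its
#' (current) member genes are removed from all of its ancestors before the
#' ancestors are tested; reported sizes, overlaps and p-values are the
#' post-elimination ones. With `elim_cutoff = 0` no gene is ever removed and
#' the result equals the classic analysis.
#'
#' @param deg_genes character vector of DEG gene symbols
#' @param collection a `GeneSetCollection` with DAG terms
#' @param universe gene universe (default: the collection's)
#' @param elim_cutoff raw-p threshold triggering elimination (default 0.01,
#'   the conventional default for this algorithm)
#' @return data frame of `EnrichmentRow`s with `method = "elim"`
#' @export
elim_enrich <- function(deg_genes, collection, universe = NULL,
                        elim_cutoff = 0.01) {
  if (length(collection$dag) == 0)
    stop_format("collection has no DAG terms")
  universe <- unique(universe %||% collection$universe)
  if (length(universe) == 0) stop_format("empty gene universe")
  deg <- intersect(unique(deg_genes), universe)
  N <- length(universe); n <- length(deg)

  sets <- lapply(collection$dag, intersect, y = universe)
  depths <- dag_depths(collection$dag_parents)
  ord <- names(sets)[order(-depths[names(sets)], names(sets), method = "radix")]

  rows <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    id <- ord[i]
    members <- sets[[id]]
    hit <- intersect(members, deg)
    p <- fisher_one_sided(length(hit), length(members), n, N)
    rows[[i]] <- data.frame(term_id = id,
                            name = (collection$term_names[[id]] %||% id),
                            namespace = "dag",
                            size = length(members),
                            overlap = length(hit),
                            p = p, method = "elim",
                            genes = paste(sort(hit), collapse = ","),
                            stringsAsFactors = FALSE)
    if (p <= elim_cutoff && length(members)) {
      for (anc in dag_ancestors(collection, id))
        sets[[anc]] <- setdiff(sets[[anc]], members)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$term_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out$adj_p <- bh_adjust(out$p)
  out[, c("term_id", "name", "namespace", "size", "overlap", "p", "adj_p",
          "method", "genes")]
}

#' Reporting filter for enriched terms
#'
#' Keeps terms that are significant after adjustment and carry enough of the
#' DEG list: adjusted p <= `alpha` and (overlap >= `min_deg` DEG, or — for
#' small terms — at least `min_fraction` of the term's genes differentially
#' expressed).
#'
#' @param rows enrichment rows (from [fisher_enrich()] or [elim_enrich()])
#' @param min_deg minimum DEG in the term (default 3)
#' @param min_fraction minimum DEG fraction of the term (default 0.5)
#' @param alpha adjusted-p gate (default 0.05)
#' @return the kept rows, with a logical `kept` column set to `TRUE`
#' @export
apply_report_filter <- function(rows, min_deg = 3, min_fraction = 0.5,
                                alpha = 0.05) {
  if (nrow(rows) == 0) { rows$kept <- logical(0); return(rows) }
  frac <- ifelse(rows$size > 0, rows$overlap / rows$size, 0)
  keep <- rows$adj_p <= alpha & (rows$overlap >= min_deg | frac >= min_fraction)
  out <- rows[keep, , drop = FALSE]
  out$kept <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Direction-wise or pooled enrichment of a DEG table
#'
#' `mode = "separate"` analyses up- and downregulated DEG independently (the
#' inputs of the six toxicity-profile axes); `mode = "pooled"` analyses the
#' union (the input of the superordinate-process ring summaries). Probes
#' with the `"unannotated"` sentinel are excluded from the gene lists.
#'
#' @param deg_tab a `DEGTable`
#' @param collection a `GeneSetCollection`
#' @param mode `"separate"` or `"pooled"`
#' @param namespace `"flat"` or `"dag"`
#' @param method `"classic"` or `"elim"` (elim requires the DAG namespace)
#' @param elim_cutoff passed to [elim_enrich()]
#' @param universe optional gene universe
#' @return named list of enrichment-row data frames: elements `up` and
#'   `down`, or a single element `pooled`
#' @export
enrich_by_direction <- function(deg_tab, collection,
                                mode = c("separate", "pooled"),
                                namespace = c("dag", "flat"),
                                method = c("classic", "elim"),
                                elim_cutoff = 0.01, universe = NULL) {
  mode <- match.arg(mode); namespace <- match.arg(namespace)
  method <- match.arg(method)
  if (method == "elim" && namespace != "dag")
    stop_format("elim applies to the DAG namespace only")
  gene_list <- function(dir) {
    sel <- deg_tab$is_DEG & deg_tab$gene != "unannotated"
    if (!is.null(dir)) sel <- sel & deg_tab$direction == dir
    unique(deg_tab$gene[sel])
  }
  run <- function(genes) {
    if (method == "elim")
      elim_enrich(genes, collection, universe = universe,
                  elim_cutoff = elim_cutoff)
    else fisher_enrich(genes, collection, universe = universe,
                       namespace = namespace)
  }
  if (mode == "separate")
    list(up = run(gene_list("up")), down = run(gene_list("down")))
  else
    list(pooled = run(gene_list(NULL)))
}
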