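# GeneSetCollection: flat KEGG-like pathway sets plus GO-like DAG terms with
# parent links. DAG term membership obeys the true-path rule: after loading,
# each term's gene set is propagated to all its ancestors, so a child's
# members are always a subset of its parents'.

#' Construct a gene-set collection
#'
#' @param flat named list of character vectors: flat (pathway-like) sets
#' @param flat_names optional named character vector of set descriptions
#' @param dag named list of character vectors: direct gene annotations of DAG
#'   terms (may be empty vectors for structure-only terms)
#' @param dag_parents named list: for each DAG term, character vector of its
#'   parent term ids (empty for roots). Must be acyclic.
#' @param term_names optional named character vector of DAG term names
#' @param universe optional character vector of all annotated genes; defaults
#'   to the union of all set members
#' @param propagate propagate DAG annotations to ancestors (default TRUE)
#' @return object of class `GeneSetCollection`
#' @export
gene_set_collection <- function(flat = list(), flat_names = NULL,
                                dag = list(), dag_parents = list(),
                                term_names = NULL, universe = NULL,
                                propagate = TRUE) {
  flat <- lapply(flat, function(g) unique(as.character(g)))
  dag <- lapply(dag, function(g) unique(as.character(g)))
  # every DAG term mentioned as a parent must exist
  terms <- union(names(dag), names(dag_parents))
  extra <- setdiff(unique(unlist(dag_parents)), terms)
  if (length(extra))
    stop_format("DAG parent(s) never defined as terms: %s",
                paste(extra, collapse = ", "))
  for (t in setdiff(terms, names(dag))) dag[[t]] <- character(0)
  for (t in setdiff(terms, names(dag_parents))) dag_parents[[t]] <- character(0)
  check_acyclic(dag_parents)
  if (propagate && length(dag)) dag <- propagate_up(dag, dag_parents)
  universe <- unique(as.character(
    universe %||% union(unlist(flat, use.names = FALSE),
                        unlist(dag, use.names = FALSE))))
  structure(list(flat = flat, flat_names = flat_names,
                 dag = dag, dag_parents = dag_parents,
                 term_names = term_names, universe = universe),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d flat set(s), %d DAG term(s), universe %d genes\n",
              length(x$flat), length(x$dag), length(x$universe)))
  invisible(x)
}

check_acyclic <- function(parents) {
  edges <- parent_edges(parents)
  if (nrow(edges) == 0) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g))
    stop_format("format error: DAG parent links contain a cycle")
  invisible(TRUE)
}

parent_edges <- function(parents) {
  child <- rep(names(parents), lengths(parents))
  data.frame(child = child, parent = unlist(parents, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# push each term's genes to all ancestors (true-path rule)
propagate_up <- function(dag, parents) {
  depths <- dag_depths(parents)
  for (t in names(dag)[order(-depths[names(dag)])]) {
    for (p in parents[[t]]) dag[[p]] <- union(dag[[p]], dag[[t]])
  }
  dag
}

# depth = longest path to a root (roots have depth 0)
dag_depths <- function(parents) {
  depth <- setNames(rep(NA_real_, length(parents)), names(parents))
  visit <- function(t) {
    if (!is.na(depth[[t]])) return(depth[[t]])
    ps <- parents[[t]]
    d <- if (length(ps) == 0) 0 else 1 + max(vapply(ps, visit, numeric(1)))
    depth[[t]] <<- d
    d
  }
  for (t in names(parents)) visit(t)
  depth
}

#' Ancestors of a DAG term
#'
#' @param collection a `GeneSetCollection`
#' @param term term id
#' @return character vector of all ancestor term ids (excluding `term`)
#' @export
dag_ancestors <- function(collection, term) {
  parents <- collection$dag_parents
  if (!term %in% names(parents)) stop_format("unknown DAG term '%s'", term)
  seen <- character(0)
  frontier <- parents[[term]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)), seen)
  }
  seen
}

#' Read a GMT gene-set file
#'
#' One set per line: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file
#' @return list with `sets` (named list of gene vectors) and `descriptions`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop_format("format error: GMT line %d has fewer than 3 fields", bad[1])
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) stop_format("duplicated set ids in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  desc <- setNames(vapply(parts, `[[`, character(1), 2), ids)
  list(sets = sets, descriptions = desc)
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene vectors
#' @param path destination
#' @param descriptions optional named character vector
#' @return invisibly, `path`
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% id, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# OBO-lite: only [Term] stanzas with id:, name:, is_a: lines are honoured.
read_obo_lite <- function(path) {
  lines <- readLines(path)
  ids <- character(0); nms <- character(0); parents <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      ids <<- c(ids, cur$id)
      nms <<- c(nms, cur$name %||% cur$id)
      parents[[cur$id]] <<- cur$is_a %||% character(0)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(is_a = character(0)); next }
    if (is.null(cur)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$is_a <- c(cur$is_a, tgt)
    }
  }
  flush()
  list(parents = parents, names = setNames(nms, ids))
}

# 2-column child<TAB>parent edge list (header optional)
read_edge_list <- function(path) {
  tab <- read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_format("edge list needs two columns (child, parent)")
  if (identical(tolower(as.character(tab[1, 1:2])), c("child", "parent")))
    tab <- tab[-1, , drop = FALSE]
  child <- as.character(tab[[1]]); parent <- as.character(tab[[2]])
  terms <- union(child, parent)
  parents <- setNames(lapply(terms, function(t) unique(parent[child == t])), terms)
  list(parents = parents, names = setNames(terms, terms))
}

#' Read gene-set inputs into a collection
#'
#' Flat sets come from a GMT file; DAG structure from an OBO-lite file (only
#' `id:`, `name:`, `is_a:` honoured) or a 2-column child/parent edge TSV; DAG
#' term gene membership from a second GMT keyed by term id. After loading,
#' DAG annotations are propagated to ancestors.
#'
#' @param gmt_path flat-set GMT (or `NULL`)
#' @param dag_path OBO-lite file (`.obo`) or edge TSV (or `NULL`)
#' @param dag_gmt_path GMT of direct DAG term annotations (or `NULL`)
#' @param universe optional gene universe
#' @return a `GeneSetCollection`
#' @export
read_gene_sets <- function(gmt_path = NULL, dag_path = NULL,
                           dag_gmt_path = NULL, universe = NULL) {
  flat <- list(); flat_names <- NULL
  if (!is.null(gmt_path)) {
    g <- read_gmt(gmt_path)
    flat <- g$sets; flat_names <- g$descriptions
  }
  dag_parents <- list(); term_names <- NULL; dag <- list()
  if (!is.null(dag_path)) {
    d <- if (grepl("\\.obo$", dag_path)) read_obo_lite(dag_path)
         else read_edge_list(dag_path)
    dag_parents <- d$parents; term_names <- d$names
    if (!is.null(dag_gmt_path)) {
      a <- read_gmt(dag_gmt_path)
      dag <- a$sets
      unknown <- setdiff(names(dag), names(dag_parents))
      for (t in unknown) dag_parents[[t]] <- character(0)
    }
  }
  gene_set_collection(flat = flat, flat_names = flat_names, dag = dag,
                      dag_parents = dag_parents, term_names = term_names,
                      universe = universe)
}
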