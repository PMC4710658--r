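# Synthetic-study generator. Emulates the structure of the six-compound
# neural crest study: 6 toxicants x (3 training + 2 testing) replicates,
# 15 controls shared across three matched control groups (geldanamycin,
# PBDE-99 and triadimefon share one group; the two HDAC inhibitors TSA and
# VPA share another; arsenic trioxide has its own), log2 intensities on the
# 3-15 instrument scale, compound-specific planted DEG signatures of varying
# size and direction, and one compound pair (the HDACi analogue) sharing a
# near-identical signature.

SUPERORDINATE_CLASSES <- c("migration/adhesion", "metabolism",
                           "differentiation", "signalling",
                           "stress response", "other")

#' Define a synthetic study design
#'
#' Defaults reproduce the modelled study: six compounds, three matched
#' control groups (5 controls each: 3 training + 2 testing), per-compound
#' signature sizes scaled from the relative response strengths of the real
#' compounds, planted log2 effects drawn uniformly from `effect_range` with
#' compound-specific up/down balance, and the HDACi pair (TSA, VPA) sharing
#' one signature up to small independent jitter (effect correlation >= 0.95
#' by construction).
#'
#' @param compounds compound ids; defaults to the six study toxicants
#' @param n_train,n_test treated replicates per compound per batch
#' @param n_ctrl_train,n_ctrl_test control replicates per control group per
#'   batch (3 + 2 gives the study's 15 controls across three groups)
#' @param n_genes number of genes in the synthetic genome
#' @param probes_per_gene integer vector sampled uniformly per gene
#' @param frac_unannotated fraction of extra probes mapping to no gene
#' @param noise_sd Gaussian noise SD per sample on the log2 scale
#' @param effect_range range of |log2 effect| for planted signature genes
#' @param signature_sizes named integer vector: planted genes per compound
#' @param up_fraction named numeric vector: fraction of each signature that
#'   is upregulated (captures the up- vs down-dominant response types)
#' @param shared_pair length-2 character: compounds sharing a signature
#' @param shared_jitter_sd SD of the jitter distinguishing the shared pair
#' @param baseline_range range of per-probe baseline log2 intensity
#' @param seed integer seed; the design (signatures) and the data generated
#'   from it are both deterministic functions of it
#' @return object of class `StudyDesign`
#' @export
study_design <- function(compounds = c("GA", "TDF", "PBDE", "TSA", "VPA", "As2O3"),
                         n_train = 3, n_test = 2,
                         n_ctrl_train = 3, n_ctrl_test = 2,
                         n_genes = 1000,
                         probes_per_gene = 1:3,
                         frac_unannotated = 0.02,
                         noise_sd = 0.25,
                         effect_range = c(0.9, 2.0),
                         signature_sizes = NULL,
                         up_fraction = NULL,
                         shared_pair = c("TSA", "VPA"),
                         shared_jitter_sd = 0.05,
                         baseline_range = c(6, 12),
                         seed = 1) {
  stopifnot(n_train >= 1, n_test >= 1, n_train + n_test >= 2,
            n_genes >= 50, noise_sd >= 0, all(is.finite(effect_range)))
  if (is.null(signature_sizes)) {
    # relative sizes follow the pooled per-compound DEG strengths of the
    # modelled study (up-dominant GA/TSA/VPA, down-dominant TDF, mixed
    # PBDE/As2O3), scaled to the synthetic genome
    base <- c(GA = 0.12, TDF = 0.05, PBDE = 0.17, TSA = 0.09, VPA = 0.05,
              As2O3 = 0.15)
    sizes <- round(base[seq_along(compounds)] * n_genes)
    names(sizes) <- compounds
    signature_sizes <- sizes
  }
  if (is.null(up_fraction)) {
    uf <- c(GA = 0.9, TDF = 0.1, PBDE = 0.6, TSA = 0.9, VPA = 0.9,
            As2O3 = 0.5)
    up_fraction <- setNames(uf[seq_along(compounds)], compounds)
  }
  if (!all(shared_pair %in% compounds)) shared_pair <- NULL

  # three control groups mirroring the study's sharing structure
  groups <- rep(c("ctrlA", "ctrlB", "ctrlC"), length.out = length(compounds))
  if (length(compounds) == 6)
    groups <- c("ctrlA", "ctrlA", "ctrlA", "ctrlB", "ctrlB", "ctrlC")
  control_group <- setNames(groups, compounds)

  design <- structure(list(
    compounds = compounds, n_train = n_train, n_test = n_test,
    n_ctrl_train = n_ctrl_train, n_ctrl_test = n_ctrl_test,
    control_group = control_group,
    n_genes = n_genes, probes_per_gene = probes_per_gene,
    frac_unannotated = frac_unannotated,
    noise_sd = noise_sd, effect_range = effect_range,
    signature_sizes = signature_sizes, up_fraction = up_fraction,
    shared_pair = shared_pair, shared_jitter_sd = shared_jitter_sd,
    baseline_range = baseline_range, seed = as.integer(seed),
    biomarker_set = NULL), class = "StudyDesign")
  design$genes <- sprintf("g%04d", seq_len(n_genes))
  design$signatures <- build_signatures(design)
  design
}

#' @export
print.StudyDesign <- function(x, ...) {
  cat(sprintf("StudyDesign: %d compounds x (%d train + %d test) reps, %d genes, noise SD %.2f\n",
              length(x$compounds), x$n_train, x$n_test, x$n_genes, x$noise_sd))
  cat(sprintf("  planted signature genes: %s\n",
              paste(sprintf("%s=%d", x$compounds,
                            x$signature_sizes[x$compounds]), collapse = ", ")))
  if (!is.null(x$biomarker_set))
    cat(sprintf("  designated biomarker set: %d genes\n", length(x$biomarker_set)))
  invisible(x)
}

build_signatures <- function(design) {
  set.seed(design$seed)
  genes <- design$genes
  sig <- list()
  shared <- design$shared_pair
  for (cmp in design$compounds) {
    if (!is.null(shared) && cmp == shared[2]) next  # filled from partner below
    n <- design$signature_sizes[[cmp]]
    gs <- sample(genes, n)
    up <- runif(n) < design$up_fraction[[cmp]]
    eff <- runif(n, design$effect_range[1], design$effect_range[2]) *
      ifelse(up, 1, -1)
    sig[[cmp]] <- data.frame(compound = cmp, gene = gs, effect = eff,
                             stringsAsFactors = FALSE)
  }
  if (!is.null(shared)) {
    # the analogue pair shares the full signature up to small jitter, which
    # keeps the two compounds mutually confusable but separable as a group
    b <- sig[[shared[1]]]
    b$compound <- shared[2]
    b$effect <- b$effect + rnorm(nrow(b), 0, design$shared_jitter_sd)
    sig[[shared[2]]] <- b
  }
  out <- do.call(rbind, sig[design$compounds[design$compounds %in% names(sig)]])
  rownames(out) <- NULL
  out$direction <- ifelse(out$effect >= 0, "up", "down")
  out
}

# probe table: gene-level probes plus a tail of unannotated probes
design_probes <- function(design) {
  set.seed(design$seed + 1L)
  npg <- sample(design$probes_per_gene, design$n_genes, replace = TRUE)
  gene <- rep(design$genes, npg)
  idx <- unlist(lapply(npg, seq_len), use.names = FALSE)
  probe <- sprintf("%s_at%d", gene, idx)
  n_extra <- round(design$frac_unannotated * length(probe))
  if (n_extra > 0) {
    probe <- c(probe, sprintf("ctrl_at%03d", seq_len(n_extra)))
    gene <- c(gene, rep("unannotated", n_extra))
  }
  probe_annotation(probe, gene)
}

#' Generate a synthetic expression study
#'
#' Draws a per-probe baseline uniformly within the instrument range, then
#' forms control samples as baseline + Gaussian noise and treated samples as
#' baseline + planted signature effect + Gaussian noise; all values are
#' clipped to the \[3, 15\] log2 scale. With `noise_sd = 0`, treated minus
#' matched control recovers every planted effect exactly.
#'
#' @param design a [study_design()]
#' @return list with `matrix` (an `ExpressionMatrix`), `annotation` (a
#'   `ProbeAnnotation`), and `truth` (data frame of planted
#'   compound/gene/effect/direction rows). If more than 10% of values hit the
#'   clip bounds, attribute `clip_warning` on the result is set.
#' @export
generate_expression <- function(design) {
  stopifnot(inherits(design, "StudyDesign"))
  ann <- design_probes(design)
  probes <- ann$probe_id
  n_probes <- length(probes)

  sheet <- design_sample_sheet(design)
  n_samples <- nrow(sheet)

  set.seed(design$seed + 2L)
  baseline <- runif(n_probes, design$baseline_range[1], design$baseline_range[2])

  # per-probe effect per compound (probes inherit their gene's effect)
  eff <- matrix(0, n_probes, length(design$compounds),
                dimnames = list(probes, design$compounds))
  sig <- design$signatures
  for (cmp in design$compounds) {
    s <- sig[sig$compound == cmp, , drop = FALSE]
    hit <- ann$gene %in% s$gene & ann$gene != "unannotated"
    eff[hit, cmp] <- s$effect[match(ann$gene[hit], s$gene)]
  }

  vals <- matrix(0, n_probes, n_samples, dimnames = list(probes, sheet$sample_id))
  for (j in seq_len(n_samples)) {
    mu <- baseline
    if (sheet$compound[j] != "control") mu <- mu + eff[, sheet$compound[j]]
    noise <- if (design$noise_sd > 0) rnorm(n_probes, 0, design$noise_sd) else 0
    vals[, j] <- mu + noise
  }
  n_clip <- sum(vals < 3 | vals > 15)
  vals[vals < 3] <- 3
  vals[vals > 15] <- 15

  em <- expression_matrix(vals, sheet)
  truth <- design$signatures
  res <- list(matrix = em, annotation = ann, truth = truth)
  if (n_clip > 0.1 * length(vals)) {
    warning(sprintf("planted effects pushed %.1f%% of values to the clip bounds",
                    100 * n_clip / length(vals)))
    attr(res, "clip_warning") <- TRUE
  }
  res
}

design_sample_sheet <- function(design) {
  rows <- list()
  add <- function(sample_id, compound, replicate, batch, control_group) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, compound = compound, replicate = replicate,
      batch = batch, control_group = control_group, stringsAsFactors = FALSE)
  }
  for (grp in unique(design$control_group)) {
    for (r in seq_len(design$n_ctrl_train))
      add(sprintf("%s_tr%d", grp, r), "control", r, "training", grp)
    for (r in seq_len(design$n_ctrl_test))
      add(sprintf("%s_te%d", grp, r), "control", r, "testing", grp)
  }
  for (cmp in design$compounds) {
    grp <- design$control_group[[cmp]]
    for (r in seq_len(design$n_train))
      add(sprintf("%s_tr%d", cmp, r), cmp, r, "training", grp)
    for (r in seq_len(design$n_test))
      add(sprintf("%s_te%d", cmp, r), cmp, r, "testing", grp)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic annotation: DAG terms, flat sets, class mapping
#'
#' Builds a rooted 3-level DAG (root, mid-level terms, leaf terms with 1-2
#' parents) whose gene annotations respect the true-path rule after
#' propagation, a set of flat KEGG-like pathways, a mapping of every term to
#' one of the six superordinate biological process classes
#' (migration/adhesion, metabolism, differentiation, signalling, stress
#' response, other), and a gene family table for the related-gene biomarker
#' score.
#'
#' @param n_genes number of genes (ids `g0001`...)
#' @param n_terms number of DAG terms (>= 6)
#' @param seed integer seed
#' @param n_flat number of flat sets (default `max(6, n_terms %/% 3)`)
#' @return list with `collection` (a `GeneSetCollection`),
#'   `superordinate_map` (data frame `term_id`, `class`) and `family_map`
#'   (data frame `gene`, `family`)
#' @export
generate_annotation <- function(n_genes, n_terms = 60, seed = 1,
                                n_flat = NULL) {
  stopifnot(n_terms >= 6)
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_flat <- n_flat %||% max(6L, n_terms %/% 3L)

  root <- "T000"
  n_mid <- max(2L, min(n_terms %/% 5L, 12L))
  n_leaf <- n_terms - 1L - n_mid
  if (n_leaf < 0) { n_mid <- n_terms - 1L; n_leaf <- 0L }
  mids <- sprintf("T%03d", seq_len(n_mid))
  leaves <- if (n_leaf > 0) sprintf("T%03d", n_mid + seq_len(n_leaf)) else character(0)

  parents <- list()
  parents[[root]] <- character(0)
  for (t in mids) parents[[t]] <- root
  for (t in leaves) parents[[t]] <- sample(mids, sample(1:2, 1))

  dag <- list()
  dag[[root]] <- character(0)
  for (t in mids) dag[[t]] <- sample(genes, sample(5:15, 1))
  for (t in leaves) dag[[t]] <- sample(genes, sample(8:40, 1))

  flat_ids <- sprintf("K%02d", seq_len(n_flat))
  flat <- setNames(lapply(flat_ids, function(i) sample(genes, sample(10:40, 1))),
                   flat_ids)

  classes <- SUPERORDINATE_CLASSES
  terms <- c(root, mids, leaves)
  cls <- classes[1 + (seq_along(terms) - 1L) %% length(classes)]
  keywords <- c("cell migration and adhesion", "metabolic process",
                "cell differentiation", "signal transduction",
                "response to stress", "biological process")
  term_names <- setNames(sprintf("%s term %s", keywords[match(cls, classes)], terms),
                         terms)
  superordinate_map <- data.frame(term_id = terms, class = cls,
                                  stringsAsFactors = FALSE)

  fam_size <- sample(1:4, n_genes, replace = TRUE)
  fam_id <- rep(seq_along(fam_size), fam_size)[seq_len(n_genes)]
  family_map <- data.frame(gene = genes,
                           family = sprintf("fam%04d", fam_id),
                           stringsAsFactors = FALSE)

  collection <- gene_set_collection(flat = flat, dag = dag,
                                    dag_parents = parents,
                                    term_names = term_names,
                                    universe = genes)
  list(collection = collection, superordinate_map = superordinate_map,
       family_map = family_map)
}

#' Plant a designated strong biomarker set into a design
#'
#' Adds a 39-gene (by default) set, disjoint from all existing planted
#' signatures, with large same-magnitude effects in every compound. Serves as
#' a positive control for the separation-units metric: the set should land
#' far above the bootstrap null.
#'
#' @param design a [study_design()]
#' @param n_set set size (default 39)
#' @param effect |log2 effect| planted for every set gene in every compound
#' @return the augmented design (field `biomarker_set` holds the gene ids)
#' @export
plant_biomarker_scenario <- function(design, n_set = 39, effect = 2.5) {
  stopifnot(inherits(design, "StudyDesign"))
  free <- setdiff(design$genes, design$signatures$gene)
  if (length(free) < n_set)
    stop_format("only %d unperturbed genes available, need %d", length(free), n_set)
  set.seed(design$seed + 3L)
  chosen <- sort(sample(free, n_set))
  extra <- do.call(rbind, lapply(design$compounds, function(cmp) {
    sgn <- ifelse(runif(n_set) < 0.5, -1, 1)
    data.frame(compound = cmp, gene = chosen, effect = sgn * effect,
               direction = ifelse(sgn >= 0, "up", "down"),
               stringsAsFactors = FALSE)
  }))
  design$signatures <- rbind(design$signatures, extra)
  design$biomarker_set <- chosen
  design
}
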