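# Pipeline orchestration: a RunConfig names the inputs and thresholds, and
# run_pipeline() executes the stages in fixed order (deg -> classification
# -> enrichment -> profiles -> biomarkers -> su), writing per-stage CSV/JSON
# reports plus a manifest. With the same config and seed the numeric tables
# are byte-identical across runs.

#' Assemble a run configuration
#'
#' Input fields accept either file paths (loaded at run time) or in-memory
#' objects (an `ExpressionMatrix`, `ProbeAnnotation`, `GeneSetCollection`,
#' mapping data frames).
#'
#' @param expression matrix TSV path or `ExpressionMatrix`
#' @param sheet sample-sheet TSV path (ignored when `expression` is an
#'   object)
#' @param annotation probe-annotation TSV path or `ProbeAnnotation`; may be
#'   `NULL`, in which case every probe counts as unannotated and the
#'   enrichment stage refuses to run
#' @param gene_sets list of paths (`gmt`, `dag`, `dag_gmt`) or a
#'   `GeneSetCollection`
#' @param superordinate_map TSV path or data frame `term_id`, `class`
#' @param family_map TSV path or data frame `gene`, `family`
#' @param out_dir run directory for stage outputs
#' @param fc_min,fdr_max DEG thresholds (defaults 1.8 and 0.05)
#' @param expr_floor minimum control expression for biomarker scoring
#'   (default 5)
#' @param n_top_var features kept for classification/PCA (default 100)
#' @param enrich_method default enrichment algorithm for the DAG namespace
#'   (`"elim"` or `"classic"`); `enrich_method_overrides` maps specific
#'   compounds to the other method
#' @param elim_cutoff elimination threshold (default 0.01)
#' @param toxpi_weights six axis weights (default `c(1,1,2,2,2,2)`)
#' @param toxpi_norm `"axis"` or `"category"` maxima, see [build_axes()]
#' @param group_map optional named vector mapping compounds to mechanism
#'   groups for grouped prediction scoring
#' @param su_reps bootstrap replicates for the SU stage (default 1000)
#' @param seed integer seed recorded in every output header
#' @param enrich_method_overrides named character vector of per-compound
#'   method choices
#' @return object of class `RunConfig`
#' @export
run_config <- function(expression, sheet = NULL, annotation = NULL,
                       gene_sets = NULL, superordinate_map = NULL,
                       family_map = NULL, out_dir = tempfile("crestmark_run_"),
                       fc_min = 1.8, fdr_max = 0.05, expr_floor = 5,
                       n_top_var = 100, enrich_method = c("elim", "classic"),
                       elim_cutoff = 0.01, toxpi_weights = TOXPI_WEIGHTS,
                       toxpi_norm = c("axis", "category"),
                       group_map = NULL, su_reps = 1000, seed = 1L,
                       enrich_method_overrides = NULL) {
  enrich_method <- match.arg(enrich_method)
  toxpi_norm <- match.arg(toxpi_norm)
  if (fc_min <= 0 || fdr_max <= 0 || n_top_var <= 0 || su_reps <= 0)
    stop_format("thresholds must be strictly positive")
  structure(list(expression = expression, sheet = sheet,
                 annotation = annotation, gene_sets = gene_sets,
                 superordinate_map = superordinate_map,
                 family_map = family_map, out_dir = out_dir,
                 fc_min = fc_min, fdr_max = fdr_max, expr_floor = expr_floor,
                 n_top_var = n_top_var, enrich_method = enrich_method,
                 elim_cutoff = elim_cutoff, toxpi_weights = toxpi_weights,
                 toxpi_norm = toxpi_norm, group_map = group_map,
                 su_reps = su_reps, seed = as.integer(seed),
                 enrich_method_overrides = enrich_method_overrides),
            class = "RunConfig")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with fields as in [run_config()] (input fields as
#'   paths)
#' @return a `RunConfig`
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_format("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Stages, in fixed order: load inputs; per-compound DEG tables (pooled
#' replicates); classifier trained on the training batch and scored on the
#' blinded testing batch; per-compound enrichment (GO DAG up/down + pooled,
#' KEGG up/down); toxicity profiles with ToxPi scores and superordinate
#' tallies; biomarker selection (joint signature + scorecard + panel); SU of
#' the panel with a bootstrap null. Each stage writes its reports under
#' `config$out_dir`; a `manifest.json` lists them together with the config
#' and seed. Any failure aborts with an error naming the stage.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
    write_tsv6(df, p)
    outputs <<- c(outputs, name)
  }
  emit_json <- function(x, name) {
    p <- file.path(config$out_dir, name)
    dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(x, p, digits = NA, auto_unbox = TRUE, null = "null")
    outputs <<- c(outputs, name)
  }

  ## load ------------------------------------------------------------------
  inputs <- stage("load", {
    em <- if (inherits(config$expression, "ExpressionMatrix")) config$expression
          else read_expression_matrix(config$expression, config$sheet)
    ann <- config$annotation
    if (is.character(ann)) ann <- read_probe_annotation(ann)
    if (is.null(ann))
      ann <- probe_annotation(rownames(em$values),
                              rep(NA_character_, nrow(em$values)))
    gs <- config$gene_sets
    if (!is.null(gs) && !inherits(gs, "GeneSetCollection"))
      gs <- read_gene_sets(gmt_path = gs$gmt, dag_path = gs$dag,
                           dag_gmt_path = gs$dag_gmt)
    smap <- config$superordinate_map
    if (is.character(smap)) smap <- read_tsv(smap)
    fmap <- config$family_map
    if (is.character(fmap)) fmap <- read_tsv(fmap)
    list(em = em, ann = ann, gs = gs, smap = smap, fmap = fmap)
  })
  em <- inputs$em; ann <- inputs$ann
  compounds <- setdiff(unique(em$sample_sheet$compound), "control")

  ## deg -------------------------------------------------------------------
  deg_tables <- stage("deg", {
    tabs <- setNames(lapply(compounds, function(cmp)
      deg_table(em, cmp, ann, fc_min = config$fc_min,
                fdr_max = config$fdr_max)), compounds)
    for (cmp in compounds) emit(tabs[[cmp]], sprintf("deg/%s.csv", cmp))
    emit(deg_summary(tabs), "deg/summary.csv")
    tabs
  })

  ## classification --------------------------------------------------------
  classification <- stage("classification", {
    train <- contrast_set(em, compounds, batch = "training")
    test <- contrast_set(em, compounds, batch = "testing")
    model <- train_classifier(train, k = config$n_top_var, seed = config$seed)
    report <- predict_blind(model, test, group_map = config$group_map)
    emit(as.data.frame(report), "classify/predictions.csv")
    emit_json(serialize_model(model), "classify/model.json")
    list(model = model, report = report)
  })

  ## enrichment ------------------------------------------------------------
  enrichment <- stage("enrichment", {
    if (all(ann$gene == "unannotated"))
      stop("probe annotation required for gene-level enrichment")
    if (is.null(inputs$gs)) stop("gene-set collection required")
    method_for <- function(cmp) {
      ov <- config$enrich_method_overrides
      if (!is.null(ov) && cmp %in% names(ov)) ov[[cmp]] else config$enrich_method
    }
    res <- list()
    for (cmp in compounds) {
      go_dir <- enrich_by_direction(deg_tables[[cmp]], inputs$gs,
                                    mode = "separate", namespace = "dag",
                                    method = method_for(cmp),
                                    elim_cutoff = config$elim_cutoff)
      kegg_dir <- enrich_by_direction(deg_tables[[cmp]], inputs$gs,
                                      mode = "separate", namespace = "flat",
                                      method = "classic")
      pooled <- enrich_by_direction(deg_tables[[cmp]], inputs$gs,
                                    mode = "pooled", namespace = "dag",
                                    method = method_for(cmp),
                                    elim_cutoff = config$elim_cutoff)
      res[[cmp]] <- list(go = go_dir, kegg = kegg_dir, pooled = pooled$pooled)
      emit(go_dir$up, sprintf("enrich/%s_go_up.csv", cmp))
      emit(go_dir$down, sprintf("enrich/%s_go_down.csv", cmp))
      emit(kegg_dir$up, sprintf("enrich/%s_kegg_up.csv", cmp))
      emit(kegg_dir$down, sprintf("enrich/%s_kegg_down.csv", cmp))
      emit(pooled$pooled, sprintf("enrich/%s_pooled_go.csv", cmp))
    }
    res
  })

  ## profiles --------------------------------------------------------------
  profiles <- stage("profiles", {
    kept <- function(rows) nrow(apply_report_filter(rows))
    counts <- do.call(rbind, lapply(compounds, function(cmp) {
      tab <- deg_tables[[cmp]]
      e <- enrichment[[cmp]]
      data.frame(compound = cmp,
                 deg_up = sum(tab$is_DEG & tab$direction == "up"),
                 deg_down = sum(tab$is_DEG & tab$direction == "down"),
                 go_up = kept(e$go$up), go_down = kept(e$go$down),
                 kegg_up = kept(e$kegg$up), kegg_down = kept(e$kegg$down),
                 stringsAsFactors = FALSE)
    }))
    prof <- build_axes(counts, norm_by = config$toxpi_norm)
    scores <- toxpi_score(prof, config$toxpi_weights)
    smap <- inputs$smap %||%
      default_superordinate_map(names(inputs$gs$dag),
                                unlist(inputs$gs$term_names[names(inputs$gs$dag)]))
    rings <- lapply(compounds, function(cmp)
      superordinate_distribution(apply_report_filter(enrichment[[cmp]]$pooled),
                                 smap))
    names(rings) <- compounds
    out <- cbind(counts, toxpi = scores)
    emit(out, "profiles/profiles.csv")
    ring_df <- do.call(rbind, lapply(compounds, function(cmp)
      data.frame(compound = cmp, class = names(rings[[cmp]]$tally),
                 n_terms = as.integer(rings[[cmp]]$tally),
                 stringsAsFactors = FALSE)))
    emit(ring_df, "profiles/superordinate.csv")
    export_radar(prof, config$toxpi_weights,
                 path = file.path(config$out_dir, "profiles/radar.json"))
    outputs <- c(outputs, "profiles/radar.json")
    list(profile = prof, scores = scores, rings = rings)
  })

  ## biomarkers ------------------------------------------------------------
  biomarkers <- stage("biomarkers", {
    joint <- joint_signature(deg_tables)
    go_kept <- lapply(compounds, function(cmp)
      apply_report_filter(rbind(enrichment[[cmp]]$go$up,
                                enrichment[[cmp]]$go$down)))
    kegg_kept <- lapply(compounds, function(cmp)
      apply_report_filter(rbind(enrichment[[cmp]]$kegg$up,
                                enrichment[[cmp]]$kegg$down)))
    card <- score_genes(deg_tables, enriched_go = go_kept,
                        enriched_kegg = kegg_kept,
                        family_map = inputs$fmap,
                        expr_floor = config$expr_floor)
    panel <- select_final_panel(card, deg_tables, joint = joint)
    emit(joint, "biomarkers/joint_signature.csv")
    emit(card, "biomarkers/scorecards.csv")
    emit_json(list(panel = panel$panel,
                   per_compound = panel$per_compound,
                   seed = config$seed), "biomarkers/panel.json")
    list(joint = joint, scorecard = card, panel = panel)
  })

  ## su --------------------------------------------------------------------
  su <- stage("su", {
    genes <- biomarkers$panel$panel$gene
    res <- su_bootstrap(genes, em, ann, n_reps = config$su_reps,
                        seed = config$seed)
    emit_json(list(su = res$su, rbar = as.list(res$rbar),
                   null_mean = res$null_mean, null_sd = res$null_sd,
                   percentile = res$percentile, z = res$z,
                   n_reps = res$n_reps, set_size = length(genes),
                   missing = res$missing, seed = config$seed),
              "su/su_report.json")
    res
  })

  manifest <- list(
    package = "crestmark",
    seed = config$seed,
    stages = c("load", "deg", "classification", "enrichment", "profiles",
               "biomarkers", "su"),
    thresholds = list(fc_min = config$fc_min, fdr_max = config$fdr_max,
                      expr_floor = config$expr_floor,
                      n_top_var = config$n_top_var,
                      elim_cutoff = config$elim_cutoff,
                      su_reps = config$su_reps),
    outputs = sort(unique(c(outputs, "profiles/radar.json"))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(deg = deg_tables, classification = classification,
                 enrichment = enrichment, profiles = profiles,
                 biomarkers = biomarkers, su = su, manifest = manifest))
}

serialize_model <- function(model) {
  list(classes = model$classes, features = model$features, cost = model$cost,
       seed = model$seed,
       pairs = lapply(model$pairs, function(p)
         list(ci = p$ci, cj = p$cj, w = as.list(setNames(p$w, model$features)),
              b = p$b, A = p$A, B = p$B)))
}
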