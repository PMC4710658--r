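test_that("zero noise recovers every planted contrast exactly", {
  design <- study_design(seed = 2, noise_sd = 0, n_genes = 200)
  sim <- generate_expression(design)
  for (cmp in design$compounds) {
    ctr <- paired_contrasts(sim$matrix, cmp)
    planted <- design$signatures[design$signatures$compound == cmp, ]
    for (i in seq_len(nrow(planted))) {
      probes <- sim$annotation$probe_id[sim$annotation$gene == planted$gene[i]]
      expect_equal(unname(rowMeans(ctr[probes, , drop = FALSE])),
                   rep(planted$effect[i], length(probes)), tolerance = 1e-12)
    }
    # unperturbed probes show exactly zero difference
    bg <- sim$annotation$probe_id[!(sim$annotation$gene %in% planted$gene)]
    expect_true(all(ctr[bg, ] == 0))
  }
})

test_that("generated matrices satisfy the container invariants", {
  sim <- paper_sim(seed = 21, n_genes = 100)
  v <- sim$matrix$values
  expect_true(all(v >= 3 & v <= 15))
  expect_false(anyNA(v))
  sh <- sim$matrix$sample_sheet
  expect_identical(sum(sh$compound == "control"), 15L)
  expect_identical(length(unique(sh$control_group[sh$compound == "control"])), 3L)
  # the three HDACi/common-control groups of the modelled design
  expect_identical(unname(sim$design$control_group[c("GA", "PBDE", "TDF")]),
                   rep("ctrlA", 3))
  expect_identical(unname(sim$design$control_group[c("TSA", "VPA")]),
                   rep("ctrlB", 2))
})

test_that("noisy contrasts concentrate around planted effects as normal theory predicts", {
  design <- study_design(seed = 31, noise_sd = 0.25, n_genes = 500)
  sim <- generate_expression(design)
  # contrast = treated - matched control, so SD = noise_sd * sqrt(2); the
  # mean over n replicates has SE = noise_sd * sqrt(2 / n)
  ok <- 0L; total <- 0L
  for (cmp in design$compounds) {
    ctr <- paired_contrasts(sim$matrix, cmp)
    n <- ncol(ctr)
    se <- 0.25 * sqrt(2 / n)
    planted <- design$signatures[design$signatures$compound == cmp, ]
    probes_of <- split(sim$annotation$probe_id, sim$annotation$gene)
    for (i in seq_len(nrow(planted))) {
      m <- mean(rowMeans(ctr[probes_of[[planted$gene[i]]], , drop = FALSE]))
      ok <- ok + (abs(m - planted$effect[i]) <= 3 * se)
      total <- total + 1L
    }
  }
  expect_gte(ok / total, 0.99)
})

test_that("shared-pair signatures are near-identical by construction", {
  design <- study_design(seed = 4)
  sig <- design$signatures
  a <- sig[sig$compound == "TSA", ]
  b <- sig[sig$compound == "VPA", ]
  expect_setequal(a$gene, b$gene)
  expect_gte(cor(a$effect, b$effect[match(a$gene, b$gene)]), 0.95)
})

test_that("synthetic annotation respects DAG and class structure and is seeded", {
  ann1 <- generate_annotation(200, n_terms = 30, seed = 9)
  ann2 <- generate_annotation(200, n_terms = 30, seed = 9)
  expect_identical(ann1$collection$dag, ann2$collection$dag)
  expect_identical(ann1$superordinate_map, ann2$superordinate_map)

  coll <- ann1$collection
  for (t in names(coll$dag_parents)) {
    for (p in coll$dag_parents[[t]]) {
      expect_true(all(coll$dag[[t]] %in% coll$dag[[p]]))
    }
  }
  expect_setequal(unique(ann1$superordinate_map$class),
                  c("migration/adhesion", "metabolism", "differentiation",
                    "signalling", "stress response", "other"))

  tiny <- generate_annotation(100, n_terms = 6, seed = 1)
  expect_identical(sort(tiny$superordinate_map$class),
                   sort(c("migration/adhesion", "metabolism", "differentiation",
                          "signalling", "stress response", "other")))
})

test_that("biomarker scenario plants a designated set disjoint from other signatures", {
  design <- study_design(seed = 6, n_genes = 600)
  base_genes <- unique(design$signatures$gene)
  design2 <- plant_biomarker_scenario(design)
  expect_length(design2$biomarker_set, 39)
  expect_length(intersect(design2$biomarker_set, base_genes), 0)
  planted <- design2$signatures[design2$signatures$gene %in% design2$biomarker_set, ]
  per_gene <- table(planted$gene)
  expect_true(all(per_gene >= 4))

  # too few unperturbed genes left -> error
  small <- study_design(seed = 6, n_genes = 60,
                        signature_sizes = setNames(rep(10, 6),
                                                   study_design()$compounds))
  small$signatures <- data.frame(compound = "GA", gene = small$genes[1:40],
                                 effect = 1, direction = "up",
                                 stringsAsFactors = FALSE)
  expect_error(plant_biomarker_scenario(small), "unperturbed genes")
})
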