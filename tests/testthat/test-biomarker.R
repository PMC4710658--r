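# minimal DEGTable builder for selection-logic tests
mk_tab <- function(genes, log2FC, adj_p, ctrl_expr = 8,
                   probe_id = NULL) {
  n <- length(genes)
  tab <- data.frame(
    probe_id = probe_id %||% sprintf("ps%02d", seq_len(n)),
    gene = genes,
    log2FC = rep_len(log2FC, n),
    p = rep_len(adj_p, n),
    adj_p = rep_len(adj_p, n),
    ctrl_expr = rep_len(ctrl_expr, n),
    stringsAsFactors = FALSE)
  call_degs(tab)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("joint signature requires DEG in enough compounds, ignoring direction", {
  cmps <- c("c1", "c2", "c3", "c4", "c5", "c6")
  # gA: DEG in 4 compounds (3 up, 1 down); gB: 3 compounds; gC: 5 compounds
  tabs <- setNames(lapply(seq_along(cmps), function(i) {
    genes <- c("gA", "gB", "gC")
    fc <- c(if (i <= 3) 1 else if (i == 4) -1 else 0.1,
            if (i <= 3) 1 else 0.1,
            if (i <= 5) 1 else 0.1)
    mk_tab(genes, fc, 0.01)
  }), cmps)
  js <- joint_signature(tabs, min_compounds = 4)
  expect_setequal(js$gene, c("gA", "gC"))
  expect_equal(js$n_compounds[js$gene == "gA"], 4L)
  expect_identical(js$c4[js$gene == "gA"], "down")
  expect_identical(js$c1[js$gene == "gA"], "up")

  all_genes <- joint_signature(tabs, min_compounds = 1)
  expect_setequal(all_genes$gene, c("gA", "gB", "gC"))
  expect_equal(nrow(joint_signature(tabs, min_compounds = 7)), 0)
})

test_that("scoring enforces minimum criteria and sums component points", {
  # gene below the fold-change threshold is never scored
  tabs <- list(c1 = mk_tab("gLow", log2(1.7), 0.001))
  expect_equal(nrow(score_genes(tabs)), 0)

  # gene below the expression floor is never scored
  tabs2 <- list(c1 = mk_tab("gDim", 1.5, 0.001, ctrl_expr = 4.5))
  expect_equal(nrow(score_genes(tabs2)), 0)

  # two same-direction probes + enriched-GO member + related DEG gene:
  # confirmation + GO + related (+ expression + p strength) >= 3
  tab <- mk_tab(c("gHit", "gHit", "gKin"), c(1.5, 1.4, 1.2), 1e-5,
                ctrl_expr = c(9, 9, 9))
  enr <- data.frame(term_id = "T1", genes = "gHit", adj_p = 0.01)
  fam <- data.frame(gene = c("gHit", "gKin"), family = "famX")
  card <- score_genes(list(c1 = tab), enriched_go = enr, family_map = fam)
  row <- card[card$gene == "gHit", ]
  expect_equal(row$confirmation, 1L)
  expect_equal(row$go_member, 1L)
  expect_equal(row$related_gene, 1L)
  expect_equal(row$p_strength, 1L)
  expect_gte(row$total, 3)
  expect_true(row$shortlisted)
  expect_equal(row$total, sum(row[, c("expression_level", "confirmation",
                                      "related_gene", "go_member",
                                      "kegg_member", "p_strength")]))
  # single down-direction probe gets no confirmation or membership points
  other <- card[card$gene == "gKin", ]
  expect_equal(other$confirmation, 0L)
  expect_equal(other$go_member, 0L)
})

test_that("final panel selection is deterministic with declared tie-breaks", {
  genes <- sprintf("g%02d", 1:6)
  tab <- mk_tab(genes, 1.5, c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 2e-2))
  card <- score_genes(list(c1 = tab))
  card$total <- c(4, 4, 4, 4, 3, 3)
  card$shortlisted <- TRUE
  sel <- select_final_panel(card, list(c1 = tab), per_compound_min = 1,
                            per_compound_max = 4)
  # ties on score resolved by ascending p
  expect_identical(sel$per_compound$c1, genes[1:4])

  joint <- data.frame(gene = c("g01", "gZZ"))
  sel2 <- select_final_panel(card, list(c1 = tab), per_compound_min = 1,
                             per_compound_max = 4, joint = joint)
  expect_identical(sel2$panel$origin[sel2$panel$gene == "g01"], "both")
  expect_identical(sel2$panel$origin[sel2$panel$gene == "gZZ"], "joint")
  expect_equal(sum(sel2$panel$gene == "g01"), 1L)
  expect_warning(
    select_final_panel(card, list(c1 = tab), per_compound_min = 10,
                       per_compound_max = 12),
    "shortlisted")
})

test_that("SU formula attains its analytic bounds and hand values", {
  expect_equal(su_from_ranks(rep(1, 6)), sqrt(6))
  expect_equal(round(su_from_ranks(rep(1, 6)), 2), 2.45)
  expect_equal(su_from_ranks(rep(0, 6)), 0)
  expect_equal(su_from_ranks(rep(0.5, 6)), sqrt(1.5))
  expect_error(su_from_ranks(c(0.5, 1.2, rep(0, 4))), "\\[0, 1\\]")
  # monotone in each component
  base <- rep(0.4, 6)
  for (i in 1:6) {
    up <- base; up[i] <- 0.9
    expect_gt(su_from_ranks(up), su_from_ranks(base))
  }
})

test_that("a uniquely dominant gene reaches SU = sqrt(6); missing genes get r = 0", {
  design <- study_design(seed = 19, n_genes = 300, noise_sd = 0.1,
                         effect_range = c(0.3, 0.5), baseline_range = c(6, 10))
  # one gene with a much larger effect than any signature gene, all compounds
  design$signatures <- rbind(
    design$signatures[design$signatures$gene != "g0001", ],
    data.frame(compound = design$compounds, gene = "g0001", effect = 4,
               direction = "up", stringsAsFactors = FALSE))
  sim <- generate_expression(design)
  ranks <- su_ranks(sim$matrix, sim$annotation)
  res <- su_metric("g0001", ranks = ranks)
  expect_equal(res$su, sqrt(6), tolerance = 1e-12)
  expect_equal(unname(res$rbar), rep(1, 6))

  expect_message(res0 <- su_metric("not_a_gene", ranks = ranks),
                 "outside the filtered pool")
  expect_equal(res0$su, 0)
  expect_identical(res0$missing, "not_a_gene")
})

test_that("bootstrap null is stable, bounded, and flags planted sets", {
  sim <- paper_sim(seed = 3, effect_range = c(0.9, 2.0), planted_set = TRUE)
  ranks <- su_ranks(sim$matrix, sim$annotation)
  expect_true(all(ranks$r >= 0 & ranks$r <= 1))

  res <- su_bootstrap(sim$design$biomarker_set, ranks = ranks,
                      n_reps = 2000, seed = 5)
  expect_gte(res$z, 6)
  expect_true(all(res$null_su >= 0 & res$null_su <= sqrt(6)))
  expect_gt(res$su, res$null_mean)

  # null mean converges across rep counts (Monte-Carlo error shrinks)
  r10 <- su_bootstrap(sim$design$biomarker_set, ranks = ranks,
                      n_reps = 10, seed = 5)
  r2000 <- res
  expect_lt(abs(r10$null_mean - r2000$null_mean),
            3 * sd(r2000$null_su) / sqrt(10) + 3 * sd(r2000$null_su) / sqrt(2000))

  # a random candidate drawn from the pool sits inside its own null
  set.seed(6)
  rand_set <- sample(ranks$pool, 39)
  rr <- su_bootstrap(rand_set, ranks = ranks, n_reps = 2000, seed = 7)
  expect_gt(rr$percentile, 0.1)
  expect_lt(rr$percentile, 99.9)

  expect_error(su_bootstrap(rand_set, ranks = ranks, set_size = 1e6),
               "smaller than set size")
})
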