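toy_universe <- sprintf("g%02d", 1:20)

toy_collection <- function() {
  gene_set_collection(
    flat = list(K1 = sprintf("g%02d", 1:10), K2 = sprintf("g%02d", 11:20)),
    dag = list(root = character(0),
               parent = sprintf("g%02d", 1:10),
               child = sprintf("g%02d", 1:5)),
    dag_parents = list(root = character(0), parent = "root", child = "parent"),
    universe = toy_universe)
}

test_that("classic Fisher enrichment matches hypergeometric enumeration and edge cases", {
  coll <- toy_collection()

  # disjoint term: overlap 0 -> p = 1 under the over-representation tail
  rows <- fisher_enrich(sprintf("g%02d", 1:5), coll, namespace = "flat")
  expect_equal(rows$p[rows$term_id == "K2"], 1)
  expect_equal(rows$overlap[rows$term_id == "K2"], 0)

  # specific table: universe 100, term 10, DEG 20, overlap 8
  expect_equal(fisher_overrep_p(8, 10, 20, 100),
               hyper_tail_oracle(8, 10, 20, 100), tolerance = 1e-12)

  # DEG = universe: every overlap = term size, p = 1
  rows_all <- fisher_enrich(toy_universe, coll, namespace = "flat")
  expect_true(all(rows_all$overlap == rows_all$size))
  expect_true(all(rows_all$p == 1))

  expect_error(fisher_enrich("g01", coll, universe = character(0)), "empty")
})

test_that("elim eliminates parents driven by significant children; cutoff 0 reduces to classic", {
  coll <- toy_collection()
  deg <- sprintf("g%02d", 1:5)

  classic <- fisher_enrich(deg, coll, namespace = "dag")
  # frozen closed forms: child C(20,5) tables computed by hand
  expect_equal(classic$p[classic$term_id == "child"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(classic$p[classic$term_id == "parent"],
               choose(10, 5) / choose(20, 5), tolerance = 1e-12)
  expect_true(all(classic$p[classic$term_id %in% c("child", "parent")] < 0.05))

  el <- elim_enrich(deg, coll, elim_cutoff = 0.01)
  expect_equal(el$p[el$term_id == "child"], 1 / choose(20, 5), tolerance = 1e-12)
  # parent retested on its remaining 5 genes with 0 DEG -> p = 1
  expect_equal(el$size[el$term_id == "parent"], 5)
  expect_equal(el$overlap[el$term_id == "parent"], 0)
  expect_equal(el$p[el$term_id == "parent"], 1)

  el0 <- elim_enrich(deg, coll, elim_cutoff = 0)
  expect_equal(el0$p[order(el0$term_id)], classic$p[order(classic$term_id)],
               tolerance = 1e-12)
  expect_equal(el0$overlap[order(el0$term_id)],
               classic$overlap[order(classic$term_id)])

  expect_error(elim_enrich(deg, gene_set_collection(
    flat = list(K = "g01"), universe = toy_universe)), "no DAG terms")
})

test_that("report filter keeps significant terms by count or small-term fraction", {
  rows <- data.frame(
    term_id = c("a", "b", "c", "d"),
    size = c(4, 40, 30, 10),
    overlap = c(2, 2, 3, 5),
    adj_p = c(0.01, 0.01, 0.2, 0.001))
  kept <- apply_report_filter(rows)
  # a: 50% rule; b: neither rule; c: fails significance; d: count rule
  expect_setequal(kept$term_id, c("a", "d"))
  expect_true(all(kept$kept))
})

test_that("directional enrichment splits gene lists and pools their union", {
  coll <- toy_collection()
  tab <- data.frame(
    probe_id = sprintf("p%02d", 1:8),
    gene = c("g01", "g02", "g03", "g11", "g12", "g04", "g05", "unannotated"),
    log2FC = c(1, 1, 1, -1, -1, 1, -1, 2),
    adj_p = rep(0.01, 8))
  tab <- call_degs(tab, fc_min = 1.8)
  tab$is_DEG <- abs(tab$log2FC) >= 0.9  # directions as constructed
  res <- enrich_by_direction(tab, coll, mode = "separate", namespace = "flat",
                             method = "classic")
  up_k1 <- res$up[res$up$term_id == "K1", ]
  expect_equal(up_k1$overlap, 4)  # g01 g02 g03 g04
  down_k1 <- res$down[res$down$term_id == "K1", ]
  expect_equal(down_k1$overlap, 1)  # g05

  pooled <- enrich_by_direction(tab, coll, mode = "pooled", namespace = "flat",
                                method = "classic")$pooled
  # pooled overlap equals the union of the directional gene lists
  expect_equal(pooled$overlap[pooled$term_id == "K1"], 5)
  expect_false(any(grepl("unannotated", pooled$genes)))

  # no downregulated DEG -> empty down gene list, no enriched down rows
  tab_up <- tab
  tab_up$is_DEG <- tab_up$direction == "up" & tab_up$gene != "unannotated"
  res_up <- enrich_by_direction(tab_up, coll, mode = "separate",
                                namespace = "flat", method = "classic")
  expect_true(all(res_up$down$overlap == 0))
  expect_equal(nrow(apply_report_filter(res_up$down)), 0)
})

test_that("Fisher p equals exhaustive enumeration for every table with universe <= 60", {
  grid <- do.call(rbind, lapply(1:60, function(N)
    data.frame(N = N, K = rep(0:N, each = N + 1), n = rep(0:N, times = N + 1))))
  # all attainable overlap counts per table
  lo <- pmax(0, grid$n + grid$K - grid$N)
  hi <- pmin(grid$K, grid$n)
  len <- hi - lo + 1
  N <- rep(grid$N, len); K <- rep(grid$K, len); n <- rep(grid$n, len)
  k <- sequence(len) - 1L + rep(lo, len)

  p_impl <- fisher_overrep_p(k, K, n, N)

  # enumeration oracle: point probabilities from binomial coefficients,
  # upper tails as reverse cumulative sums within each table
  pt_prob <- exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
  cs <- cumsum(pt_prob)
  ends <- cumsum(len)
  p_oracle <- rep(cs[ends], len) - c(0, cs)[seq_along(pt_prob)]
  expect_lt(max(abs(p_impl - pmin(p_oracle, 1))), 1e-9)
})

test_that("a planted pathway is top-ranked in its matching direction", {
  sim <- paper_sim(seed = 41, effect_range = c(1.5, 1.5), n_genes = 600)
  cmp <- "GA"
  planted_up <- unique(sim$truth$gene[sim$truth$compound == cmp &
                                      sim$truth$direction == "up"])
  set.seed(18)
  coll <- gene_set_collection(
    flat = c(list(PATH = sample(planted_up, 20)),
             setNames(lapply(1:5, function(i) sample(sim$design$genes, 20)),
                      paste0("RND", 1:5))),
    universe = sim$design$genes)
  tab <- deg_table(sim$matrix, cmp, sim$annotation)
  res <- enrich_by_direction(tab, coll, mode = "separate", namespace = "flat",
                             method = "classic")
  expect_identical(res$up$term_id[which.min(res$up$p)], "PATH")
})
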