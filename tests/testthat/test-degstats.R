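test_that("paired contrasts subtract matched controls by replicate index", {
  em0 <- tiny_em(trt_offset = 0)
  expect_true(all(paired_contrasts(em0, "cmpA") == 0))
  em1 <- tiny_em(trt_offset = 1)
  expect_true(all(paired_contrasts(em1, "cmpA") == 1))
  expect_error(paired_contrasts(em1, "nope"), "not present")

  # replicate-index pairing: perturb control replicate 2 only; the
  # difference must land entirely on treated replicate 2
  em <- tiny_em(trt_offset = 0)
  v <- em$values
  v["p01", "c2"] <- v["p01", "c2"] + 0.5
  em <- expression_matrix(v, em$sample_sheet)
  ctr <- paired_contrasts(em, "cmpA")
  expect_equal(unname(ctr["p01", c("t1", "t2")]), c(0, -0.5))
})

test_that("moderated t handles degenerate probes and reduces to known limits", {
  set.seed(10)
  m <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(sprintf("p%03d", 1:100)))
  m[1, ] <- 0  # all-zero probe

  mt <- moderated_t(m)
  expect_equal(mt$table$t[1], 0)
  expect_equal(mt$table$p[1], 1)
  expect_gt(mt$params$d0, 0)
  # posterior variance lies in the envelope spanned by s^2 and s0^2
  s2 <- apply(m, 1, var)
  env_lo <- pmin(s2, mt$params$s0_sq)
  env_hi <- pmax(s2, mt$params$s0_sq)
  expect_true(all(mt$params$s2_post >= env_lo - 1e-12 &
                  mt$params$s2_post <= env_hi + 1e-12))

  # d0 = 0: ordinary one-sample t, closed form on 5 numbers
  x <- c(0.3, 1.1, -0.2, 0.8, 0.5)
  mx <- matrix(x, 1, 5, dimnames = list("probe"))
  t_ref <- mean(x) / (sd(x) / sqrt(5))
  mt0 <- moderated_t(rbind(probe = x, other = rnorm(5)), d0 = 0)
  expect_equal(mt0$table$t[1], t_ref, tolerance = 1e-12)
  expect_equal(mt0$table$p[1], 2 * pt(-abs(t_ref), df = 4), tolerance = 1e-12)

  # d0 = Inf: fixed-variance statistic mean / (s0 / sqrt(n))
  mtInf <- moderated_t(mx, d0 = Inf, s0_sq = 0.25)
  expect_equal(mtInf$table$t[1], mean(x) / (0.5 / sqrt(5)), tolerance = 1e-12)

  expect_error(moderated_t(matrix(1, 3, 4)), "degenerate")
  expect_error(moderated_t(matrix(1, 3, 1)), ">= 2 replicates")
})

test_that("moderated t agrees with the limma empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  set.seed(11)
  sigma2 <- 0.3 * 6 / rchisq(400, df = 6)
  m <- t(vapply(sigma2, function(s2) rnorm(5, 0, sqrt(s2)), numeric(5)))
  rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  mt <- moderated_t(m)
  fit <- limma::eBayes(limma::lmFit(m, design = matrix(1, 5, 1)))
  expect_equal(mt$params$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(mt$params$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(mt$table$t, unname(fit$t[, 1]), tolerance = 1e-9)
  expect_equal(mt$table$p, unname(fit$p.value[, 1]), tolerance = 1e-9)
})

test_that("moderated-t p-values are uniform under the null", {
  set.seed(12)
  m <- matrix(rnorm(2000 * 5), 2000, 5,
              dimnames = list(sprintf("p%04d", 1:2000)))
  mt <- moderated_t(m)
  ks <- suppressWarnings(ks.test(mt$table$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches hand-computed and definitional results", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone over the order statistics
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("DEG calling applies inclusive thresholds and is threshold-monotone", {
  tab <- data.frame(
    probe_id = c("a", "b", "c", "d"),
    log2FC = c(log2(1.8), 0.5, -log2(1.8), -2),
    adj_p = c(0.05, 0.001, 0.049, 0.2))
  out <- call_degs(tab)
  expect_identical(out$is_DEG, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(out$direction, c("up", "up", "down", "down"))
  expect_identical(unname(attr(out, "summary")), c(1L, 1L))

  # raising fc_min never adds a DEG; calling is idempotent
  set.seed(14)
  tab2 <- data.frame(probe_id = sprintf("p%03d", 1:200),
                     log2FC = rnorm(200, 0, 1.2),
                     adj_p = runif(200)^2)
  prev <- rep(TRUE, 200)
  for (fc in c(1.2, 1.8, 2.5, 4)) {
    cur <- call_degs(tab2, fc_min = fc)$is_DEG
    expect_true(all(!cur | prev))
    expect_identical(call_degs(call_degs(tab2, fc_min = fc), fc_min = fc)$is_DEG, cur)
    prev <- cur
  }
})

test_that("planted DEG are recovered with high sensitivity and controlled FDR", {
  sim <- paper_sim(seed = 41, effect_range = c(1.5, 1.5), n_genes = 600)
  called <- character(0); truth <- character(0)
  fp <- 0L; pos <- 0L
  for (cmp in sim$design$compounds) {
    tab <- deg_table(sim$matrix, cmp, sim$annotation)
    planted <- unique(sim$truth$gene[sim$truth$compound == cmp])
    found <- unique(tab$gene[tab$is_DEG & tab$gene != "unannotated"])
    called <- c(called, paste(cmp, found)); truth <- c(truth, paste(cmp, planted))
    fp <- fp + length(setdiff(found, planted))
    pos <- pos + length(found)
  }
  sens <- length(intersect(called, truth)) / length(truth)
  expect_gte(sens, 0.90)
  expect_lte(fp / max(pos, 1), 0.05)
})

test_that("top-variance selection matches a direct oracle and breaks ties by id", {
  set.seed(15)
  m <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(sprintf("p%02d", 20:1)))
  sel <- top_variance_features(m, k = 7)
  v <- apply(m, 1, var)
  expect_identical(sel, names(sort(v, decreasing = TRUE))[1:7])

  const <- matrix(5, 4, 3, dimnames = list(c("pb", "pa", "pd", "pc")))
  expect_identical(top_variance_features(const, k = 4),
                   c("pa", "pb", "pc", "pd"))
  one_hot <- const
  one_hot["pc", ] <- c(1, 5, 9)
  expect_identical(top_variance_features(one_hot, k = 1), "pc")
  expect_error(top_variance_features(const, k = 9), "exceeds")
})

test_that("2D PCA separates point clouds and matches the eigenvalue oracle", {
  set.seed(16)
  cloud <- cbind(matrix(rnorm(30 * 4, 0, 0.1), 30),
                 matrix(rnorm(30 * 4, 3, 0.1), 30))
  rownames(cloud) <- sprintf("p%02d", 1:30)
  colnames(cloud) <- sprintf("s%d", 1:8)
  pc <- pca_2d(cloud)
  lab <- rep(c("A", "B"), each = 4)
  expect_true(max(pc$coordinates$PC1[lab == "A"]) <
              min(pc$coordinates$PC1[lab == "B"]) ||
              min(pc$coordinates$PC1[lab == "A"]) >
              max(pc$coordinates$PC1[lab == "B"]))
  expect_gt(pc$var_explained[["PC1"]], pc$var_explained[["PC2"]])

  # variance fractions against a full eigendecomposition
  X <- scale(t(cloud), center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)$values
  expect_equal(unname(pc$var_explained),
               (ev / sum(ev))[1:2], tolerance = 1e-9)
  expect_lte(sum(pc$var_explained), 1)

  dup <- cloud[, c(1, 1, 2, 3)]
  colnames(dup) <- c("s1", "s1b", "s2", "s3")
  pcd <- pca_2d(dup)
  expect_equal(pcd$coordinates[1, -1], pcd$coordinates[2, -1],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca_2d(cloud[, 1:2]), "3 samples")
})
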