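# Shared fixtures and independent oracles. Everything is built in code;
# expensive synthetic studies are cached per seed within the test run.

.fixture_cache <- new.env(parent = emptyenv())

# paper-layout synthetic study (6 compounds, 3+2 reps, 15 controls), cached
paper_sim <- function(seed, effect_range = c(1.2, 2.0), noise_sd = 0.25,
                      n_genes = 1000, planted_set = FALSE) {
  key <- paste(seed, paste(effect_range, collapse = "-"), noise_sd, n_genes,
               planted_set, sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  design <- study_design(seed = seed, effect_range = effect_range,
                         noise_sd = noise_sd, n_genes = n_genes)
  if (planted_set) design <- plant_biomarker_scenario(design)
  sim <- generate_expression(design)
  out <- list(design = design, matrix = sim$matrix,
              annotation = sim$annotation, truth = sim$truth)
  .fixture_cache[[key]] <- out
  out
}

# tiny handmade ExpressionMatrix: n_probes x (1 compound x 2 reps + 2 ctrl),
# single batch, used for loader and contrast unit tests
tiny_em <- function(trt_offset = 0) {
  probes <- sprintf("p%02d", 1:4)
  base <- c(6, 8, 10, 12)
  vals <- cbind(c1 = base, c2 = base,
                t1 = base + trt_offset, t2 = base + trt_offset)
  rownames(vals) <- probes
  sheet <- data.frame(
    sample_id = c("c1", "c2", "t1", "t2"),
    compound = c("control", "control", "cmpA", "cmpA"),
    replicate = c(1, 2, 1, 2),
    batch = "training",
    control_group = "ctrlA",
    stringsAsFactors = FALSE)
  expression_matrix(vals, sheet)
}

# --- independent oracles -------------------------------------------------

# hypergeometric upper tail by direct enumeration of binomial coefficients
hyper_tail_oracle <- function(k, K, n, N) {
  js <- seq(k, min(K, n))
  js <- js[js >= max(0, n + K - N)]
  if (length(js) == 0) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# BH from its definition: adjusted p_i is the smallest level q at which the
# step-up procedure rejects hypothesis i. At level q the procedure rejects
# hypotheses 1..j* (sorted), j* = max{j : p_(j) <= q j/m}; so hypothesis
# with rank r is rejected iff some j >= r has m p_(j) / j <= q, and its
# adjusted value is min_{j >= r} m p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    r <- which(ps == pi)[1]
    min(1, min(m * ps[r:m] / (r:m)))
  }, numeric(1))
}

# dense + locally refined simplex grid minimizer of the pairwise-coupling
# QP objective for 3 classes; vectorized over grid points
coupling_grid_oracle <- function(R, coarse = 0.002, fine = 1e-4) {
  qp_obj <- function(P) {
    v <- 0
    for (i in 1:3) for (j in 1:3) if (i != j)
      v <- v + (R[j, i] * P[, i] - R[i, j] * P[, j])^2
    v
  }
  simplex_grid <- function(lo1, hi1, lo2fun, hi2fun, step) {
    p1 <- seq(lo1, hi1, by = step)
    pts <- do.call(rbind, lapply(p1, function(a) {
      lo2 <- max(0, lo2fun(a)); hi2 <- min(1 - a, hi2fun(a))
      if (lo2 > hi2) return(NULL)
      b <- seq(lo2, hi2, by = step)
      cbind(a, b, 1 - a - b)
    }))
    pts[pts[, 3] >= -1e-12, , drop = FALSE]
  }
  P <- simplex_grid(0, 1, function(a) 0, function(a) 1, coarse)
  best <- P[which.min(qp_obj(P)), ]
  P2 <- simplex_grid(max(0, best[1] - coarse), min(1, best[1] + coarse),
                     function(a) best[2] - coarse,
                     function(a) best[2] + coarse, fine)
  unname(P2[which.min(qp_obj(P2)), ])
}

# group map for the HDACi analogue pair in the default synthetic design
hdaci_groups <- c(TSA = "HDACi", VPA = "HDACi")

# all permutations of 1..n as a matrix (one permutation per row)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
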