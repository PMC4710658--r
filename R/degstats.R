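# Paired-design differential expression. Each treated replicate is reduced to
# a difference against its matched control (same control group, same batch;
# paired by replicate index when counts allow, otherwise against the control
# group mean). Statistics are one-sample moderated t-tests of these
# differences against zero, with empirical-Bayes shrinkage of the per-probe
# variance towards a prior estimated by the method of moments on the log
# sample variances.

#' Paired contrasts for one compound
#'
#' @param em an `ExpressionMatrix`
#' @param compound compound id present in the sample sheet
#' @param batch restrict to `"training"` or `"testing"` (default: all)
#' @return a `ContrastMatrix`: numeric matrix probes x treated replicates of
#'   log2 differences, with attributes `compound` and `ctrl_mean` (per-probe
#'   mean of all matched controls used, the control expression level)
#' @export
paired_contrasts <- function(em, compound, batch = NULL) {
  sh <- em$sample_sheet
  if (!compound %in% sh$compound)
    stop_format("compound '%s' not present in the study", compound)
  trt <- sh[sh$compound == compound, , drop = FALSE]
  if (!is.null(batch)) trt <- trt[trt$batch %in% batch, , drop = FALSE]
  if (nrow(trt) == 0)
    stop_format("no '%s' samples in batch '%s'", compound, paste(batch, collapse = ","))

  diffs <- matrix(NA_real_, nrow(em$values), nrow(trt),
                  dimnames = list(rownames(em$values), trt$sample_id))
  ctrl_used <- character(0)
  for (b in unique(trt$batch)) {
    tb <- trt[trt$batch == b, , drop = FALSE]
    tb <- tb[order(tb$replicate), , drop = FALSE]
    cb <- sh[sh$compound == "control" & sh$batch == b &
               sh$control_group == tb$control_group[1], , drop = FALSE]
    cb <- cb[order(cb$replicate), , drop = FALSE]
    ctrl_used <- c(ctrl_used, cb$sample_id)
    cv <- em$values[, cb$sample_id, drop = FALSE]
    if (nrow(cb) == nrow(tb)) {
      # replicate-index pairing preserves n and the paired structure
      for (i in seq_len(nrow(tb)))
        diffs[, tb$sample_id[i]] <- em$values[, tb$sample_id[i]] - cv[, i]
    } else {
      cm <- rowMeans(cv)
      for (i in seq_len(nrow(tb)))
        diffs[, tb$sample_id[i]] <- em$values[, tb$sample_id[i]] - cm
    }
  }
  ctrl_mean <- rowMeans(em$values[, unique(ctrl_used), drop = FALSE])
  structure(diffs, compound = compound, ctrl_mean = ctrl_mean,
            class = c("ContrastMatrix", "matrix", "array"))
}

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' One-sample moderated t-statistics with empirical-Bayes shrinkage
#'
#' Tests the per-probe mean difference against zero. The posterior variance
#' is `(d0*s0^2 + d*s^2) / (d0 + d)` with `d = n - 1`; the prior degrees of
#' freedom `d0` and prior variance `s0^2` are estimated by the method of
#' moments on the log sample variances (matching the scaled inverse
#' chi-square hierarchical model), unless supplied. `d0 = 0` reduces to the
#' ordinary one-sample t; `d0 = Inf` to a fixed-variance statistic
#' `mean / (s0 / sqrt(n))`. Two-sided p-values use `d0 + d` degrees of
#' freedom.
#'
#' @param contrasts a `ContrastMatrix` (or probes x replicates matrix)
#' @param d0 prior degrees of freedom; `NULL` (default) to estimate,
#'   `0` or `Inf` to force the limits
#' @param s0_sq prior variance; `NULL` to estimate
#' @return list with `table` (data frame `probe_id`, `log2FC`, `t`, `p`,
#'   `df`) and `params` (list `d0`, `s0_sq`, `s2_post`)
#' @export
moderated_t <- function(contrasts, d0 = NULL, s0_sq = NULL) {
  m <- unclass(contrasts)
  n <- ncol(m)
  if (n < 2) stop_format("need >= 2 replicates for a moderated t")
  mu <- rowMeans(m)
  s2 <- apply(m, 1, var)
  d <- n - 1

  if (all(s2 == 0) && is.null(s0_sq) && !identical(d0, 0))
    stop_format("degenerate fit: zero variance for every probe")

  est <- estimate_prior(s2, d)
  if (is.null(d0)) d0 <- est$d0
  if (is.null(s0_sq)) s0_sq <- est$s0_sq

  if (d0 == 0) {
    s2_post <- s2
    df <- d
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
    df <- Inf
  } else {
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
    df <- d0 + d
  }
  se <- sqrt(s2_post / n)
  tstat <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, sign(mu) * Inf))
  p <- 2 * pt(-abs(tstat), df = df)
  list(table = data.frame(probe_id = rownames(m), log2FC = mu, t = tstat,
                          p = p, df = df, stringsAsFactors = FALSE),
       params = list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post))
}

# method-of-moments fit of the scaled inverse chi-square prior on variances;
# if the moment estimate of d0 is non-positive, fall back to d0 = Inf
# (pooled prior)
estimate_prior <- function(s2, d) {
  ok <- s2 > 0
  if (!any(ok)) return(list(d0 = Inf, s0_sq = mean(s2) + 1e-8))
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- if (sum(ok) > 1) var(e) else 0
  rhs <- evar - trigamma(d / 2)
  if (rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, monotone over the order statistics, capped at 1
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_format("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Full DEG table for one compound
#'
#' Chains [paired_contrasts()], [moderated_t()], [bh_adjust()] and
#' [call_degs()].
#'
#' @param em an `ExpressionMatrix`
#' @param compound compound id
#' @param annotation a `ProbeAnnotation`
#' @param batch optional batch restriction
#' @param fc_min,fdr_max DEG thresholds (defaults 1.8 fold, FDR 0.05)
#' @param d0,s0_sq optional prior overrides, see [moderated_t()]
#' @return a `DEGTable` data frame: `probe_id`, `gene`, `log2FC`, `t`, `p`,
#'   `adj_p`, `direction`, `is_DEG`, `ctrl_expr`
#' @export
deg_table <- function(em, compound, annotation, batch = NULL,
                      fc_min = 1.8, fdr_max = 0.05, d0 = NULL, s0_sq = NULL) {
  ctr <- paired_contrasts(em, compound, batch = batch)
  mt <- moderated_t(ctr, d0 = d0, s0_sq = s0_sq)
  tab <- mt$table
  tab$gene <- probe_genes(tab$probe_id, annotation)
  tab$adj_p <- bh_adjust(tab$p)
  tab$ctrl_expr <- attr(ctr, "ctrl_mean")[tab$probe_id]
  tab <- tab[, c("probe_id", "gene", "log2FC", "t", "p", "adj_p", "ctrl_expr")]
  call_degs(tab, fc_min = fc_min, fdr_max = fdr_max)
}

#' Flag differentially expressed probes
#'
#' A probe is a DEG when its FDR-adjusted p-value is at most `fdr_max` and
#' its absolute fold change is at least `fc_min` (i.e. |log2FC| >=
#' log2(`fc_min`)); both boundaries inclusive.
#'
#' @param table data frame with columns `log2FC` and `adj_p`
#' @param fc_min fold-change threshold on the natural scale (default 1.8)
#' @param fdr_max adjusted-p threshold (default 0.05)
#' @return the table with `direction` (`"up"`/`"down"`) and logical `is_DEG`
#'   columns (re)computed; attribute `summary` holds the up/down counts
#' @export
call_degs <- function(table, fc_min = 1.8, fdr_max = 0.05) {
  stopifnot(fc_min > 0, fdr_max > 0)
  table$direction <- ifelse(table$log2FC >= 0, "up", "down")
  table$is_DEG <- table$adj_p <= fdr_max & abs(table$log2FC) >= log2(fc_min)
  attr(table, "summary") <- c(up = sum(table$is_DEG & table$direction == "up"),
                              down = sum(table$is_DEG & table$direction == "down"))
  class(table) <- unique(c("DEGTable", class(table)))
  table
}

#' Per-compound DEG counts
#'
#' @param deg_tables named list of `DEGTable`s
#' @return data frame `compound`, `deg_up`, `deg_down`
#' @export
deg_summary <- function(deg_tables) {
  do.call(rbind, lapply(names(deg_tables), function(cmp) {
    tab <- deg_tables[[cmp]]
    data.frame(compound = cmp,
               deg_up = sum(tab$is_DEG & tab$direction == "up"),
               deg_down = sum(tab$is_DEG & tab$direction == "down"),
               stringsAsFactors = FALSE)
  }))
}

#' Top-variance feature selection
#'
#' @param x probes x samples numeric matrix (a `ContrastMatrix` works)
#' @param k number of probes to keep
#' @return character vector of `k` probe ids by descending variance, ties
#'   broken lexicographically by probe id
#' @export
top_variance_features <- function(x, k = 100) {
  m <- unclass(x)
  if (k > nrow(m)) stop_format("k = %d exceeds %d probes", k, nrow(m))
  v <- apply(m, 1, var)
  ids <- rownames(m)
  ord <- order(-v, ids, method = "radix")
  ids[ord][seq_len(k)]
}

#' Two-dimensional PCA of samples
#'
#' Centered (unscaled) PCA of the samples over the supplied probes, as used
#' for the study overview plots. Sign convention: within each component the
#' largest-magnitude probe loading is made positive, so coordinates are
#' reproducible across platforms.
#'
#' @param x probes x samples numeric matrix (typically restricted to
#'   [top_variance_features()] first)
#' @param features optional probe ids to restrict to
#' @return list with `coordinates` (data frame `sample`, `PC1`, `PC2`),
#'   `var_explained` (fractions of total variance for PC1 and PC2) and
#'   `loadings` (probes x 2)
#' @export
pca_2d <- function(x, features = NULL) {
  m <- unclass(x)
  if (!is.null(features)) m <- m[features, , drop = FALSE]
  if (ncol(m) < 3) stop_format("PCA needs at least 3 samples")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    imax <- which.max(abs(load[, j]))
    if (load[imax, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (k < 2) {
    scores <- cbind(scores, PC2 = 0)
    load <- cbind(load, PC2 = 0)
    frac <- c(frac, 0)
  }
  list(coordinates = data.frame(sample = colnames(m),
                                PC1 = scores[, 1], PC2 = scores[, 2],
                                stringsAsFactors = FALSE),
       var_explained = c(PC1 = frac[1], PC2 = frac[2]),
       loadings = load)
}
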