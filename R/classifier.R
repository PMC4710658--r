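# Blinded compound assignment. Training samples are control-subtracted
# replicate profiles; features are the top-k variance probes of the training
# set only. All C(n,2) class pairs get a linear SVM (cost chosen by a
# power-of-two grid with leave-one-replicate-out cross-validation, ties to
# the smallest cost), each calibrated with a Platt sigmoid fitted to the
# training decision values. Multiclass posteriors come from pairwise
# coupling: the quadratic program
#   min_p sum_i sum_{j != i} (r_ji p_i - r_ij p_j)^2  s.t. sum p = 1, p >= 0
# solved by the standard iterative scaling method.

#' Assemble control-subtracted training data per compound
#'
#' @param em an `ExpressionMatrix`
#' @param compounds compounds to include (default: all treated)
#' @param batch batch restriction, e.g. `"training"`
#' @return named list of `ContrastMatrix` objects
#' @export
contrast_set <- function(em, compounds = NULL, batch = NULL) {
  compounds <- compounds %||%
    setdiff(unique(em$sample_sheet$compound), "control")
  setNames(lapply(compounds, paired_contrasts, em = em, batch = batch),
           compounds)
}

bind_contrasts <- function(contrast_list) {
  x <- do.call(cbind, lapply(contrast_list, unclass))
  y <- rep(names(contrast_list), vapply(contrast_list, ncol, integer(1)))
  rep_idx <- unlist(lapply(contrast_list, function(m) seq_len(ncol(m))),
                    use.names = FALSE)
  list(x = x, y = y, rep_idx = rep_idx)
}

# Platt sigmoid fit: P(y = +1 | f) = 1 / (1 + exp(A f + B)), Newton descent
# with backtracking on the cross-entropy of smoothed targets
platt_fit <- function(f, y_pos) {
  prior1 <- sum(y_pos); prior0 <- length(y_pos) - prior1
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  tt <- ifelse(y_pos, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  obj <- function(A, B) {
    fab <- f * A + B
    sum(ifelse(fab >= 0, tt * fab + log1p(exp(-fab)),
               (tt - 1) * fab + log1p(exp(fab))))
  }
  fval <- obj(A, B)
  for (it in 1:100) {
    fab <- f * A + B
    p <- ifelse(fab >= 0, exp(-fab) / (1 + exp(-fab)), 1 / (1 + exp(fab)))
    d1 <- tt - p; d2 <- p * (1 - p)
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newf <- obj(A + step * dA, B + step * dB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- A + step * dA; B <- B + step * dB; fval <- newf
        break
      }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)
}

platt_prob <- function(f, A, B) {
  fab <- f * A + B
  ifelse(fab >= 0, exp(-fab) / (1 + exp(-fab)), 1 / (1 + exp(fab)))
}

# fit one linear pairwise SVM and its calibration; returns explicit weights
# so the model serializes to JSON and predicts without e1071 state
fit_pair <- function(X, y, ci, cj, cost) {
  sel <- y %in% c(ci, cj)
  Xs <- X[sel, , drop = FALSE]
  ys <- factor(y[sel], levels = c(ci, cj))
  fit <- e1071::svm(Xs, ys, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  f <- drop(Xs %*% w) + b            # decision value, positive => ci
  ab <- platt_fit(f, ys == ci)
  list(ci = ci, cj = cj, w = w, b = b, A = ab[["A"]], B = ab[["B"]])
}

pair_decision <- function(pair, X) drop(X %*% pair$w) + pair$b

# class posterior for each row of X under a list of calibrated pair models
coupled_posteriors <- function(pairs, classes, X) {
  k <- length(classes)
  out <- matrix(NA_real_, nrow(X), k, dimnames = list(rownames(X), classes))
  R <- matrix(0.5, k, k, dimnames = list(classes, classes))
  for (s in seq_len(nrow(X))) {
    for (pm in pairs) {
      r <- platt_prob(pair_decision(pm, X[s, , drop = FALSE]), pm$A, pm$B)
      r <- min(max(r, 1e-7), 1 - 1e-7)
      R[pm$ci, pm$cj] <- r
      R[pm$cj, pm$ci] <- 1 - r
    }
    out[s, ] <- couple_probabilities(R)
  }
  out
}

#' Couple pairwise class probabilities into a multiclass posterior
#'
#' Solves `min_p sum_i sum_{j != i} (r_ji p_i - r_ij p_j)^2` subject to
#' `sum(p) = 1, p >= 0` by the iterative scaling method used for
#' one-against-one SVM probability estimates.
#'
#' @param R square matrix of pairwise probabilities, `R[i, j]` the estimated
#'   probability of class i in the (i, j) subproblem; `R[j, i] = 1 - R[i, j]`
#'   and entries strictly inside (0, 1)
#' @param max_iter iteration cap
#' @param eps convergence tolerance on the KKT residual
#' @return posterior probability vector summing to 1
#' @export
couple_probabilities <- function(R, max_iter = 1000, eps = 1e-12) {
  k <- nrow(R)
  stopifnot(ncol(R) == k)
  off <- R[upper.tri(R) | lower.tri(R)]
  if (any(off <= 0) || any(off >= 1))
    stop_format("pairwise probabilities must lie strictly in (0, 1)")
  if (k == 2) {
    p <- c(R[1, 2], R[2, 1]) / (R[1, 2] + R[2, 1])
    return(setNames(p, rownames(R)))
  }
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(R[-t, t]^2)
    for (j in seq_len(k)) if (j != t) Q[t, j] <- -R[j, t] * R[t, j]
  }
  p <- rep(1 / k, k)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Qp <- drop(Q %*% p)
    pQp <- drop(crossprod(p, Qp))
    if (max(abs(Qp - pQp)) < eps) { converged <- TRUE; break }
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  if (!converged) {
    Qp <- drop(Q %*% p)
    pQp <- drop(crossprod(p, Qp))
    if (max(abs(Qp - pQp)) >= 1e-8)
      stop_format("pairwise coupling did not converge (residual %.3g)",
                  max(abs(Qp - pQp)))
  }
  setNames(p / sum(p), rownames(R))
}

#' Train the one-against-one compound classifier
#'
#' @param contrast_list named list of `ContrastMatrix` objects, one per
#'   compound (names are the class labels); every class needs >= 2 replicates
#' @param k number of top-variance probes to keep as features (default 100),
#'   computed on the training set only
#' @param cost_grid SVM cost grid (default powers of two, 2^-5..2^5); the
#'   cost is chosen by leave-one-replicate-out CV accuracy, ties resolved
#'   towards the smallest cost
#' @param seed integer; recorded in the model (training itself is
#'   deterministic)
#' @return object of class `ClassifierModel`: features, classes, chosen
#'   cost, per-pair weights and Platt coefficients, CV accuracy by cost
#' @export
train_classifier <- function(contrast_list, k = 100,
                             cost_grid = 2^(-5:5), seed = 1L) {
  if (is.null(names(contrast_list)) || anyDuplicated(names(contrast_list)))
    stop_format("contrast list must have unique class labels as names")
  if (length(contrast_list) < 2) stop_format("need >= 2 classes")
  nrep <- vapply(contrast_list, ncol, integer(1))
  if (any(nrep < 2))
    stop_format("class '%s' has fewer than 2 replicates",
                names(contrast_list)[which(nrep < 2)[1]])
  b <- bind_contrasts(contrast_list)
  features <- top_variance_features(b$x, k = min(k, nrow(b$x)))
  X <- t(b$x[features, , drop = FALSE])
  y <- b$y
  classes <- names(contrast_list)
  pairs_idx <- combn(classes, 2, simplify = FALSE)

  cv_acc <- vapply(cost_grid, function(cost) {
    correct <- 0L; total <- 0L
    for (r in unique(b$rep_idx)) {
      hold <- b$rep_idx == r
      if (all(hold) || !any(hold)) next
      pms <- lapply(pairs_idx, function(pr)
        fit_pair(X[!hold, , drop = FALSE], y[!hold], pr[1], pr[2], cost))
      post <- coupled_posteriors(pms, classes, X[hold, , drop = FALSE])
      pred <- classes[max.col(post, ties.method = "first")]
      correct <- correct + sum(pred == y[hold])
      total <- total + sum(hold)
    }
    correct / total
  }, numeric(1))
  cost <- cost_grid[which.max(cv_acc)]  # which.max takes the first (smallest)

  pairs <- lapply(pairs_idx, function(pr) fit_pair(X, y, pr[1], pr[2], cost))
  structure(list(features = features, classes = classes, cost = cost,
                 pairs = pairs,
                 cv_accuracy = setNames(cv_acc, as.character(cost_grid)),
                 n_replicates = nrep, seed = as.integer(seed)),
            class = "ClassifierModel")
}

#' @export
print.ClassifierModel <- function(x, ...) {
  cat(sprintf("ClassifierModel: %d classes, %d pairwise linear SVMs, %d features, cost %g\n",
              length(x$classes), length(x$pairs), length(x$features), x$cost))
  invisible(x)
}

#' Predict blinded samples
#'
#' @param model a `ClassifierModel`
#' @param contrasts control-subtracted testing data: a probes x samples
#'   matrix, or a named list of `ContrastMatrix` objects (names then provide
#'   the truth)
#' @param truth optional character vector of true compounds per sample
#' @param group_map optional named character vector mapping compounds to
#'   mechanism groups (e.g. both HDAC inhibitors to one group); grouped
#'   scoring counts a prediction as correct when truth and prediction share
#'   a group
#' @return a `PredictionReport` data frame (`sample`, `best`, `best_prob`,
#'   `second`, `second_prob`, and `truth`/`correct`/`correct_grouped` when
#'   truth is known), with the full posterior matrix in attribute
#'   `posteriors` and summary percentages in attributes `percent_correct`
#'   and `percent_correct_grouped`
#' @export
predict_blind <- function(model, contrasts, truth = NULL, group_map = NULL) {
  if (is.list(contrasts) && !is.matrix(contrasts)) {
    b <- bind_contrasts(contrasts)
    if (is.null(truth)) truth <- b$y
    m <- b$x
  } else m <- unclass(contrasts)
  missing <- setdiff(model$features, rownames(m))
  if (length(missing))
    stop_format("%d model feature probe(s) absent from testing data", length(missing))
  X <- t(m[model$features, , drop = FALSE])
  post <- coupled_posteriors(model$pairs, model$classes, X)
  ord <- t(apply(post, 1, order, decreasing = TRUE))
  best <- model$classes[ord[, 1]]
  second <- model$classes[ord[, 2]]
  rep_df <- data.frame(
    sample = colnames(m),
    best = best,
    best_prob = post[cbind(seq_len(nrow(post)), ord[, 1])],
    second = second,
    second_prob = post[cbind(seq_len(nrow(post)), ord[, 2])],
    stringsAsFactors = FALSE)
  if (!is.null(truth)) {
    rep_df$truth <- truth
    rep_df$correct <- rep_df$best == truth
    grp <- function(x) if (is.null(group_map)) x else
      ifelse(x %in% names(group_map), group_map[x], x)
    rep_df$correct_grouped <- grp(rep_df$best) == grp(rep_df$truth)
    attr(rep_df, "percent_correct") <- 100 * mean(rep_df$correct)
    attr(rep_df, "percent_correct_grouped") <- 100 * mean(rep_df$correct_grouped)
  }
  attr(rep_df, "posteriors") <- post
  class(rep_df) <- unique(c("PredictionReport", class(rep_df)))
  rep_df
}

#' Human-readable prediction report
#'
#' Probabilities rounded to whole percents, mirroring the tabular blind
#' report format; the machine columns keep full precision.
#'
#' @param x a `PredictionReport`
#' @param ... unused
#' @export
print.PredictionReport <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    line <- sprintf("%s: %s (%.0f %%), %s (%.0f %%)",
                    x$sample[i], x$best[i], 100 * x$best_prob[i],
                    x$second[i], 100 * x$second_prob[i])
    if (!is.null(x$truth)) line <- paste0(line, " | truth: ", x$truth[i])
    cat(line, "\n")
  }
  if (!is.null(attr(x, "percent_correct")))
    cat(sprintf("raw predictivity %.1f %%; grouped %.1f %%\n",
                attr(x, "percent_correct"),
                attr(x, "percent_correct_grouped")))
  invisible(x)
}

#' Random train/test split resampling of the classifier
#'
#' Repeatedly partitions the replicates of every compound into training and
#' testing subsets at random, retrains, and scores the held-out samples.
#'
#' @param contrast_list named list of `ContrastMatrix` objects holding all
#'   replicates per compound (e.g. 5 in the modelled design)
#' @param n_splits number of random partitions
#' @param n_train training replicates per compound per split
#' @param k,cost_grid passed to [train_classifier()]
#' @param group_map optional mechanism grouping for grouped scoring
#' @param seed RNG seed
#' @return list with `per_compound` (data frame of raw/grouped percent
#'   correct per compound), `confusion` (truth x prediction count matrix)
#'   and `n_splits`
#' @export
split_resampling <- function(contrast_list, n_splits = 1000, n_train = 3,
                             k = 100, cost_grid = 2^(-5:5),
                             group_map = NULL, seed = 1L) {
  classes <- names(contrast_list)
  nrep <- vapply(contrast_list, ncol, integer(1))
  stopifnot(all(nrep > n_train))
  set.seed(seed)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes, predicted = classes))
  correct <- setNames(numeric(length(classes)), classes)
  correct_grp <- setNames(numeric(length(classes)), classes)
  total <- setNames(numeric(length(classes)), classes)
  for (s in seq_len(n_splits)) {
    train <- list(); test <- list()
    for (cmp in classes) {
      idx <- sample(nrep[[cmp]], n_train)
      m <- contrast_list[[cmp]]
      train[[cmp]] <- m[, idx, drop = FALSE]
      test[[cmp]] <- m[, -idx, drop = FALSE]
    }
    model <- train_classifier(train, k = k, cost_grid = cost_grid, seed = seed)
    rep_df <- predict_blind(model, test, group_map = group_map)
    for (i in seq_len(nrow(rep_df))) {
      tr <- rep_df$truth[i]; pr <- rep_df$best[i]
      confusion[tr, pr] <- confusion[tr, pr] + 1L
      correct[tr] <- correct[tr] + (pr == tr)
      correct_grp[tr] <- correct_grp[tr] + rep_df$correct_grouped[i]
      total[tr] <- total[tr] + 1
    }
  }
  list(per_compound = data.frame(compound = classes,
                                 percent_correct = 100 * correct / total,
                                 percent_correct_grouped = 100 * correct_grp / total,
                                 stringsAsFactors = FALSE),
       confusion = confusion, n_splits = n_splits)
}
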