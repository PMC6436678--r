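# Cross-task analysis: Pearson correlation with significance masking,
# within-task PCA, and regularized canonical correlation analysis (CCA)
# for multi-view augmentation of an external dataset.

#' Cross-task correlations with significance masking
#'
#' Pearson correlation with a two-sided p-value for every metric pair,
#' over pairwise-complete subjects. Entries are flagged `masked` when the
#' two metrics belong to the same task or when `p > alpha`; no
#' multiple-testing correction is applied by default (an optional
#' Benjamini-Hochberg adjustment is available), mirroring the raw-alpha
#' display convention for cross-task correlation maps.
#'
#' @param metrics Numeric matrix or data frame, subjects x metrics
#'   (column names required).
#' @param metric_task Named character vector mapping metric name -> task
#'   (same-task masking); omit for no same-task masking.
#' @param alpha Significance level (default 0.05).
#' @param fdr Apply Benjamini-Hochberg adjustment before masking.
#' @return Data frame `metric1`, `metric2`, `rho`, `p`, `masked`.
#' @export
cross_task_correlations <- function(metrics, metric_task = NULL, alpha = 0.05,
                                    fdr = FALSE) {
  X <- as.matrix(metrics)
  stopifnot(!is.null(colnames(X)))
  nm <- colnames(X)
  pairs <- utils::combn(length(nm), 2L)
  res <- data.frame(metric1 = nm[pairs[1, ]], metric2 = nm[pairs[2, ]],
                    rho = NA_real_, p = NA_real_, masked = TRUE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    x <- X[, pairs[1, k]]; y <- X[, pairs[2, k]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    res$rho[k] <- unname(ct$estimate)
    res$p[k] <- ct$p.value
  }
  p_eff <- if (fdr) stats::p.adjust(res$p, "BH") else res$p
  same_task <- if (is.null(metric_task)) rep(FALSE, nrow(res)) else {
    metric_task[res$metric1] == metric_task[res$metric2]
  }
  res$masked <- is.na(res$rho) | same_task | p_eff > alpha
  res
}

#' PCA of within-task score metrics
#'
#' Standardized-variable principal components for combining the several
#' metrics of one task into interpretable components (biplot-style
#' loadings).
#'
#' @param metrics Numeric matrix/data frame, subjects x metrics; constant
#'   columns are dropped.
#' @param k Number of components (must not exceed the data rank).
#' @return List with `loadings` (metrics x k), `explained_variance`
#'   (length k, non-increasing), `explained_ratio`, and `scores`
#'   (subjects x k).
#' @export
pca_scores <- function(metrics, k = 2L) {
  X <- as.matrix(metrics)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  keep <- apply(X, 2L, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < k) stop("k exceeds the number of non-constant metrics")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > 1e-10)
  if (k > rank) stop("k exceeds the rank of the metric table")
  list(
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    explained_variance = pc$sdev[seq_len(k)]^2,
    explained_ratio = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2),
    scores = pc$x[, seq_len(k), drop = FALSE]
  )
}

#' Fit a canonical correlation model on two feature views
#'
#' Both views are standardized (per stored mean/sd; zero-variance columns
#' get sd 1 so projection never divides by zero) and the regularized
#' canonical correlation problem is solved by singular value
#' decomposition of the whitened cross-covariance
#' `(S11 + ridge I)^(-1/2) S12 (S22 + ridge I)^(-1/2)`. The returned
#' canonical correlations are non-increasing and clamped to \[0, 1\].
#'
#' @param view1,view2 Numeric matrices with the same row (sample) count.
#' @param k Number of canonical embeddings (default 20, capped at
#'   `min(d1, d2)`).
#' @param ridge Regularization added to each view's covariance (default
#'   1e-3). With `ridge = 0` a rank-deficient view is rejected with
#'   guidance to set `ridge > 0`.
#' @return Object of class `cca_model`: projection matrices `W1`
#'   (d1 x k), `W2` (d2 x k), `correlations`, `k`, and the per-view
#'   standardization parameters.
#' @export
cca_fit <- function(view1, view2, k = 20L, ridge = 1e-3) {
  X <- as.matrix(view1); Y <- as.matrix(view2)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3L, ridge >= 0)
  k <- min(as.integer(k), ncol(X), ncol(Y))
  std <- function(M) {
    mu <- colMeans(M)
    sd <- apply(M, 2L, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    list(mu = mu, sd = sd, Z = sweep(sweep(M, 2L, mu), 2L, sd, "/"))
  }
  s1 <- std(X); s2 <- std(Y)
  n <- nrow(X)
  S11 <- crossprod(s1$Z) / (n - 1) + diag(ridge, ncol(X))
  S22 <- crossprod(s2$Z) / (n - 1) + diag(ridge, ncol(Y))
  S12 <- crossprod(s1$Z, s2$Z) / (n - 1)
  inv_sqrt <- function(S, label) {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < 1e-10)
      stop(label, " is rank-deficient; set ridge > 0 to regularize")
    e$vectors %*% diag(1 / sqrt(e$values), nrow(S)) %*% t(e$vectors)
  }
  K1 <- inv_sqrt(S11, "view1 covariance")
  K2 <- inv_sqrt(S22, "view2 covariance")
  sv <- svd(K1 %*% S12 %*% K2)
  structure(
    list(
      W1 = K1 %*% sv$u[, seq_len(k), drop = FALSE],
      W2 = K2 %*% sv$v[, seq_len(k), drop = FALSE],
      correlations = pmin(pmax(sv$d[seq_len(k)], 0), 1),
      k = k,
      std1 = s1[c("mu", "sd")], std2 = s2[c("mu", "sd")]
    ),
    class = "cca_model"
  )
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model> k = %d embeddings (%d x %d / %d x %d views)\n",
              x$k, nrow(x$W1), x$k, nrow(x$W2), x$k))
  cat("canonical correlations:",
      paste(sprintf("%.3f", utils::head(x$correlations, 5L)), collapse = ", "),
      if (x$k > 5L) "..." else "", "\n")
  invisible(x)
}

#' Project new samples into the shared canonical space
#'
#' @param object A [cca_fit()] model.
#' @param newdata Samples x features matrix in the chosen view's feature
#'   space.
#' @param view Which view's projection to apply (1 or 2).
#' @param ... Unused.
#' @return Samples x k matrix of canonical embeddings.
#' @export
predict.cca_model <- function(object, newdata, view = 1L, ...) {
  W <- if (view == 1L) object$W1 else object$W2
  std <- if (view == 1L) object$std1 else object$std2
  M <- as.matrix(newdata)
  if (ncol(M) != nrow(W))
    stop("newdata has ", ncol(M), " features; view ", view, " expects ", nrow(W))
  Z <- sweep(sweep(M, 2L, std$mu), 2L, std$sd, "/")
  Z %*% W
}

#' Augment an external dataset with canonical embeddings
#'
#' External samples sharing view 1's feature space are projected into the
#' shared canonical space (using the model's stored standardization) and
#' the embeddings are concatenated column-wise with caller-selected
#' original features, yielding a samples x (k + m) design matrix.
#'
#' @param model A [cca_fit()] model.
#' @param external_view1 External samples x d1 matrix (view 1 feature
#'   space).
#' @param selected_features External samples x m matrix of retained
#'   original features.
#' @return Samples x (k + m) numeric matrix.
#' @export
cca_augment <- function(model, external_view1, selected_features) {
  stopifnot(inherits(model, "cca_model"))
  emb <- predict(model, external_view1, view = 1L)
  sel <- as.matrix(selected_features)
  stopifnot(nrow(sel) == nrow(emb))
  out <- cbind(emb, sel)
  colnames(out) <- c(paste0("cca_", seq_len(ncol(emb))),
                     colnames(sel) %||% paste0("feat_", seq_len(ncol(sel))))
  out
}
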