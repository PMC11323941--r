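#' Partial least squares discriminant analysis with cross-validated Q2
#'
#' Two-component NIPALS PLS2 fit of the samples on a one-hot class matrix,
#' with Q2 = 1 - PRESS/TSS under stratified cross-validation. Axes are
#' oriented so tail samples score negative on LV1 and duct samples positive
#' on LV2 (when those classes are present); per-gene part labels follow the
#' loading-quadrant rule tail (LV1 < 0), sac (LV1 >= 0, LV2 <= 0), duct
#' (LV1 >= 0, LV2 > 0).
#'
#' @param x VST `expr_matrix` (genes x samples) or a plain matrix with
#'   samples in columns.
#' @param labels factor/character of class labels per sample; defaults to
#'   the `tissue` metadata column.
#' @param n_components number of latent variables (default 2).
#' @param cv_folds requested folds for Q2 (default 7); reduced with a
#'   warning when the smallest class has fewer members.
#' @param seed seed for the fold shuffle (default 1).
#' @return An object of class `plsda_model` with elements `scores`,
#'   `x_loadings`, `weights`, `Q2`, `classes`, `cv_folds`, and
#'   `gene_parts` (data.frame gene/lv1/lv2/part).
#' @export
plsda <- function(x, labels = NULL, n_components = 2, cv_folds = 7, seed = 1) {
  if (inherits(x, "expr_matrix")) {
    if (is.null(labels)) labels <- x$meta$tissue
    x <- as.matrix(x$values)
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) .stopf("PLS-DA requires at least two classes")
  if (min(table(labels)) < 3)
    .stopf("at least 3 samples per class are required")
  X <- t(x)                                  # samples x genes
  Y <- stats::model.matrix(~ 0 + factor(labels, levels = classes))
  colnames(Y) <- classes

  fit <- .pls_nipals(X, Y, n_components)

  # orientation anchors
  flip <- c(FALSE, FALSE)
  if ("tail" %in% labels && n_components >= 1)
    flip[1] <- mean(fit$scores[labels == "tail", 1]) > 0
  if ("duct" %in% labels && n_components >= 2)
    flip[2] <- mean(fit$scores[labels == "duct", 2]) < 0
  for (a in which(flip)) {
    fit$scores[, a] <- -fit$scores[, a]
    fit$x_loadings[, a] <- -fit$x_loadings[, a]
    fit$weights[, a] <- -fit$weights[, a]
    fit$y_loadings[, a] <- -fit$y_loadings[, a]
  }

  q2 <- .pls_q2(X, Y, labels, n_components, cv_folds, seed)

  l <- sweep(fit$x_loadings, 2, apply(fit$scores, 2, stats::sd), "*")
  part <- if (n_components >= 2)
    ifelse(l[, 1] < 0, "tail", ifelse(l[, 2] <= 0, "sac", "duct"))
  else rep(NA_character_, nrow(l))
  gene_parts <- data.frame(gene = colnames(X), lv1 = l[, 1],
                           lv2 = if (n_components >= 2) l[, 2] else NA_real_,
                           part = part, row.names = NULL)
  structure(list(scores = fit$scores, x_loadings = fit$x_loadings,
                 weights = fit$weights, y_loadings = fit$y_loadings,
                 Q2 = q2$Q2, cv_folds = q2$folds, classes = classes,
                 labels = labels, gene_parts = gene_parts),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d components, classes: %s, Q2 = %.3f (%d-fold CV)\n",
              ncol(x$scores), paste(x$classes, collapse = "/"), x$Q2,
              x$cv_folds))
  invisible(x)
}

# NIPALS PLS2 on centered X (samples x vars) and centered one-hot Y.
.pls_nipals <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(Yc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); TT <- matrix(0, n, ncomp)
  E <- Xc; F <- Yc
  for (a in seq_len(ncomp)) {
    u <- F[, which.max(apply(F, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u)); w <- w / sqrt(sum(w^2))
      tt <- drop(E %*% w)
      qv <- drop(crossprod(F, tt)) / sum(tt^2)
      u <- drop(F %*% qv) / sum(qv^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    pv <- drop(crossprod(E, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, pv)
    F <- F - tcrossprod(tt, qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; TT[, a] <- tt
  }
  dimnames(W) <- dimnames(P) <- list(colnames(X), paste0("LV", seq_len(ncomp)))
  dimnames(TT) <- list(rownames(X), paste0("LV", seq_len(ncomp)))
  dimnames(Q) <- list(colnames(Y), paste0("LV", seq_len(ncomp)))
  list(scores = TT, x_loadings = P, weights = W, y_loadings = Q,
       x_center = attr(Xc, "scaled:center"), y_center = attr(Yc, "scaled:center"))
}

# Predict Y for new X rows from a NIPALS fit: B = W (P'W)^-1 Q'.
.pls_predict <- function(fit, Xnew) {
  B <- fit$weights %*% solve(crossprod(fit$x_loadings, fit$weights),
                             t(fit$y_loadings))
  sweep(scale(Xnew, center = fit$x_center, scale = FALSE) %*% B, 2,
        -fit$y_center)
}

# Stratified cross-validated Q2 = 1 - PRESS/TSS.
.pls_q2 <- function(X, Y, labels, ncomp, cv_folds, seed) {
  n <- nrow(X)
  min_class <- min(table(labels))
  folds <- min(cv_folds, min_class)
  if (folds < cv_folds)
    .warnf("cv folds reduced from %d to %d (smallest class has %d samples)",
           cv_folds, folds, min_class)
  if (folds < 2) .stopf("cross-validation requires at least 2 usable folds")
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(labels)) {
    i <- sample(which(labels == cl))
    fold[i] <- rep_len(seq_len(folds), length(i))
  }
  pred <- matrix(NA_real_, n, ncol(Y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    f <- .pls_nipals(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], ncomp)
    pred[!tr, ] <- .pls_predict(f, X[!tr, , drop = FALSE])
  }
  press <- sum((Y - pred)^2)
  tss <- sum(scale(Y, center = TRUE, scale = FALSE)^2)
  list(Q2 = 1 - press / tss, folds = folds)
}
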