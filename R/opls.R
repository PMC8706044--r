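#' Scale an intensity matrix for multivariate modelling
#'
#' Optional `log10(1 + x)` transform followed by mean-centering and, under
#' `"uv"` (unit variance, the default) or `"pareto"`, column scaling.
#' Columns with zero variance cannot be variance-scaled and are dropped
#' with a warning (kept under plain centering).
#'
#' @param X numeric matrix, samples in rows.
#' @param scaling `"uv"`, `"pareto"` or `"center"`.
#' @param log_transform apply `log10(1 + x)` first.
#' @return list: `X` (scaled), `center`, `scale`, `kept` (column indices
#'   retained), `scaling`, `log_transform`.
#' @export
scale_matrix <- function(X, scaling = c("uv", "pareto", "center"),
                         log_transform = FALSE) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (log_transform) X <- log10(1 + X)
  sds <- apply(X, 2, stats::sd)
  kept <- seq_len(ncol(X))
  if (scaling %in% c("uv", "pareto") && any(sds == 0)) {
    warning(sprintf("dropping %d constant column(s) under %s scaling",
                    sum(sds == 0), scaling))
    kept <- which(sds > 0)
    X <- X[, kept, drop = FALSE]
    sds <- sds[kept]
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- switch(scaling, uv = sds, pareto = sqrt(sds),
                center = rep(1, ncol(X)))
  if (scaling != "center") Xc <- sweep(Xc, 2, scl, "/")
  list(X = Xc, center = ctr, scale = scl, kept = kept,
       scaling = scaling, log_transform = log_transform)
}

## internal: one NIPALS PLS2 component on (X, Y), both centered.
## Returns unit-norm weight w, score t, X-loading p, Y-loading q.
nipals_component <- function(X, Y, max_iter = 500, tol = 1e-12) {
  u <- Y[, which.max(apply(Y, 2, stats::var)), drop = TRUE]
  t_old <- rep(0, nrow(X))
  for (it in seq_len(max_iter)) {
    w <- crossprod(X, u) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    tt <- as.numeric(X %*% w)
    q <- crossprod(Y, tt) / sum(tt^2)
    u <- as.numeric(Y %*% q) / sum(q^2)
    if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
    t_old <- tt
  }
  p <- crossprod(X, tt) / sum(tt^2)
  list(w = as.numeric(w), t = tt, p = as.numeric(p), q = as.numeric(q))
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis,
#' implemented as NIPALS PLS2 on a class-indicator dummy matrix with
#' orthogonal-component filtering: before the predictive components are
#' extracted, `n_orthogonal` components of Y-orthogonal X-variation are
#' removed (orthogonal weight = X-loading minus its projection on the
#' Y-predictive weight). With `n_orthogonal = 0` the model reduces exactly
#' to standard PLS2 on the scaled data.
#'
#' @param X samples x features intensity matrix (data.frame or matrix).
#' @param classes factor (or coercible) of sample classes, >= 2 levels.
#' @param n_predictive number of predictive components (>= 1).
#' @param n_orthogonal number of orthogonal components (>= 0).
#' @param scaling `"uv"`, `"pareto"` or `"center"`.
#' @param log_transform apply `log10(1 + x)` before scaling.
#' @return list of class `opls_model`: predictive `scores`, `weights`,
#'   `loadings`, `y_loadings`; orthogonal `scores_ortho`, `weights_ortho`,
#'   `loadings_ortho`; `r2x_cum`, `r2y_cum` (and per-component `r2x`),
#'   scaled matrix `X_scaled`, dummy `Y`, class levels, scaling parameters.
#' @export
fit_opls_da <- function(X, classes, n_predictive = 1, n_orthogonal = 1,
                        scaling = "uv", log_transform = FALSE) {
  classes <- factor(classes)
  check(nlevels(classes) >= 2, "need >= 2 classes")
  X <- as.matrix(X)
  check(nrow(X) == length(classes), "one class label per sample required")
  check(nrow(X) >= nlevels(classes), "need at least one sample per class")
  check(n_predictive >= 1, "n_predictive must be >= 1")

  sc <- scale_matrix(X, scaling, log_transform)
  Xs <- sc$X
  Y <- stats::model.matrix(~ 0 + classes)
  colnames(Y) <- levels(classes)
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2, y_center)

  ss_x <- sum(Xs^2)
  ss_y <- sum(Yc^2)
  Xc <- Xs

  Wo <- To <- Po <- NULL
  k_ortho <- 0L
  for (k in seq_len(n_orthogonal)) {
    comp <- nipals_component(Xc, Yc)
    w_o <- comp$p - as.numeric(crossprod(comp$w, comp$p)) * comp$w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break          # no Y-orthogonal variation left
    w_o <- w_o / nrm
    t_o <- as.numeric(Xc %*% w_o)
    p_o <- as.numeric(crossprod(Xc, t_o) / sum(t_o^2))
    Xc <- Xc - tcrossprod(t_o, p_o)
    Wo <- cbind(Wo, w_o); To <- cbind(To, t_o); Po <- cbind(Po, p_o)
    k_ortho <- k_ortho + 1L
  }

  W <- Tm <- P <- Q <- NULL
  Yd <- Yc
  r2x_comp <- numeric(0)
  for (a in seq_len(n_predictive)) {
    comp <- nipals_component(Xc, Yd)
    W <- cbind(W, comp$w); Tm <- cbind(Tm, comp$t)
    P <- cbind(P, comp$p); Q <- cbind(Q, comp$q)
    r2x_comp <- c(r2x_comp, sum(tcrossprod(comp$t, comp$p)^2) / ss_x)
    Xc <- Xc - tcrossprod(comp$t, comp$p)
    Yd <- Yd - tcrossprod(comp$t, comp$q)
  }

  structure(list(
    scores = Tm, weights = W, loadings = P, y_loadings = Q,
    scores_ortho = To, weights_ortho = Wo, loadings_ortho = Po,
    n_predictive = n_predictive, n_orthogonal = k_ortho,
    r2x_cum = 1 - sum(Xc^2) / ss_x,
    r2y_cum = 1 - sum(Yd^2) / ss_y,
    r2x_comp = r2x_comp,
    X_scaled = Xs, Y = Y, y_center = y_center,
    classes = classes, levels = levels(classes),
    center = sc$center, scale = sc$scale, kept = sc$kept,
    scaling = sc$scaling, log_transform = sc$log_transform
  ), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA: %d predictive + %d orthogonal component(s), %d samples x %d features\n",
    x$n_predictive, x$n_orthogonal, nrow(x$X_scaled), ncol(x$X_scaled)))
  cat(sprintf("  R2X(cum) = %.4f  R2Y(cum) = %.4f\n", x$r2x_cum, x$r2y_cum))
  invisible(x)
}

#' Predict class responses for new samples
#'
#' Applies the stored transform/scaling, strips the orthogonal variation,
#' projects onto the predictive components and reconstructs the dummy-Y
#' response; the predicted class is the column with the largest response.
#'
#' @param object an `opls_model`.
#' @param newdata samples x features matrix on the raw intensity scale,
#'   with the same feature columns as the training matrix.
#' @param ... unused.
#' @return list: `y_pred` (dummy scale), `class` (factor), `scores`.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)[, object$kept, drop = FALSE]
  if (object$log_transform) Xn <- log10(1 + Xn)
  Xn <- sweep(Xn, 2, object$center)
  if (object$scaling != "center") Xn <- sweep(Xn, 2, object$scale, "/")
  if (object$n_orthogonal > 0) {
    for (k in seq_len(object$n_orthogonal)) {
      t_o <- as.numeric(Xn %*% object$weights_ortho[, k])
      Xn <- Xn - tcrossprod(t_o, object$loadings_ortho[, k])
    }
  }
  Tn <- NULL
  Yhat <- matrix(0, nrow(Xn), length(object$y_center))
  for (a in seq_len(object$n_predictive)) {
    t_a <- as.numeric(Xn %*% object$weights[, a])
    Tn <- cbind(Tn, t_a)
    Yhat <- Yhat + tcrossprod(t_a, object$y_loadings[, a])
    Xn <- Xn - tcrossprod(t_a, object$loadings[, a])
  }
  Yhat <- sweep(Yhat, 2, object$y_center, "+")
  colnames(Yhat) <- object$levels
  cls <- factor(object$levels[max.col(Yhat, ties.method = "first")],
                levels = object$levels)
  list(y_pred = Yhat, class = cls, scores = Tn)
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Class-stratified k-fold cross-validation (default 7 folds): each
#' held-out sample's dummy response is predicted from a model fitted on the
#' remaining samples (scaling parameters re-estimated on the training fold
#' only), and `Q2 = 1 - PRESS / SS` where SS is taken around the training
#' class-mean response. If the smallest class has fewer samples than
#' `folds`, the fold count is reduced with a warning so every fold retains
#' all classes.
#'
#' @param X samples x features matrix.
#' @param classes sample classes.
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the stratified fold assignment.
#' @param n_predictive,n_orthogonal,scaling,log_transform model settings,
#'   as in [fit_opls_da()].
#' @return Q2 (scalar) with attribute `folds_used`.
#' @export
cross_validated_q2 <- function(X, classes, folds = 7, seed = 1,
                               n_predictive = 1, n_orthogonal = 1,
                               scaling = "uv", log_transform = FALSE) {
  check(folds >= 2, "folds must be >= 2")
  classes <- factor(classes)
  X <- as.matrix(X)
  min_class <- min(table(classes))
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    warning(sprintf("smallest class has %d samples; reducing to %d folds",
                    min_class, folds))
  }
  fold_id <- integer(length(classes))
  withr::with_seed(as.integer(seed), {
    for (lv in levels(classes)) {
      idx <- sample(which(classes == lv))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  Y <- stats::model.matrix(~ 0 + classes)
  press <- ss <- 0
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- suppressWarnings(
      fit_opls_da(X[!test, , drop = FALSE], classes[!test],
                  n_predictive = n_predictive, n_orthogonal = n_orthogonal,
                  scaling = scaling, log_transform = log_transform))
    ## training model may keep a different column subset; predict handles it
    pr <- predict(fit, X[test, , drop = FALSE])
    press <- press + sum((Y[test, , drop = FALSE] - pr$y_pred)^2)
    ybar <- colMeans(Y[!test, , drop = FALSE])
    ss <- ss + sum(sweep(Y[test, , drop = FALSE], 2, ybar)^2)
  }
  structure(1 - press / ss, folds_used = folds)
}

#' S-plot coordinates of the first predictive component
#'
#' For every (scaled) feature column x_j: the covariance-scaled loading
#' `p1 = cov(t1, x_j) / sd(t1)` against the correlation loading
#' `pcorr1 = cor(t1, x_j)`. Features with zero variance in the scaled
#' matrix get `pcorr1 = 0` and are flagged.
#'
#' @param model a fitted `opls_model`.
#' @return data.frame: `feature` (column name or index), `p1`, `pcorr1`,
#'   `zero_variance`.
#' @export
s_plot <- function(model) {
  check(inherits(model, "opls_model"), "model must be an opls_model")
  t1 <- model$scores[, 1]
  Xs <- model$X_scaled
  n <- nrow(Xs)
  t1c <- t1 - mean(t1)
  covs <- as.numeric(crossprod(Xs, t1c)) / (n - 1)  # Xs is column-centered
  sd_t <- stats::sd(t1)
  sd_x <- apply(Xs, 2, stats::sd)
  zero_var <- sd_x == 0
  pcorr <- ifelse(zero_var, 0, covs / (sd_t * ifelse(zero_var, 1, sd_x)))
  data.frame(
    feature = if (!is.null(colnames(Xs))) colnames(Xs)
              else as.character(seq_len(ncol(Xs))),
    p1 = covs / sd_t,
    pcorr1 = pcorr,
    zero_variance = zero_var,
    stringsAsFactors = FALSE
  )
}

#' Select features common to both classes from an S-plot
#'
#' On an instrument-contrast model, features whose intensities do not
#' discriminate the classes sit near the centre of the S-plot: they are
#' selected when `|pcorr1| <= pcorr_max`. When per-class S-plots are also
#' supplied, the feature's correlation loadings in the two classes must in
#' addition be approximately equal (`|pcorr_A - pcorr_B| <= balance_tol`).
#' Output is sorted by ascending `|pcorr1|`.
#'
#' @param splot an [s_plot()] result.
#' @param pcorr_max maximum |pcorr1| for a "common" feature.
#' @param balance_tol maximum per-class pcorr difference.
#' @param splot_a,splot_b optional per-class S-plots (matched by
#'   `feature`).
#' @return the selected rows of `splot`, sorted by `|pcorr1|`.
#' @export
select_common_features <- function(splot, pcorr_max = 0.1,
                                   balance_tol = 0.05,
                                   splot_a = NULL, splot_b = NULL) {
  sel <- abs(splot$pcorr1) <= pcorr_max
  if (!is.null(splot_a) && !is.null(splot_b)) {
    pa <- splot_a$pcorr1[match(splot$feature, splot_a$feature)]
    pb <- splot_b$pcorr1[match(splot$feature, splot_b$feature)]
    sel <- sel & !is.na(pa) & !is.na(pb) & abs(pa - pb) <= balance_tol
  }
  out <- splot[sel, , drop = FALSE]
  out[order(abs(out$pcorr1)), , drop = FALSE]
}

#' Serialize an OPLS-DA model summary to JSON
#'
#' @param model a fitted `opls_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_opls_summary <- function(model, path) {
  jsonlite::write_json(list(
    n_predictive = model$n_predictive,
    n_orthogonal = model$n_orthogonal,
    r2x_cum = model$r2x_cum,
    r2y_cum = model$r2y_cum,
    r2x_per_component = model$r2x_comp,
    scaling = model$scaling,
    classes = model$levels
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
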