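#' Orthogonal partial least squares discriminant analysis (O-PLS-DA)
#'
#' Single-response O-PLS by the NIPALS-style deflation of Trygg and Wold:
#' variation in X orthogonal to the class vector is peeled off into
#' `n_orthogonal` components, then one predictive PLS component is fitted on
#' the deflated matrix. With `n_orthogonal = 0` the predictive component
#' equals the one-component PLS solution. Classification assigns samples to
#' the nearest class mean on the predictive score.
#'
#' @param X numeric matrix, samples x features (feature names kept on the
#'   loadings). Centered internally; set `scale = TRUE` for unit-variance
#'   scaling.
#' @param y two-level factor/character/logical class vector, each class with
#'   >= 3 samples.
#' @param n_orthogonal number of orthogonal components (must be < rank of the
#'   centered X).
#' @param scale unit-variance scale the columns.
#' @return an `opls_model`: predictive scores `t_pred`, loadings `p_pred`,
#'   weights `w_pred`; orthogonal `T_orth`, `P_orth`, `W_orth`; `class_means`
#'   on the predictive score; `var_explained` per component; 95\% confidence
#'   `ellipses` per class in (predictive, first orthogonal) score space.
#' @export
fit_opls_da <- function(X, y, n_orthogonal = 1, scale = FALSE) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  if (any(table(y) < 3)) stop("each class needs at least 3 samples")
  if (nrow(X) != length(y)) stop("X rows must match y")
  mu <- colMeans(X)
  sdv <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  sdv[sdv == 0] <- 1
  Xc <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  rk <- qr(Xc)$rank
  if (n_orthogonal >= rk) {
    stop("n_orthogonal must be smaller than rank(X) = ", rk)
  }
  yn <- as.numeric(y == levels(y)[2])
  yn <- yn - mean(yn)
  ssx <- sum(Xc^2)

  w <- drop(crossprod(Xc, yn))
  w <- w / sqrt(sum(w^2))
  T_orth <- matrix(0, nrow(X), 0)
  P_orth <- W_orth <- matrix(0, ncol(X), 0)
  var_orth <- numeric(0)
  Xd <- Xc
  k <- 0
  while (k < n_orthogonal) {
    t_ <- drop(Xd %*% w)
    p_ <- drop(crossprod(Xd, t_)) / sum(t_^2)
    w_o <- p_ - drop(crossprod(w, p_)) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break  # no orthogonal variation left
    w_o <- w_o / nw
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    T_orth <- cbind(T_orth, t_o)
    P_orth <- cbind(P_orth, p_o)
    W_orth <- cbind(W_orth, w_o)
    var_orth <- c(var_orth,
                  stats::setNames(sum(tcrossprod(t_o, p_o)^2) / ssx,
                                  paste0("orthogonal", k + 1)))
    k <- k + 1
  }
  t_pred <- drop(Xd %*% w)
  p_pred <- drop(crossprod(Xd, t_pred)) / sum(t_pred^2)
  names(p_pred) <- colnames(X)
  var_pred <- sum(tcrossprod(t_pred, p_pred)^2) / ssx
  class_means <- tapply(t_pred, y, mean)

  ell <- lapply(levels(y), function(cl) {
    sc <- cbind(pred = t_pred[y == cl],
                orth = if (ncol(T_orth)) T_orth[y == cl, 1] else rep(0, sum(y == cl)))
    list(center = colMeans(sc), cov = stats::cov(sc),
         radius2 = stats::qchisq(0.95, df = 2))
  })
  names(ell) <- levels(y)

  structure(list(t_pred = t_pred, p_pred = p_pred, w_pred = w,
                 T_orth = T_orth, P_orth = P_orth, W_orth = W_orth,
                 class_means = class_means, classes = levels(y), y = y,
                 center = mu, scale = sdv,
                 var_explained = c(predictive = var_pred, var_orth),
                 ellipses = ell),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("opls_model: 1 predictive + %d orthogonal component(s)\n",
              ncol(x$T_orth)))
  cat("variance explained:",
      paste(sprintf("%s %.1f%%", names(x$var_explained),
                    100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Classify samples with a fitted O-PLS-DA model
#'
#' Projects samples through the orthogonal filter, computes the predictive
#' score, and assigns the nearest class mean.
#'
#' @param model an `opls_model`.
#' @param X new samples x features matrix; `NULL` classifies the training
#'   samples.
#' @return character vector of predicted class labels.
#' @export
opls_classify <- function(model, X = NULL) {
  t_pred <- if (is.null(X)) {
    model$t_pred
  } else {
    Xc <- sweep(sweep(as.matrix(X), 2, model$center), 2, model$scale, "/")
    if (ncol(model$W_orth)) {
      for (k in seq_len(ncol(model$W_orth))) {
        t_o <- drop(Xc %*% model$W_orth[, k])
        Xc <- Xc - tcrossprod(t_o, model$P_orth[, k])
      }
    }
    drop(Xc %*% model$w_pred)
  }
  d <- outer(t_pred, model$class_means, function(a, b) abs(a - b))
  model$classes[apply(d, 1, which.min)]
}
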