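#' @title Pareto scaling, NIPALS PCA, OPLS-DA and S-plot statistics
#' @name chemometrics
#' @description
#' From-scratch multivariate analysis for feature matrices (samples x
#' variables): Pareto scaling, sequential NIPALS principal components with
#' R2X and cross-validated Q2, Hotelling T-squared outlier limits, OPLS-DA
#' with one predictive and `n_ortho` orthogonal components, and the S-plot
#' covariance/correlation statistics used to select discriminant features.
#' Cross-validation uses 7 contiguous sample blocks in fixed order so every
#' result is deterministic.
NULL

.as_X <- function(x) {
  if (inherits(x, "scaled_matrix")) x$X else as.matrix(x)
}

#' Pareto-scale a samples-by-variables matrix
#'
#' Columns are mean-centered and divided by the square root of their sample
#' standard deviation, an intermediate between no scaling and unit-variance
#' scaling that damps intense features without amplifying noise floor
#' variables. Zero-variance columns are dropped with a warning.
#'
#' @param raw numeric matrix, samples in rows.
#' @param scaling `"pareto"` (default), `"unit_variance"` or `"none"`
#'   (centering only).
#' @return list of class `scaled_matrix`: `X`, `column_means`,
#'   `column_sds`, `scaling`, `dropped`.
#' @export
pareto_scale <- function(raw, scaling = c("pareto", "unit_variance",
                                          "none")) {
  scaling <- match.arg(scaling)
  raw <- as.matrix(raw)
  if (nrow(raw) < 2) stop("need at least 2 samples to scale")
  mu <- colMeans(raw)
  sds <- apply(raw, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (all(zero)) stop("all columns are constant; nothing to scale")
  if (any(zero)) {
    warning(sum(zero), " constant column(s) dropped before scaling")
  }
  keep <- which(!zero)
  div <- switch(scaling,
                pareto = sqrt(sds[keep]),
                unit_variance = sds[keep],
                none = rep(1, length(keep)))
  X <- sweep(raw[, keep, drop = FALSE], 2, mu[keep], "-")
  X <- sweep(X, 2, div, "/")
  structure(list(X = X, column_means = mu[keep], column_sds = sds[keep],
                 scaling = scaling,
                 dropped = colnames(raw)[zero]),
            class = "scaled_matrix")
}

.nipals_component <- function(E, tol = 1e-10, max_iter = 500L,
                              label = "component", strict = TRUE) {
  v <- apply(E, 2, stats::var)
  t <- E[, which.max(v)]
  if (sum(t^2) == 0) t <- E[, 1] + 1e-12
  p <- NULL
  for (it in seq_len(max_iter)) {
    p <- drop(crossprod(E, t)) / sum(t^2)
    p <- p / sqrt(sum(p^2))
    t_new <- drop(E %*% p)
    delta <- sum((t_new - t)^2) / max(sum(t_new^2), .Machine$double.eps)
    t <- t_new
    if (delta < tol) break
    if (it == max_iter && strict) {
      stop("NIPALS failed to converge for ", label, " after ", max_iter,
           " iterations")
    }
    # non-strict callers (cross-validation folds) accept the estimate at
    # the iteration cap: only the projection subspace enters PRESS, and a
    # near-degenerate component pair spans it just as well
  }
  s <- sign(p[which.max(abs(p))])
  list(t = t * s, p = p * s, iterations = it)
}

.cv_blocks <- function(n, k = 7L) {
  k <- min(k, n)
  split(seq_len(n), cut(seq_len(n), k, labels = FALSE))
}

#' Fit a PCA model by NIPALS
#'
#' Components are extracted sequentially with deflation; each converges to
#' a relative score change below `tol` (default 1e-10) within `max_iter`
#' iterations or the fit aborts naming the component. R2X per component is
#' `SS(t p') / SS(X)`; the cumulative Q2 comes from 7-fold
#' contiguous-block cross-validation (`Q2 = 1 - PRESS / SS`).
#'
#' @param X a `scaled_matrix` or a pre-scaled numeric matrix.
#' @param A number of components, at most `min(n - 1, n_variables)`.
#' @param tol,max_iter NIPALS convergence controls.
#' @param compute_q2 set `FALSE` to skip cross-validation.
#' @param cv_folds number of contiguous CV blocks (default 7).
#' @param strict error when a component has not converged at `max_iter`
#'   (the default). `strict = FALSE` accepts the estimate at the
#'   iteration cap, which is appropriate when only the dominant subspace
#'   matters (e.g. Hotelling outlier scans): a near-degenerate eigenvalue
#'   pair rotates freely within its plane without affecting T-squared.
#' @return list of class `pca_model` with `scores`, `loadings`,
#'   `r2x_per_component`, `r2x_cum`, `q2_cum`, `hotelling_t2`,
#'   `t2_limit_95`, `n`, `A`.
#' @export
pca_nipals <- function(X, A, tol = 1e-10, max_iter = 500L,
                       compute_q2 = TRUE, cv_folds = 7L, strict = TRUE) {
  Xm <- .as_X(X)
  n <- nrow(Xm); v <- ncol(Xm)
  if (A > min(n - 1, v)) {
    stop("A must be <= min(n - 1, n_variables) = ", min(n - 1, v))
  }
  ssx <- sum(Xm^2)
  E <- Xm
  T <- matrix(0, n, A); P <- matrix(0, v, A)
  for (a in seq_len(A)) {
    comp <- .nipals_component(E, tol, max_iter, paste("component", a),
                              strict = strict)
    T[, a] <- comp$t; P[, a] <- comp$p
    E <- E - tcrossprod(comp$t, comp$p)
  }
  rownames(T) <- rownames(Xm); rownames(P) <- colnames(Xm)
  r2x <- colSums(T^2) / ssx
  t2 <- rowSums(sweep(T^2, 2, apply(T, 2, stats::var), "/"))
  q2 <- rep(NA_real_, A)
  if (compute_q2) {
    blocks <- .cv_blocks(n, cv_folds)
    press <- numeric(A)
    for (bl in blocks) {
      tr <- Xm[-bl, , drop = FALSE]
      mu <- colMeans(tr)
      tr <- sweep(tr, 2, mu, "-")
      te <- sweep(Xm[bl, , drop = FALSE], 2, mu, "-")
      Af <- min(A, nrow(tr) - 1, v)
      Ef <- tr
      Pf <- matrix(0, v, Af)
      for (a in seq_len(Af)) {
        comp <- .nipals_component(Ef, tol, max_iter,
                                  paste("CV component", a),
                                  strict = FALSE)
        Pf[, a] <- comp$p
        Ef <- Ef - tcrossprod(comp$t, comp$p)
      }
      resid <- te
      for (a in seq_len(A)) {
        aa <- min(a, Af)
        Pa <- Pf[, seq_len(aa), drop = FALSE]
        press[a] <- press[a] + sum((te - te %*% Pa %*% t(Pa))^2)
      }
    }
    q2 <- 1 - press / ssx
  }
  structure(list(scores = T, loadings = P,
                 r2x_per_component = r2x, r2x_cum = cumsum(r2x),
                 q2_cum = q2,
                 hotelling_t2 = stats::setNames(t2, rownames(Xm)),
                 t2_limit_95 = hotelling_limit(n, A, 0.05),
                 n = n, A = A),
            class = "pca_model")
}

#' Hotelling T-squared control limit
#'
#' `limit = A (n - 1)(n + 1) / (n (n - A)) * F(1 - alpha; A, n - A)`.
#' @param n number of samples; must exceed `A`.
#' @param A number of components.
#' @param alpha significance level (default 0.05 for the 95% ellipse).
#' @export
hotelling_limit <- function(n, A, alpha = 0.05) {
  if (n <= A) stop("need more samples than components for a T2 limit")
  A * (n - 1) * (n + 1) / (n * (n - A)) *
    stats::qf(1 - alpha, A, n - A)
}

#' Samples beyond the Hotelling T-squared limit
#'
#' Chemically unique samples lie outside the tolerance ellipse of the PCA
#' scores; they are reported by name (or index when the matrix carried no
#' row names).
#'
#' @param model a fitted `pca_model`.
#' @param alpha significance level (default 0.05).
#' @return Character vector of outlying sample ids.
#' @export
hotelling_outliers <- function(model, alpha = 0.05) {
  lim <- hotelling_limit(model$n, model$A, alpha)
  t2 <- model$hotelling_t2
  ids <- names(t2)
  if (is.null(ids)) ids <- as.character(seq_along(t2))
  ids[t2 > lim]
}

.as_class_vector <- function(y) {
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  if (is.factor(y) || is.character(y)) {
    stop("y must be numeric +1/-1 (code the active class as +1)")
  }
  if (!all(y %in% c(-1, 1))) stop("y must contain only +1 and -1")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  as.numeric(y)
}

#' Fit an OPLS-DA model
#'
#' One predictive component plus `n_ortho` class-orthogonal components.
#' The predictive weight is `w = X'y` normalized; each orthogonal round
#' takes `p = X't/(t't)`, removes the predictive direction
#' (`w_o = p - (w'p) w`, normalized), deflates `X` by `t_o p_o'` and
#' recomputes the predictive score on the deflated matrix. The predictive
#' and summed orthogonal R2X are reported as between-group and
#' within-group percentage variation; Q2 comes from 7-fold
#' contiguous-block cross-validated class prediction.
#'
#' @param X a `scaled_matrix` or pre-scaled numeric matrix.
#' @param y class vector, +1 for the active class, -1 otherwise.
#' @param n_ortho number of orthogonal components (>= 0, < n - 1).
#' @param compute_q2 set `FALSE` to skip cross-validation.
#' @param cv_folds number of contiguous CV blocks (default 7).
#' @return list of class `oplsda_model`.
#' @export
oplsda_fit <- function(X, y, n_ortho = 1L, compute_q2 = TRUE,
                       cv_folds = 7L) {
  Xm <- .as_X(X)
  y <- .as_class_vector(y)
  n <- nrow(Xm)
  stopifnot(length(y) == n)
  if (n_ortho < 0 || n_ortho >= n - 1) {
    stop("n_ortho must be in [0, n - 2]")
  }
  ssx <- sum(Xm^2)

  core <- function(E, y) {
    w <- drop(crossprod(E, y))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(NULL)
    w <- w / nw
    t <- drop(E %*% w)
    T_o <- matrix(0, nrow(E), n_ortho)
    P_o <- matrix(0, ncol(E), n_ortho)
    W_o <- matrix(0, ncol(E), n_ortho)
    if (n_ortho > 0) {
      for (k in seq_len(n_ortho)) {
        p <- drop(crossprod(E, t)) / sum(t^2)
        w_o <- p - sum(w * p) * w
        nwo <- sqrt(sum(w_o^2))
        if (nwo < 1e-12) {
          T_o <- T_o[, seq_len(k - 1), drop = FALSE]
          P_o <- P_o[, seq_len(k - 1), drop = FALSE]
          W_o <- W_o[, seq_len(k - 1), drop = FALSE]
          break
        }
        w_o <- w_o / nwo
        t_o <- drop(E %*% w_o)
        p_o <- drop(crossprod(E, t_o)) / sum(t_o^2)
        E <- E - tcrossprod(t_o, p_o)
        T_o[, k] <- t_o; P_o[, k] <- p_o; W_o[, k] <- w_o
        t <- drop(E %*% w)
      }
    }
    p_p <- drop(crossprod(E, t)) / sum(t^2)
    list(w = w, t_p = t, p_p = p_p, T_o = T_o, P_o = P_o, W_o = W_o,
         E = E)
  }

  fit <- core(Xm, y)
  if (is.null(fit)) stop("X carries no covariance with y; cannot fit")
  yc <- y - mean(y)
  b <- sum(fit$t_p * yc) / sum(fit$t_p^2)
  r2y <- 1 - sum((yc - b * fit$t_p)^2) / sum(yc^2)
  r2x_pred <- sum(fit$t_p^2) * sum(fit$p_p^2) / ssx
  r2x_ortho <- if (ncol(fit$T_o) > 0) {
    sum(colSums(fit$T_o^2) * colSums(fit$P_o^2)) / ssx
  } else 0

  q2 <- NA_real_
  if (compute_q2) {
    blocks <- .cv_blocks(n, cv_folds)
    press <- 0; ssy <- 0
    for (bl in blocks) {
      tr_idx <- setdiff(seq_len(n), bl)
      mu <- colMeans(Xm[tr_idx, , drop = FALSE])
      Etr <- sweep(Xm[tr_idx, , drop = FALSE], 2, mu, "-")
      Ete <- sweep(Xm[bl, , drop = FALSE], 2, mu, "-")
      ytr <- y[tr_idx]
      f <- core(Etr, ytr - mean(ytr))
      yhat <- rep(mean(ytr), length(bl))
      if (!is.null(f)) {
        if (ncol(f$T_o) > 0) {
          for (k in seq_len(ncol(f$T_o))) {
            t_o_te <- drop(Ete %*% f$W_o[, k])
            Ete <- Ete - tcrossprod(t_o_te, f$P_o[, k])
          }
        }
        t_te <- drop(Ete %*% f$w)
        btr <- sum(f$t_p * (ytr - mean(ytr))) / sum(f$t_p^2)
        yhat <- mean(ytr) + btr * t_te
      }
      press <- press + sum((y[bl] - yhat)^2)
      ssy <- ssy + sum((y[bl] - mean(y))^2)
    }
    q2 <- 1 - press / ssy
  }

  structure(list(y = y, w = fit$w, t_p = fit$t_p, p_p = fit$p_p,
                 T_ortho = fit$T_o, P_ortho = fit$P_o, W_ortho = fit$W_o,
                 n_ortho = ncol(fit$T_o),
                 r2x_predictive = r2x_pred, r2x_orthogonal = r2x_ortho,
                 r2y = r2y, q2 = q2, b = b, y_mean = mean(y),
                 between_group_pct = 100 * r2x_pred,
                 within_group_pct = 100 * r2x_ortho,
                 residual_pct = 100 * (1 - r2x_pred - r2x_ortho),
                 n = n),
            class = "oplsda_model")
}

#' S-plot statistics of an OPLS-DA model
#'
#' For every variable `j`: `cov_j = t_p' X_j / (n - 1)` (modeled
#' covariance, the S-plot x axis), `corr_j = cov_j / (sd(t_p) sd(X_j))`
#' (reliability, the y axis) and a two-sided p-value for the correlation
#' under a t distribution with `n - 2` degrees of freedom.
#'
#' @param model a fitted `oplsda_model`.
#' @param X the scaled matrix the model was fitted on.
#' @return tibble with `variable`, `cov`, `corr`, `p_value`.
#' @export
splot <- function(model, X) {
  Xm <- .as_X(X)
  n <- nrow(Xm)
  t_p <- model$t_p
  sds <- apply(Xm, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable in X; drop it (pareto_scale does) ",
         "before computing S-plot statistics")
  }
  cov_j <- drop(crossprod(Xm, t_p)) / (n - 1)
  corr_j <- cov_j / (stats::sd(t_p) * sds)
  corr_j <- pmin(pmax(corr_j, -1), 1)
  tstat <- corr_j * sqrt((n - 2) / pmax(1 - corr_j^2,
                                        .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  vars <- colnames(Xm)
  if (is.null(vars)) vars <- as.character(seq_len(ncol(Xm)))
  tibble::tibble(variable = vars, cov = unname(cov_j),
                 corr = unname(corr_j), p_value = unname(p))
}

#' Selection thresholds for discriminant variables
#'
#' @param p_threshold p-value cut-off (default 0.10: smaller p-values give
#'   stronger evidence of class-discriminating behaviour).
#' @param active_side `+1` or `-1`: the sign of `cov`/`corr` that points
#'   toward the active class. Leave `NULL` to take it from the model
#'   (sign of the mean predictive score over active samples).
#' @export
selection_config <- function(p_threshold = 0.10, active_side = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  if (!is.null(active_side)) stopifnot(active_side %in% c(-1, 1))
  structure(list(p_threshold = p_threshold, active_side = active_side),
            class = "selection_config")
}

#' Active-class side of an OPLS-DA model
#'
#' The sign of the mean predictive score over the active (+1) samples;
#' removes the quadrant ambiguity of S-plots.
#' @param model a fitted `oplsda_model`.
#' @export
active_side <- function(model) {
  s <- sign(mean(model$t_p[model$y == 1]))
  if (s == 0) 1 else s
}

#' Select discriminating variables from S-plot statistics
#'
#' Variables lying on the active side (sign of `cov` matching the active
#' class) with `p_value <= p_threshold`, ranked by p ascending and then
#' absolute covariance descending.
#'
#' @param stats output of [splot()].
#' @param model the fitted `oplsda_model` (used for the active side when
#'   `cfg$active_side` is `NULL`).
#' @param cfg a [selection_config()].
#' @return The selected rows of `stats`, ranked; may be empty.
#' @export
select_discriminating <- function(stats, model = NULL,
                                  cfg = selection_config()) {
  side <- cfg$active_side
  if (is.null(side)) {
    if (is.null(model)) stop("need a model or an explicit active_side")
    side <- active_side(model)
  }
  sel <- stats[sign(stats$cov) == side &
                 stats$p_value <= cfg$p_threshold, , drop = FALSE]
  sel[order(sel$p_value, -abs(sel$cov)), , drop = FALSE]
}
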