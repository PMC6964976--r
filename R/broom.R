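
# broom-style accessors ---------------------------------------------------

#' Tidy a fitted completion model
#'
#' One row per drug-target pair with the predicted score and, when available,
#' the training observation.
#'
#' @param x an `mgnnm_fit` or `svs_fit`.
#' @param ... unused.
#' @return A tibble with columns `drug`, `target`, `score`.
#' @method tidy mgnnm_fit
#' @export
tidy.mgnnm_fit <- function(x, ...) {
  X <- predict(x)
  dn <- dimnames(X)
  tibble::tibble(
    drug = rep(dn[[1]] %||% as.character(seq_len(nrow(X))), times = ncol(X)),
    target = rep(dn[[2]] %||% as.character(seq_len(ncol(X))), each = nrow(X)),
    score = as.vector(X)
  )
}

#' @rdname tidy.mgnnm_fit
#' @method tidy svs_fit
#' @export
tidy.svs_fit <- function(x, ...) {
  class(x) <- "mgnnm_fit"
  x$dimnames <- dimnames(x$X)
  tidy.mgnnm_fit(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Glance at a fitted completion model
#'
#' @param x an `mgnnm_fit` or `svs_fit`.
#' @param ... unused.
#' @return One-row tibble: `iterations`, `converged`, `objective` (final),
#'   `rank` (numerical rank of the completed matrix).
#' @method glance mgnnm_fit
#' @export
glance.mgnnm_fit <- function(x, ...) {
  d <- svd(x$X, nu = 0, nv = 0)$d
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    objective = tail_obj(x),
    rank = sum(d > max(dim(x$X)) * .Machine$double.eps * max(d, 1))
  )
}

#' @rdname glance.mgnnm_fit
#' @method glance svs_fit
#' @export
glance.svs_fit <- glance.mgnnm_fit

#' Tidy cross-validation results
#'
#' @param x a `dti_cv` object.
#' @param ... unused.
#' @return The per-fold tibble (`run`, `fold`, `n_test`, `n_pos`, `aupr`,
#'   `auc`).
#' @method tidy dti_cv
#' @export
tidy.dti_cv <- function(x, ...) x$results

#' @rdname tidy.dti_cv
#' @method glance dti_cv
#' @export
glance.dti_cv <- function(x, ...) x$summary

#' Tidy grid search results
#'
#' @param x a `dti_grid`.
#' @param ... unused.
#' @return One row per evaluated parameter combination.
#' @method tidy dti_grid
#' @export
tidy.dti_grid <- function(x, ...) x$results

#' @rdname tidy.dti_grid
#' @method glance dti_grid
#' @export
glance.dti_grid <- function(x, ...) x$best_row

# plots -------------------------------------------------------------------

#' Convergence plot of a fitted completion model
#'
#' Objective value against (outer) iteration, on a log10 y scale.
#'
#' @param object an `mgnnm_fit` or `svs_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot mgnnm_fit
#' @export
autoplot.mgnnm_fit <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$objective) - 1,
    objective = object$objective
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "iteration", y = "objective",
      title = "Completion objective per iteration"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mgnnm_fit
#' @method autoplot svs_fit
#' @export
autoplot.svs_fit <- autoplot.mgnnm_fit

#' Plot per-fold cross-validation metrics
#'
#' @param object a `dti_cv`.
#' @param ... unused.
#' @return A ggplot of per-fold AUPR and AUC distributions.
#' @method autoplot dti_cv
#' @export
autoplot.dti_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::filter(object$results, !is.na(.data$aupr)),
    cols = c("aupr", "auc"), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 0.7) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Per-fold metrics (%s)", object$setting)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a grid-search AUPR surface or profile
#'
#' If the grid varied `mu1` and `mu2`, a tile plot of mean AUPR over the two
#' graph weights; otherwise a profile of mean AUPR against the first varied
#' parameter.
#'
#' @param object a `dti_grid`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot dti_grid
#' @export
autoplot.dti_grid <- function(object, ...) {
  res <- object$results
  varied <- names(res)[vapply(res, function(col) {
    is.numeric(col) && length(unique(col)) > 1
  }, logical(1))]
  varied <- setdiff(varied, c("aupr_mean", "aupr_sd", "auc_mean", "auc_sd"))
  if (all(c("mu1", "mu2") %in% varied)) {
    return(
      ggplot2::ggplot(res, ggplot2::aes(
        factor(.data$mu1), factor(.data$mu2), fill = .data$aupr_mean
      )) +
        ggplot2::geom_tile() +
        ggplot2::labs(x = "mu1 (drug graph)", y = "mu2 (target graph)",
                      fill = "mean AUPR") +
        ggplot2::theme_minimal()
    )
  }
  xvar <- if (length(varied) > 0) varied[1] else names(res)[1]
  ggplot2::ggplot(res, ggplot2::aes(.data[[xvar]], .data$aupr_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xvar, y = "mean AUPR") +
    ggplot2::theme_minimal()
}
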