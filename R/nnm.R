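
# Nuclear norm minimization by singular value shrinkage ------------------

#' Masked matrix completion problem
#'
#' Pairs the partially observed interaction matrix `M` with its binary
#' observation mask `A` (1 = observed, 0 = unknown). Unobserved entries of `M`
#' are ignored by all solvers.
#'
#' @param observed numeric matrix `M`; must be finite wherever `mask` is 1.
#' @param mask binary matrix of the same shape, defaults to all-observed.
#' @return An object of class `masked_problem`.
#' @export
masked_problem <- function(observed, mask = NULL) {
  if (!is.matrix(observed) || !is.numeric(observed)) {
    stop_dtimc("observed must be a numeric matrix")
  }
  if (is.null(mask)) mask <- matrix(1, nrow(observed), ncol(observed))
  check_binary_matrix(mask, "mask")
  if (!all(dim(mask) == dim(observed))) {
    stop_dtimc("mask and observed must have the same shape",
               class = "dtimc_shape_error")
  }
  if (any(!is.finite(observed[mask == 1]))) {
    stop_dtimc("observed must be finite wherever mask = 1")
  }
  observed[mask == 0] <- 0 # unobserved values are never read; keep finite
  structure(list(observed = observed, mask = mask), class = "masked_problem")
}

#' Squared masked residual
#'
#' The data-fidelity term of the completion objective: the squared Frobenius
#' norm of the residual restricted to observed entries,
#' `|| A o (M - X) ||_F^2`.
#'
#' @param problem a [masked_problem()].
#' @param X candidate completion, same shape as the observations.
#' @return A nonnegative scalar.
#' @export
masked_residual <- function(problem, X) {
  stopifnot(inherits(problem, "masked_problem"))
  if (!all(dim(X) == dim(problem$observed))) {
    stop_dtimc("X shape does not match the problem",
               class = "dtimc_shape_error")
  }
  frob2(problem$mask * (problem$observed - X))
}

#' Soft-threshold a vector of singular values
#'
#' `max(value - tau, 0)` elementwise; the proximal operator of the nuclear
#' norm acts on singular values through this map.
#'
#' @param values nonnegative numeric vector.
#' @param tau nonnegative threshold.
#' @return Thresholded vector.
#' @examples
#' soft_threshold(c(3, 0.4), 1) # 2, 0
#' @export
soft_threshold <- function(values, tau) {
  check_scalar(tau, "tau", lower = 0)
  if (any(values < 0)) stop_dtimc("values must be nonnegative singular values")
  pmax(values - tau, 0)
}

# Proximal-gradient core shared by plain NNM and the stacked X-update of the
# graph-regularized model. Minimizes
#   ||A o (M - X)||_F^2 + sum_i w_i ||T_i - X||_F^2 + lam * ||X||_*
# (aux = list of list(T=, w=)) by iterating a gradient step of length 1/(2a),
# a = step_scale >= 1 + sum(w), followed by singular value soft-thresholding
# at lam/(2a). With no aux terms and a = 1 this is the classical singular
# value shrinkage iteration (gradient operator spectral norm <= 1, threshold
# lam/2). Optionally projects onto the nonnegative orthant each iteration
# (interaction propensities are nonnegative).
svs_core <- function(M, A, lam, aux = list(), a = NULL, X0 = NULL,
                     max_iter = 500L, tol = 1e-6, nonneg = TRUE) {
  w <- vapply(aux, function(term) term$w, numeric(1))
  if (is.null(a)) a <- 1 + sum(w)
  if (a < 1 + sum(w) - 1e-12) {
    stop_dtimc("step scale a must be >= 1 + sum of auxiliary weights")
  }
  X <- if (is.null(X0)) matrix(0, nrow(M), ncol(M)) else X0
  thresh <- lam / (2 * a)

  objective <- function(X) {
    val <- frob2(A * (M - X)) + lam * nuclear_norm(X)
    for (term in aux) val <- val + term$w * frob2(term$T - X)
    val
  }
  obj <- objective(X)
  history <- obj
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    B <- X + (A * (M - X)) / a
    for (term in aux) B <- B + term$w * (term$T - X) / a
    sv <- svd(B)
    d <- soft_threshold(sv$d, thresh)
    X <- sv$u %*% (d * t(sv$v))
    if (nonneg) X[X < 0] <- 0
    obj_new <- objective(X)
    history <- c(history, obj_new)
    if (abs(obj - obj_new) <= tol * max(abs(obj), .Machine$double.eps)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  list(X = X, objective = history, iterations = length(history) - 1L,
       converged = converged)
}

#' Complete a masked matrix by singular value shrinkage
#'
#' Solves the relaxed nuclear norm minimization
#' `min_X ||A o (M - X)||_F^2 + lam ||X||_*`
#' by proximal gradient iterations: a masked gradient step
#' `B = X + (1/a) A o (M - X)` followed by an SVD of `B` with singular values
#' soft-thresholded at `lam / (2a)`, and (by default) projection onto the
#' nonnegative orthant. The objective is convex, so the iteration converges to
#' a global minimizer; it halts when the relative objective change drops below
#' `tol`.
#'
#' @param problem a [masked_problem()].
#' @param lam nuclear norm weight, `lam >= 0`.
#' @param step gradient step scale `a >= 1` (1/(2a) is the actual step
#'   length); the default `a = 1` is the largest step with guaranteed descent
#'   since the masking operator has spectral norm at most 1.
#' @param max_iter,tol iteration cap and relative objective-change tolerance.
#' @param nonneg project iterates onto the nonnegative orthant? Interaction
#'   scores are propensities, so the default keeps them nonnegative.
#' @param X0 optional warm start (default: zero matrix, making the run
#'   deterministic).
#' @return An object of class `svs_fit`: list with the completed matrix `X`,
#'   `objective` (history, including the initial value), `iterations`,
#'   `converged`, and `lam`.
#' @examples
#' M <- matrix(c(1, 0, 0, 1), 2, 2)
#' fit <- svs_complete(masked_problem(M), lam = 0)
#' fit$X
#' @export
svs_complete <- function(problem, lam = 1, step = 1, max_iter = 500L,
                         tol = 1e-6, nonneg = TRUE, X0 = NULL) {
  stopifnot(inherits(problem, "masked_problem"))
  check_scalar(lam, "lam", lower = 0)
  check_scalar(step, "step", lower = 1)
  res <- svs_core(problem$observed, problem$mask, lam,
    aux = list(), a = step, X0 = X0,
    max_iter = max_iter, tol = tol, nonneg = nonneg
  )
  structure(
    list(
      X = res$X, objective = res$objective, iterations = res$iterations,
      converged = res$converged, lam = lam
    ),
    class = "svs_fit"
  )
}

#' @export
print.svs_fit <- function(x, ...) {
  cat(sprintf(
    "<svs_fit> %dx%d, lam = %g, %d iterations (%sconverged), objective %.6g\n",
    nrow(x$X), ncol(x$X), x$lam, x$iterations,
    if (x$converged) "" else "not ", tail_obj(x)
  ))
  invisible(x)
}

tail_obj <- function(fit) fit$objective[length(fit$objective)]
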