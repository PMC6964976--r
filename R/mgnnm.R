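
# Multi-graph regularized nuclear norm minimization (ADMM) ---------------

#' Parameters of the multi-graph regularized completion model
#'
#' Collects every tunable of the graph-regularized solver. The objective being
#' minimized (over `X` and proxies `Y ~ X`, `Z ~ t(X)`) is
#' \deqn{\|A \circ (M - X)\|_F^2 + \lambda \|X\|_* +
#'   \mu_1 Tr(Z L_d Z^T) + \mu_2 Tr(Y L_t Y^T) +
#'   \nu_1 \|Z^T - X\|_F^2 + \nu_2 \|Y - X\|_F^2}
#' where `L_d`, `L_t` are the combined (optionally normalized) drug and target
#' graph Laplacians.
#'
#' @param lam nuclear norm weight, `>= 0`.
#' @param mu1 drug-graph regularization weight, `>= 0`.
#' @param mu2 target-graph regularization weight, `>= 0`.
#' @param nu1,nu2 positive proxy-coupling (splitting) penalties.
#' @param p neighborhood size for the p-nearest-neighbor sparsification of
#'   the combined similarities.
#' @param weights per-measure similarity weights; see
#'   [default_similarity_weights()].
#' @param normalized_laplacian use normalized combined Laplacians?
#' @param max_iter outer (ADMM) iteration cap.
#' @param tol relative objective-change tolerance for the outer loop.
#' @param inner_max_iter,inner_tol iteration cap and tolerance of the inner
#'   singular value shrinkage solve used for the X-update (warm started, so a
#'   modest cap suffices).
#' @param nonneg project X onto the nonnegative orthant inside the X-update?
#' @return An object of class `mgnnm_params` (a validated list).
#'
#' The defaults `mu1 = 0.5`, `mu2 = 0.1` sit at the AUPR optimum of the
#' benchmark parameter surface; `lam = 1`, `nu1 = nu2 = 1`, `p = 5` are
#' moderate settings that the cross-validation grid search can refine per
#' dataset.
#' @export
mgnnm_params <- function(lam = 1, mu1 = 0.5, mu2 = 0.1, nu1 = 1, nu2 = 1,
                         p = 5, weights = default_similarity_weights(),
                         normalized_laplacian = TRUE,
                         max_iter = 200L, tol = 1e-6,
                         inner_max_iter = 100L, inner_tol = 1e-7,
                         nonneg = TRUE) {
  check_scalar(lam, "lam", lower = 0)
  check_scalar(mu1, "mu1", lower = 0)
  check_scalar(mu2, "mu2", lower = 0)
  check_scalar(nu1, "nu1", lower = 0, strict = TRUE)
  check_scalar(nu2, "nu2", lower = 0, strict = TRUE)
  if (!is.null(p)) check_count(p, "p")
  check_count(max_iter, "max_iter")
  check_count(inner_max_iter, "inner_max_iter")
  check_scalar(tol, "tol", lower = 0, strict = TRUE)
  check_scalar(inner_tol, "inner_tol", lower = 0, strict = TRUE)
  structure(
    list(
      lam = lam, mu1 = mu1, mu2 = mu2, nu1 = nu1, nu2 = nu2, p = p,
      weights = weights, normalized_laplacian = normalized_laplacian,
      max_iter = as.integer(max_iter), tol = tol,
      inner_max_iter = as.integer(inner_max_iter), inner_tol = inner_tol,
      nonneg = nonneg
    ),
    class = "mgnnm_params"
  )
}

#' @export
print.mgnnm_params <- function(x, ...) {
  cat(sprintf(
    "<mgnnm_params> lam=%g mu1=%g mu2=%g nu1=%g nu2=%g p=%s %s Laplacian\n",
    x$lam, x$mu1, x$mu2, x$nu1, x$nu2,
    if (is.null(x$p)) "none" else x$p,
    if (x$normalized_laplacian) "normalized" else "combinatorial"
  ))
  invisible(x)
}

#' Solve the degenerate Sylvester equation of the graph proxy updates
#'
#' Both proxy updates of the ADMM iteration reduce to a Sylvester equation
#' whose left coefficient is a scalar multiple of the identity:
#' `nu * T + mu * T L = nu * C`. Because `nu I + mu L` is symmetric positive
#' definite for `nu > 0` and `L` positive semidefinite, the closed form
#' `T = nu * C (nu I + mu L)^{-1}` applies; a single Cholesky factorization is
#' reused across all rows of `C`, so no general Sylvester machinery is needed.
#'
#' @param C right-hand-side matrix (k x l).
#' @param L symmetric positive semidefinite l x l matrix (a graph Laplacian).
#' @param nu positive scalar.
#' @param mu nonnegative scalar.
#' @return The k x l solution matrix `T`.
#' @examples
#' L <- matrix(c(1, -1, -1, 1), 2, 2)
#' solve_sylvester(diag(2), L, nu = 1, mu = 0.5)
#' @export
solve_sylvester <- function(C, L, nu, mu) {
  check_scalar(nu, "nu", lower = 0, strict = TRUE)
  check_scalar(mu, "mu", lower = 0)
  check_symmetric(L, "L", tol = 1e-8)
  if (ncol(C) != nrow(L)) {
    stop_dtimc("C has ", ncol(C), " columns but L is ", nrow(L), "x", ncol(L),
               class = "dtimc_shape_error")
  }
  if (mu == 0) return(C)
  K <- nu * diag(nrow(L)) + mu * symmetrize(L)
  ch <- chol(K)
  # T = nu * C * K^{-1}; solve K t(T) = nu t(C)
  t(backsolve(ch, forwardsolve(t(ch), nu * t(C))))
}

#' Objective of the multi-graph regularized model
#'
#' Evaluates the full split objective (see [mgnnm_params()]) at given iterates.
#'
#' @param X completion iterate (n x m).
#' @param Y,Z proxy iterates (`Y` n x m, `Z` m x n, so `t(Z) ~ X`).
#' @param problem a [masked_problem()].
#' @param graph_drug,graph_target [build_graph()] operators for the drug
#'   (n x n) and target (m x m) sides.
#' @param params an [mgnnm_params()].
#' @return Scalar objective value.
#' @export
mgnnm_objective <- function(X, Y, Z, problem, graph_drug, graph_target,
                            params) {
  Ld <- graph_drug$laplacian
  Lt <- graph_target$laplacian
  masked_residual(problem, X) +
    params$lam * nuclear_norm(X) +
    params$mu1 * sum(diag(Z %*% Ld %*% t(Z))) +
    params$mu2 * sum(diag(Y %*% Lt %*% t(Y))) +
    params$nu1 * frob2(t(Z) - X) +
    params$nu2 * frob2(Y - X)
}

#' Fit the multi-graph regularized nuclear norm completion model
#'
#' Alternating (ADMM-style) minimization of the split objective in
#' [mgnnm_params()]:
#' \enumerate{
#'   \item X-update: nuclear-norm-penalized least squares against the
#'     observations and both proxies, solved by warm-started singular value
#'     shrinkage on the stacked problem
#'     `||A o (M - X)||^2 + nu1 ||t(Z) - X||^2 + nu2 ||Y - X||^2 + lam ||X||_*`.
#'   \item Y-update: `nu2 Y + mu2 Y L_t = nu2 X`, the target-side Sylvester
#'     equation, solved in closed form by [solve_sylvester()].
#'   \item Z-update: `nu1 Z + mu1 Z L_d = nu1 t(X)`, the drug-side analogue.
#' }
#' `Y` couples to the target Laplacian (it multiplies X on the right, an
#' m x m operator) and `Z` to the drug Laplacian; initialization is `Y = M`,
#' `Z = t(M)`. Each block update minimizes the joint convex objective exactly
#' (Y, Z) or monotonically from a warm start (X), so the recorded objective
#' history is non-increasing and the iteration stops when its relative change
#' falls below `params$tol`.
#'
#' @inheritParams mgnnm_objective
#' @param problem a [masked_problem()]; rows are drugs, columns targets.
#' @return An object of class `mgnnm_fit`: list with `X`, `Y`, `Z`,
#'   `objective` (history), `iterations`, `converged`, `params`, and the
#'   dimnames of the training matrix.
#' @seealso [predict.mgnnm_fit()], [dti_graphs()] to build the Laplacians.
#' @export
mgnnm_fit <- function(problem, graph_drug, graph_target,
                      params = mgnnm_params()) {
  stopifnot(inherits(problem, "masked_problem"))
  stopifnot(inherits(graph_drug, "dti_graph"), inherits(graph_target, "dti_graph"))
  stopifnot(inherits(params, "mgnnm_params"))
  M <- problem$observed
  A <- problem$mask
  n <- nrow(M)
  m <- ncol(M)
  if (nrow(graph_drug$laplacian) != n) {
    stop_dtimc("drug graph is ", nrow(graph_drug$laplacian), "x",
               ncol(graph_drug$laplacian), " but the problem has ", n, " drugs",
               class = "dtimc_shape_error")
  }
  if (nrow(graph_target$laplacian) != m) {
    stop_dtimc("target graph is ", nrow(graph_target$laplacian), "x",
               ncol(graph_target$laplacian), " but the problem has ", m,
               " targets", class = "dtimc_shape_error")
  }
  Ld <- graph_drug$laplacian
  Lt <- graph_target$laplacian

  X <- matrix(0, n, m)
  Y <- M
  Z <- t(M)
  obj <- mgnnm_objective(X, Y, Z, problem, graph_drug, graph_target, params)
  history <- obj
  converged <- FALSE

  for (iter in seq_len(params$max_iter)) {
    inner <- svs_core(M, A, params$lam,
      aux = list(list(T = t(Z), w = params$nu1), list(T = Y, w = params$nu2)),
      X0 = X, max_iter = params$inner_max_iter, tol = params$inner_tol,
      nonneg = params$nonneg
    )
    X <- inner$X
    Y <- solve_sylvester(X, Lt, params$nu2, params$mu2)
    Z <- solve_sylvester(t(X), Ld, params$nu1, params$mu1)
    obj_new <- mgnnm_objective(X, Y, Z, problem, graph_drug, graph_target,
                               params)
    history <- c(history, obj_new)
    if (abs(obj - obj_new) <= params$tol * max(abs(obj), .Machine$double.eps)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  structure(
    list(
      X = X, Y = Y, Z = Z, objective = history,
      iterations = length(history) - 1L, converged = converged,
      params = params, dimnames = dimnames(M)
    ),
    class = "mgnnm_fit"
  )
}

#' @export
print.mgnnm_fit <- function(x, ...) {
  cat(sprintf(
    "<mgnnm_fit> %dx%d, %d outer iterations (%sconverged), objective %.6g\n",
    nrow(x$X), ncol(x$X), x$iterations,
    if (x$converged) "" else "not ", tail_obj(x)
  ))
  invisible(x)
}

#' Predicted interaction scores
#'
#' Returns the completed matrix `X`; a larger entry means a higher predicted
#' interaction propensity. Scores are used only through their ranking (AUPR /
#' AUC), so no threshold is applied.
#'
#' @param object a fitted `mgnnm_fit` or `svs_fit`.
#' @param ... unused.
#' @return The n x m score matrix with the training dimnames.
#' @export
predict.mgnnm_fit <- function(object, ...) {
  X <- object$X
  if (!is.null(object$dimnames)) dimnames(X) <- object$dimnames
  X
}

#' @rdname predict.mgnnm_fit
#' @export
predict.svs_fit <- function(object, ...) object$X

#' Fit the completion model directly from a dataset
#'
#' Convenience wrapper: builds the combined graphs from a [dti_dataset()]
#' (optionally from a training matrix with held-out entries removed) and runs
#' [mgnnm_fit()].
#'
#' @param ds a [dti_dataset()].
#' @param params an [mgnnm_params()].
#' @param mask optional binary observation mask (default: everything
#'   observed).
#' @param leak_free derive interaction-profile similarities from the masked
#'   training matrix only (default) rather than the full matrix.
#' @return An `mgnnm_fit`.
#' @export
fit_dti <- function(ds, params = mgnnm_params(), mask = NULL,
                    leak_free = TRUE) {
  stopifnot(inherits(ds, "dti_dataset"))
  if (is.null(mask)) mask <- matrix(1, nrow(ds$interactions), ncol(ds$interactions))
  M <- ds$interactions * mask
  X_sim <- if (leak_free) M else ds$interactions
  graphs <- dti_graphs(ds, X_train = X_sim, p = params$p,
                       weights = params$weights,
                       normalized = params$normalized_laplacian)
  problem <- masked_problem(M, mask)
  fit <- mgnnm_fit(problem, graphs$drug, graphs$target, params)
  fit$dimnames <- dimnames(ds$interactions)
  fit
}
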