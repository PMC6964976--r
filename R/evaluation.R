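
# Cross-validation settings, AUPR/AUC, aggregation, grid search ----------

#' Build a cross-validation fold plan
#'
#' Three hold-out settings are supported, matching how drug-target prediction
#' methods are benchmarked:
#' \describe{
#'   \item{CVS1 (pair prediction)}{random drug-target pairs are held out; test
#'     sets are linear (column-major) indices into the interaction matrix.}
#'   \item{CVS2 (novel drugs)}{entire drug rows are held out; test sets are
#'     drug indices.}
#'   \item{CVS3 (novel targets)}{entire target columns are held out; test sets
#'     are target indices.}
#' }
#' Within each run the test sets are disjoint, cover every unit exactly once
#' and differ in size by at most one. The plan is a deterministic function of
#' `seed`.
#'
#' @param n_drugs,n_targets interaction matrix dimensions.
#' @param setting `"CVS1"`, `"CVS2"` or `"CVS3"`.
#' @param k_folds folds per run (default 10).
#' @param n_runs independent repetitions (default 5).
#' @param seed integer seed.
#' @return An object of class `fold_plan`: list with the settings and `folds`,
#'   a list (one element per run) of lists of integer test-index vectors.
#' @examples
#' plan <- make_folds(10, 8, "CVS1", k_folds = 5, n_runs = 1, seed = 1)
#' lengths(plan$folds[[1]])
#' @export
make_folds <- function(n_drugs, n_targets,
                       setting = c("CVS1", "CVS2", "CVS3"),
                       k_folds = 10L, n_runs = 5L, seed = 1L) {
  setting <- match.arg(setting)
  check_count(n_drugs, "n_drugs")
  check_count(n_targets, "n_targets")
  k_folds <- check_count(k_folds, "k_folds")
  n_runs <- check_count(n_runs, "n_runs")
  n_units <- switch(setting,
    CVS1 = n_drugs * n_targets,
    CVS2 = n_drugs,
    CVS3 = n_targets
  )
  if (k_folds > n_units) {
    stop_dtimc(
      "k_folds = ", k_folds, " exceeds the ", n_units,
      " partitionable units of setting ", setting
    )
  }
  withr::with_seed(as.integer(seed), {
    run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
    folds <- lapply(run_seeds, function(s) {
      withr::with_seed(s, {
        shuffled <- sample.int(n_units)
        fold_id <- sort(rep_len(seq_len(k_folds), n_units))
        unname(split(shuffled, fold_id))
      })
    })
  })
  structure(
    list(
      setting = setting, k_folds = k_folds, n_runs = n_runs,
      seed = as.integer(seed), run_seeds = run_seeds,
      n_drugs = n_drugs, n_targets = n_targets, folds = folds
    ),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf(
    "<fold_plan> %s: %d runs x %d folds on %d drugs x %d targets (seed %d)\n",
    x$setting, x$n_runs, x$k_folds, x$n_drugs, x$n_targets, x$seed
  ))
  invisible(x)
}

# training mask for one fold: 1 everywhere except the held-out entries
fold_mask <- function(plan, run, fold) {
  A <- matrix(1, plan$n_drugs, plan$n_targets)
  idx <- plan$folds[[run]][[fold]]
  switch(plan$setting,
    CVS1 = A[idx] <- 0,
    CVS2 = A[idx, ] <- 0,
    CVS3 = A[, idx] <- 0
  )
  A
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step-curve area: scores are ranked in descending order
#' (ties broken pessimistically, i.e. negatives ahead of positives) and the
#' precision at each positive's rank is averaged over the positives. This is
#' the preferred metric for interaction prediction because it punishes
#' high-ranked false positives, the candidates that would be carried into
#' experimental validation.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (same length); at least one positive required.
#' @return Scalar in \[0, 1\].
#' @examples
#' aupr(c(0.9, 0.8, 0.7), c(1, 0, 1)) # (1 + 2/3) / 2
#' @export
aupr <- function(scores, labels) {
  check_metric_inputs(scores, labels)
  if (sum(labels) == 0) {
    stop_dtimc("aupr is undefined without positive labels",
               class = "dtimc_metric_error")
  }
  ord <- order(-scores, labels) # ties: negatives first (pessimistic)
  y <- labels[ord]
  cum_tp <- cumsum(y)
  precision_at_pos <- cum_tp[y == 1] / which(y == 1)
  mean(precision_at_pos)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs ranked correctly, with ties counted one half.
#'
#' @inheritParams aupr
#' @return Scalar in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  check_metric_inputs(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_dtimc("auc needs at least one positive and one negative label",
               class = "dtimc_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

check_metric_inputs <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_dtimc("scores and labels must have the same length")
  }
  if (!all(labels %in% c(0, 1))) stop_dtimc("labels must be binary")
  if (any(!is.finite(scores))) stop_dtimc("scores must be finite")
  invisible(NULL)
}

# indices (linear, column-major) of the test entries of one fold
fold_test_entries <- function(plan, run, fold) {
  idx <- plan$folds[[run]][[fold]]
  switch(plan$setting,
    CVS1 = idx,
    CVS2 = as.vector(outer(idx, (seq_len(plan$n_targets) - 1) * plan$n_drugs, "+")),
    CVS3 = as.vector(outer(seq_len(plan$n_drugs), (idx - 1) * plan$n_drugs, "+"))
  )
}

#' Cross-validate the completion model on a DTI dataset
#'
#' For every fold of every run: zero the held-out entries to form the training
#' matrix (training zeros are treated as observed non-interactions, held-out
#' entries as unobserved), rebuild the interaction-profile similarities from
#' the training matrix (unless `leak_free = FALSE`), build the combined
#' graphs, fit the model, and score the held-out entries. AUPR and AUC are
#' computed per fold and aggregated as mean and standard deviation across all
#' folds of all runs. Folds whose test set lacks a positive (or, for AUC, a
#' negative) label are skipped with a warning; this occurs for very sparse
#' networks.
#'
#' @param ds a [dti_dataset()].
#' @param params an [mgnnm_params()]; set `mu1 = mu2 = 0` for the plain
#'   nuclear-norm baseline.
#' @param plan a [make_folds()] plan matching the dataset dimensions.
#' @param leak_free recompute interaction-derived similarities from the
#'   training matrix only (default). `FALSE` reproduces the variant that
#'   derives them once from the full matrix.
#' @return An object of class `dti_cv`: list with `results` (tibble with one
#'   row per fold: run, fold, n_test, n_pos, aupr, auc), `summary` (one-row
#'   tibble of means/sds), `setting`, `params`, `plan`.
#' @export
cross_validate <- function(ds, params = mgnnm_params(), plan,
                           leak_free = TRUE) {
  stopifnot(inherits(ds, "dti_dataset"), inherits(plan, "fold_plan"))
  if (plan$n_drugs != nrow(ds$interactions) ||
      plan$n_targets != ncol(ds$interactions)) {
    stop_dtimc("fold plan dimensions do not match the dataset",
               class = "dtimc_shape_error")
  }
  grid <- tidyr::expand_grid(run = seq_len(plan$n_runs),
                             fold = seq_len(plan$k_folds))
  rows <- purrr::pmap(grid, function(run, fold) {
    A <- fold_mask(plan, run, fold)
    fit <- fit_dti(ds, params, mask = A, leak_free = leak_free)
    test_idx <- fold_test_entries(plan, run, fold)
    scores <- predict(fit)[test_idx]
    labels <- ds$interactions[test_idx]
    n_pos <- sum(labels == 1)
    n_neg <- sum(labels == 0)
    if (n_pos == 0 || n_neg == 0) {
      rlang::warn(sprintf(
        "skipping %s run %d fold %d: test set has %d positives / %d negatives",
        plan$setting, run, fold, n_pos, n_neg
      ))
      return(tibble::tibble(
        run = run, fold = fold, n_test = length(labels),
        n_pos = n_pos, aupr = NA_real_, auc = NA_real_
      ))
    }
    tibble::tibble(
      run = run, fold = fold, n_test = length(labels), n_pos = n_pos,
      aupr = aupr(scores, labels), auc = auc_score(scores, labels)
    )
  })
  results <- dplyr::bind_rows(rows)
  structure(
    list(
      results = results,
      summary = summarize_cv(results, plan$setting),
      setting = plan$setting, params = params, plan = plan
    ),
    class = "dti_cv"
  )
}

summarize_cv <- function(results, setting) {
  scored <- dplyr::filter(results, !is.na(.data$aupr))
  tibble::tibble(
    setting = setting,
    n_folds = nrow(results),
    n_scored = nrow(scored),
    aupr_mean = mean(scored$aupr),
    aupr_sd = sd(scored$aupr),
    auc_mean = mean(scored$auc),
    auc_sd = sd(scored$auc)
  )
}

#' @export
print.dti_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<dti_cv> %s: AUPR %.4f (%.4f), AUC %.4f (%.4f) over %d/%d folds\n",
    x$setting, s$aupr_mean, s$aupr_sd, s$auc_mean, s$auc_sd,
    s$n_scored, s$n_folds
  ))
  invisible(x)
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every combination of the supplied parameter values by
#' cross-validation on the given dataset (which should be the training portion
#' of any outer evaluation, so held-out test data never influences the
#' selection) and returns the combination with the best mean AUPR. Ties are
#' broken deterministically by grid order (earlier combination wins).
#'
#' @param ds a [dti_dataset()] (training data).
#' @param setting hold-out setting used for the inner validation folds.
#' @param grid named list of parameter value vectors; names must be arguments
#'   of [mgnnm_params()] (e.g. `list(mu1 = c(0, 0.5), lam = c(0.5, 1))`).
#' @param k_folds,n_runs,seed inner fold-plan settings (defaults: 3 folds,
#'   1 run).
#' @param base_params parameters that every grid point inherits for arguments
#'   the grid does not vary.
#' @return An object of class `dti_grid`: list with `best_params` (an
#'   `mgnnm_params`), `best_row`, and `results` (one row per grid point with
#'   its mean/sd AUPR and AUC).
#' @export
grid_search <- function(ds, setting = "CVS1", grid,
                        k_folds = 3L, n_runs = 1L, seed = 1L,
                        base_params = mgnnm_params()) {
  stopifnot(inherits(ds, "dti_dataset"))
  if (length(grid) == 0) stop_dtimc("grid must be a non-empty named list")
  if (is.null(names(grid)) || any(names(grid) == "")) {
    stop_dtimc("grid entries must be named after mgnnm_params() arguments")
  }
  combos <- do.call(tidyr::expand_grid, grid)
  plan <- make_folds(nrow(ds$interactions), ncol(ds$interactions),
                     setting = setting, k_folds = k_folds, n_runs = n_runs,
                     seed = seed)
  results <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    args <- as.list(combos[i, ])
    params <- do.call(update_params, c(list(params = base_params), args))
    cv <- cross_validate(ds, params, plan)
    dplyr::bind_cols(
      combos[i, ],
      dplyr::select(cv$summary, "aupr_mean", "aupr_sd", "auc_mean", "auc_sd")
    )
  })
  best_i <- which.max(results$aupr_mean)[1]
  best_params <- do.call(
    update_params,
    c(list(params = base_params), as.list(combos[best_i, ]))
  )
  structure(
    list(
      best_params = best_params, best_row = results[best_i, ],
      results = results, setting = setting
    ),
    class = "dti_grid"
  )
}

# rebuild an mgnnm_params with some fields replaced
update_params <- function(params, ...) {
  changes <- list(...)
  fields <- params[setdiff(names(params), NULL)]
  fields[names(changes)] <- changes
  do.call(mgnnm_params, c(
    fields[c("lam", "mu1", "mu2", "nu1", "nu2", "p", "weights",
             "normalized_laplacian", "max_iter", "tol",
             "inner_max_iter", "inner_tol", "nonneg")]
  ))
}

#' @export
print.dti_grid <- function(x, ...) {
  cat(sprintf("<dti_grid> %d grid points (%s); best mean AUPR %.4f\n",
              nrow(x$results), x$setting, x$best_row$aupr_mean))
  print(x$best_params)
  invisible(x)
}
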