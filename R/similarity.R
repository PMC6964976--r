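
# Interaction-profile similarities, weighted fusion, p-NN sparsification,
# combined graph Laplacians ----------------------------------------------

#' Similarity between interaction profiles
#'
#' Computes a pairwise similarity matrix between drugs (rows of the binary
#' interaction matrix) or targets (columns) from their interaction profiles.
#' Four measures are supported:
#' \describe{
#'   \item{cosine}{inner product of the profiles over the product of their
#'     Euclidean norms; a zero profile has no direction, so any pair
#'     involving one gets similarity 0.}
#'   \item{correlation}{Pearson correlation of the profiles; pairs involving
#'     a constant profile (variance 0) get 0.}
#'   \item{hamming}{1 minus the fraction of positions at which the profiles
#'     differ.}
#'   \item{jaccard}{fraction of positions, among those where at least one
#'     profile is non-zero, at which the profiles agree; an empty union
#'     gets 0.}
#' }
#' The degenerate-case conventions (0 rather than NaN) matter for novel
#' drugs/targets whose training profile is all zeros: their interaction-derived
#' similarity then defers entirely to the structure/sequence similarity.
#'
#' @param X binary interaction matrix (drugs x targets).
#' @param side `"drug"` compares rows, `"target"` compares columns.
#' @param kind one of `"cosine"`, `"correlation"`, `"hamming"`, `"jaccard"`.
#' @return A symmetric k x k matrix (k = number of drugs or targets) with unit
#'   diagonal wherever the profile is non-degenerate.
#' @examples
#' X <- matrix(c(1, 1, 0, 1, 0, 0), 2, 3, byrow = TRUE)
#' interaction_similarity(X, "drug", "cosine")[1, 2] # 1/sqrt(2)
#' @export
interaction_similarity <- function(X, side = c("drug", "target"),
                                   kind = c("cosine", "correlation",
                                            "hamming", "jaccard")) {
  side <- match.arg(side)
  kind <- match.arg(kind)
  check_binary_matrix(X, "X")
  P <- if (side == "drug") X else t(X) # profiles in rows
  k <- nrow(P)
  n <- ncol(P)

  S <- switch(kind,
    cosine = {
      nrm <- sqrt(rowSums(P^2))
      G <- P %*% t(P)
      denom <- outer(nrm, nrm)
      out <- ifelse(denom > 0, G / pmax(denom, .Machine$double.eps), 0)
      out[denom == 0] <- 0
      out
    },
    correlation = {
      v <- apply(P, 1, sd)
      out <- matrix(0, k, k)
      ok <- v > 0
      if (sum(ok) >= 2) out[ok, ok] <- cor(t(P[ok, , drop = FALSE]))
      if (any(ok)) out[cbind(which(ok), which(ok))] <- 1
      out
    },
    hamming = {
      # fraction of equal positions; for binary rows
      agree <- P %*% t(P) + (1 - P) %*% t(1 - P)
      agree / n
    },
    jaccard = {
      both <- P %*% t(P)
      union <- outer(rowSums(P), rowSums(P), "+") - both
      out <- ifelse(union > 0, both / pmax(union, 1), 0)
      out[union == 0] <- 0
      out
    }
  )
  S <- symmetrize(S)
  ids <- if (side == "drug") rownames(X) else colnames(X)
  dimnames(S) <- list(ids, ids)
  S
}

#' Default weighting of the five similarity measures
#'
#' Cosine, correlation and Jaccard similarities are weighted four times as
#' heavily as Hamming similarity, which contributes the least predictive
#' signal; the standard (chemical structure or sequence) similarity keeps
#' unit weight.
#'
#' @return Named numeric vector over
#'   `c("standard", "cosine", "correlation", "hamming", "jaccard")`.
#' @export
default_similarity_weights <- function() {
  c(standard = 1, cosine = 4, correlation = 4, hamming = 1, jaccard = 4)
}

#' Bundle the five similarity matrices for one side
#'
#' Computes the four interaction-profile similarities from `X` and attaches
#' the standard similarity (chemical structure for drugs, sequence for
#' targets) with per-measure weights.
#'
#' @param X binary interaction matrix (drugs x targets); inside
#'   cross-validation this should be the training matrix with held-out entries
#'   zeroed, so no test information leaks into the graphs.
#' @param standard the precomputed standard similarity for this side.
#' @param side `"drug"` or `"target"`.
#' @param weights named nonnegative weights over the five measures; see
#'   [default_similarity_weights()].
#' @return An object of class `similarity_bundle`: list with `side`,
#'   `matrices` (named list of five k x k matrices) and `weights`.
#' @export
similarity_bundle <- function(X, standard, side = c("drug", "target"),
                              weights = default_similarity_weights()) {
  side <- match.arg(side)
  k <- if (side == "drug") nrow(X) else ncol(X)
  if (nrow(standard) != k || ncol(standard) != k) {
    stop_dtimc("standard similarity must be ", k, "x", k,
               class = "dtimc_shape_error")
  }
  check_symmetric(standard, "standard similarity")
  mats <- list(
    standard = standard,
    cosine = interaction_similarity(X, side, "cosine"),
    correlation = interaction_similarity(X, side, "correlation"),
    hamming = interaction_similarity(X, side, "hamming"),
    jaccard = interaction_similarity(X, side, "jaccard")
  )
  new_similarity_bundle(side, mats, weights)
}

new_similarity_bundle <- function(side, matrices, weights) {
  if (!setequal(names(matrices), names(weights))) {
    stop_dtimc("similarity matrices and weights must have the same names",
               class = "dtimc_key_error")
  }
  if (any(weights < 0)) stop_dtimc("weights must be nonnegative")
  lapply(names(matrices), function(nm) {
    check_symmetric(matrices[[nm]], paste0("similarity '", nm, "'"))
  })
  structure(
    list(side = side, matrices = matrices, weights = weights[names(matrices)]),
    class = "similarity_bundle"
  )
}

#' Weighted combination of a similarity bundle
#'
#' Forms the combined similarity `S_COM = sum_i w_i S_i`. Summing similarities
#' before building the Laplacian is algebraically identical to summing the
#' per-measure graph Laplacians.
#'
#' @param bundle a [similarity_bundle()].
#' @return The combined k x k symmetric matrix.
#' @export
combine_similarities <- function(bundle) {
  stopifnot(inherits(bundle, "similarity_bundle"))
  S <- Reduce(
    `+`,
    purrr::map2(bundle$matrices, bundle$weights, function(m, w) w * m)
  )
  symmetrize(S)
}

#' Sparsify a similarity matrix with a mutual p-nearest-neighbor mask
#'
#' Keeps a similarity entry at full weight when the two nodes are in each
#' other's p-nearest-neighbor sets, at half weight when only one of the two
#' is, and drops it otherwise:
#' `N_ij = 1` if mutual, `0.5` if one-sided, `0` if neither; the output is
#' `S * N` with the diagonal preserved. Neighbors are ranked by descending
#' similarity, ties broken by ascending index; a node is never its own
#' neighbor.
#'
#' @param S symmetric similarity matrix.
#' @param p neighborhood size, `1 <= p <= nrow(S) - 1`.
#' @return Sparsified symmetric matrix of the same shape.
#' @export
sparsify_pnn <- function(S, p) {
  check_symmetric(S, "S")
  k <- nrow(S)
  p <- check_count(p, "p")
  if (p < 1 || p > k - 1) {
    stop_dtimc("p must be between 1 and ", k - 1, " for a ", k, "x", k,
               " similarity matrix")
  }
  in_nbhd <- matrix(FALSE, k, k) # in_nbhd[i, j]: j is among i's p nearest
  for (i in seq_len(k)) {
    cand <- setdiff(seq_len(k), i)
    ord <- cand[order(-S[i, cand], cand)]
    in_nbhd[i, ord[seq_len(p)]] <- TRUE
  }
  N <- (in_nbhd + t(in_nbhd)) / 2 # 1 mutual, 0.5 one-sided, 0 neither
  diag(N) <- 1
  symmetrize(S * N)
}

#' Build a graph operator (degree + Laplacian) from a combined similarity
#'
#' Computes the degree vector `d_i = sum_j S_ij`, the combinatorial Laplacian
#' `L = D - S` and, when `normalized = TRUE` (the default, which tends to
#' behave better as a regularizer), the symmetric normalized Laplacian
#' `D^{-1/2} L D^{-1/2}` with the convention that zero-degree nodes get a zero
#' scaling entry. Entries of `S` must be nonnegative; clip negative combined
#' similarities (possible when cosine/correlation measures are combined) with
#' [clip_nonnegative()] first.
#'
#' @param S symmetric, elementwise-nonnegative similarity matrix (typically
#'   the sparsified combined similarity).
#' @param normalized use the symmetric normalized Laplacian?
#' @param p_used optional neighbor count recorded for provenance.
#' @return An object of class `dti_graph`: list with `similarity`, `degree`,
#'   `laplacian`, `normalized`, `p_used`.
#' @examples
#' g <- build_graph(matrix(c(0, 1, 1, 0), 2, 2), normalized = FALSE)
#' g$laplacian
#' @export
build_graph <- function(S, normalized = TRUE, p_used = NA_integer_) {
  check_symmetric(S, "S")
  if (min(S) < -1e-12) {
    stop_dtimc(
      "S has negative entries (min ", format(min(S)),
      "); clip with clip_nonnegative() before building the graph"
    )
  }
  deg <- rowSums(S)
  L <- diag(deg, nrow(S)) - S
  if (normalized) {
    inv_sqrt <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    L <- symmetrize(L * outer(inv_sqrt, inv_sqrt))
  }
  structure(
    list(
      similarity = S, degree = deg, laplacian = L,
      normalized = normalized, p_used = p_used
    ),
    class = "dti_graph"
  )
}

#' Clip negative similarity entries to zero
#'
#' Combined similarities can pick up negative entries from the cosine and
#' correlation measures; a graph Laplacian needs nonnegative edge weights to
#' be positive semidefinite, so negative entries are treated as absent edges.
#'
#' @param S similarity matrix.
#' @return `pmax(S, 0)` with symmetry preserved.
#' @export
clip_nonnegative <- function(S) symmetrize(pmax(S, 0))

#' @export
print.dti_graph <- function(x, ...) {
  cat(sprintf(
    "<dti_graph> %d nodes, %s Laplacian, mean degree %.3f\n",
    nrow(x$laplacian), if (x$normalized) "normalized" else "combinatorial",
    mean(x$degree)
  ))
  invisible(x)
}

#' Combined graph operators for both sides of a DTI dataset
#'
#' Full preprocessing path for one fit: compute the four interaction-profile
#' similarities from the (training) interaction matrix, combine all five
#' measures per side with `weights`, clip negative entries, sparsify with the
#' mutual p-nearest-neighbor mask, and build the (normalized) combined
#' Laplacians.
#'
#' @param ds a [dti_dataset()] supplying the standard similarities.
#' @param X_train interaction matrix to derive profile similarities from;
#'   defaults to `ds$interactions`. Inside cross-validation pass the training
#'   matrix (held-out entries zeroed).
#' @param p neighborhood size for [sparsify_pnn()]; `NULL` skips
#'   sparsification. Capped per side at one less than the number of nodes, so
#'   small networks degrade gracefully to the full neighborhood.
#' @param weights per-measure weights, see [default_similarity_weights()].
#' @param normalized use normalized Laplacians?
#' @return List with elements `drug` and `target`, each a `dti_graph`.
#' @export
dti_graphs <- function(ds, X_train = ds$interactions, p = 5,
                       weights = default_similarity_weights(),
                       normalized = TRUE) {
  stopifnot(inherits(ds, "dti_dataset"))
  build_side <- function(side, standard) {
    bundle <- similarity_bundle(X_train, standard, side, weights)
    S <- clip_nonnegative(combine_similarities(bundle))
    p_side <- if (is.null(p)) NULL else min(p, nrow(S) - 1L) # p capped at k-1
    if (!is.null(p_side)) S <- sparsify_pnn(S, p_side)
    build_graph(S, normalized = normalized,
                p_used = if (is.null(p_side)) NA_integer_ else as.integer(p_side))
  }
  list(
    drug = build_side("drug", ds$chem_similarity),
    target = build_side("target", ds$seq_similarity)
  )
}
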