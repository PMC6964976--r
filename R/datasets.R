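
# DTI dataset container, Yamanishi-dialect I/O, synthetic generator ------

#' Construct a drug-target interaction dataset
#'
#' Bundles a binary drug-target interaction matrix (rows = drugs, columns =
#' targets) with the two side-information similarity matrices: chemical
#' structure similarity between drugs and genomic sequence similarity between
#' targets. All invariants (binary interactions, symmetric similarities with
#' unit diagonal, consistent shapes) are enforced at construction.
#'
#' @param interactions numeric matrix in \{0,1\}, drugs in rows, targets in
#'   columns. Row/column names are used as drug/target identifiers; default
#'   identifiers are generated when absent.
#' @param chem_similarity square symmetric drug-drug similarity matrix with
#'   values in \[0,1\] and unit diagonal.
#' @param seq_similarity square symmetric target-target similarity matrix with
#'   values in \[0,1\] and unit diagonal.
#' @return An object of class `dti_dataset`: a list with elements `drug_ids`,
#'   `target_ids`, `interactions`, `chem_similarity`, `seq_similarity`.
#' @examples
#' ds <- dti_dataset(matrix(c(1, 0, 0, 1), 2, 2), diag(2), diag(2))
#' dataset_stats(ds)
#' @export
dti_dataset <- function(interactions, chem_similarity, seq_similarity) {
  check_binary_matrix(interactions, "interactions")
  n <- nrow(interactions)
  m <- ncol(interactions)
  if (is.null(rownames(interactions))) {
    rownames(interactions) <- sprintf("drug%03d", seq_len(n))
  }
  if (is.null(colnames(interactions))) {
    colnames(interactions) <- sprintf("target%03d", seq_len(m))
  }
  check_similarity_side(chem_similarity, n, "chem_similarity", "drug")
  check_similarity_side(seq_similarity, m, "seq_similarity", "target")
  dimnames(chem_similarity) <- list(rownames(interactions), rownames(interactions))
  dimnames(seq_similarity) <- list(colnames(interactions), colnames(interactions))
  structure(
    list(
      drug_ids = rownames(interactions),
      target_ids = colnames(interactions),
      interactions = interactions,
      chem_similarity = chem_similarity,
      seq_similarity = seq_similarity
    ),
    class = "dti_dataset"
  )
}

check_similarity_side <- function(S, k, name, side) {
  if (!is.matrix(S) || !is.numeric(S)) stop_dtimc(name, " must be a numeric matrix")
  if (nrow(S) != k || ncol(S) != k) {
    stop_dtimc(
      name, " must be ", k, "x", k, " to match the number of ", side,
      "s, got ", nrow(S), "x", ncol(S),
      class = "dtimc_shape_error"
    )
  }
  check_symmetric(S, name)
  if (min(S) < -1e-10 || max(S) > 1 + 1e-10) {
    stop_dtimc(name, " values must lie in [0, 1]")
  }
  if (max(abs(diag(S) - 1)) > 1e-10) {
    stop_dtimc(name, " must have unit diagonal")
  }
  invisible(S)
}

#' @export
print.dti_dataset <- function(x, ...) {
  s <- dataset_stats(x)
  cat(sprintf(
    "<dti_dataset> %d drugs x %d targets, %d interactions (density %.4f)\n",
    s$n_drugs, s$n_targets, s$n_interactions, s$sparsity
  ))
  invisible(x)
}

#' Summary statistics of a DTI dataset
#'
#' @param ds a [dti_dataset()].
#' @return A one-row tibble with `n_drugs`, `n_targets`, `n_interactions`
#'   (number of 1 entries) and `sparsity` (fraction of pairs that interact).
#' @examples
#' ds <- dti_dataset(matrix(0, 3, 4), diag(3), diag(4))
#' dataset_stats(ds)
#' @export
dataset_stats <- function(ds) {
  stopifnot(inherits(ds, "dti_dataset"))
  tibble::tibble(
    n_drugs = nrow(ds$interactions),
    n_targets = ncol(ds$interactions),
    n_interactions = as.integer(sum(ds$interactions)),
    sparsity = sum(ds$interactions) / length(ds$interactions)
  )
}

# Yamanishi gold-standard dialect: tab-delimited numeric matrix, one header
# row of column identifiers, one leading column of row identifiers. The
# distributed interaction files store targets as rows; we transpose on load so
# rows = drugs everywhere (the drug Laplacian acts on rows of X).

read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_dtimc("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  M <- as.matrix(df)
  storage.mode(M) <- "double"
  M
}

#' Read a DTI dataset in the Yamanishi gold-standard format
#'
#' Reads three tab-delimited matrix files (header row of column identifiers,
#' leading column of row identifiers): the binary interaction matrix stored
#' with targets as rows and drugs as columns (transposed on load so rows =
#' drugs internally), the drug-drug chemical structure similarity, and the
#' target-target sequence similarity. Rows/columns of the similarity matrices
#' are matched to the interaction matrix by identifier, not by position.
#'
#' @param interaction_file,drug_sim_file,target_sim_file file paths.
#' @return A [dti_dataset()].
#' @export
read_dti <- function(interaction_file, drug_sim_file, target_sim_file) {
  inter_tx <- read_matrix_tsv(interaction_file) # targets x drugs on disk
  X <- t(inter_tx)                              # drugs x targets
  check_binary_matrix(X, "interaction matrix")
  Sd <- read_matrix_tsv(drug_sim_file)
  St <- read_matrix_tsv(target_sim_file)
  Sd <- match_similarity(Sd, rownames(X), "drug similarity", "drug")
  St <- match_similarity(St, colnames(X), "target similarity", "target")
  dti_dataset(X, Sd, St)
}

match_similarity <- function(S, ids, name, side) {
  if (nrow(S) != length(ids)) {
    stop_dtimc(
      name, " has ", nrow(S), " rows but the interaction matrix has ",
      length(ids), " ", side, "s",
      class = "dtimc_shape_error"
    )
  }
  missing_ids <- setdiff(ids, rownames(S))
  if (length(missing_ids) > 0) {
    stop_dtimc(
      name, " is missing identifiers: ",
      paste(head(missing_ids, 5), collapse = ", "),
      class = "dtimc_id_error"
    )
  }
  S[ids, ids, drop = FALSE]
}

#' Write a DTI dataset in the Yamanishi gold-standard format
#'
#' Inverse of [read_dti()]: the interaction matrix is written with targets as
#' rows, similarities as square identifier-labelled matrices. Numbers are
#' written with full precision so that a read/write cycle round-trips exactly.
#'
#' @param ds a [dti_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix, default `"dti"`.
#' @return Invisibly, a named character vector of the three paths written.
#' @export
write_dti <- function(ds, dir, prefix = "dti") {
  stopifnot(inherits(ds, "dti_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    interactions = file.path(dir, paste0(prefix, "_admat.txt")),
    drug_sim = file.path(dir, paste0(prefix, "_simmat_drugs.txt")),
    target_sim = file.path(dir, paste0(prefix, "_simmat_targets.txt"))
  )
  write_matrix_tsv(t(ds$interactions), paths[["interactions"]])
  write_matrix_tsv(ds$chem_similarity, paths[["drug_sim"]])
  write_matrix_tsv(ds$seq_similarity, paths[["target_sim"]])
  invisible(paths)
}

write_matrix_tsv <- function(M, path) {
  # %.17g keeps every double bit-exact across a write/read cycle
  chars <- matrix(sprintf("%.17g", M), nrow(M), ncol(M))
  lines <- c(
    paste(c("", colnames(M)), collapse = "\t"),
    vapply(seq_len(nrow(M)), function(i) {
      paste(c(rownames(M)[i], chars[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
}

#' Generate a graph-consistent synthetic DTI dataset
#'
#' Simulates an interaction network with the statistical structure that
#' low-rank completion with graph regularization exploits: drugs and targets
#' carry positive latent factors drawn around cluster centroids, the noiseless
#' interaction propensity is the scaled latent inner product (so its matrix
#' rank equals `latent_rank` exactly), interactions are the top
#' `round(interaction_density * n * m)` propensities, and observed labels are
#' then flipped independently with probability `label_flip_rate`. The side
#' similarity matrices are a positive monotone transform of the latent-factor
#' cosine similarity, so the drug/target graphs are informative about the
#' low-rank signal.
#'
#' Latent factors are log-normal around per-cluster centroids:
#' `u_i = c_k * exp(noise_sd * z)`, keeping all factors positive.
#'
#' @param n_drugs,n_targets dimensions of the interaction matrix.
#' @param latent_rank rank of the noiseless propensity matrix; must not exceed
#'   `min(n_drugs, n_targets)`.
#' @param n_drug_clusters,n_target_clusters number of latent clusters per side.
#' @param interaction_density fraction of pairs labelled 1 before flips,
#'   in (0, 1).
#' @param label_flip_rate independent label flip probability, in \[0, 0.5).
#' @param seed integer seed; the output is a deterministic function of the
#'   arguments.
#' @param noise_sd standard deviation of the multiplicative log-normal noise
#'   around cluster centroids (dimensionless; smaller values give tighter
#'   clusters and more informative similarity graphs).
#' @return A list of class `dti_sim` with elements `dataset` (a
#'   [dti_dataset()]), `prob` (the noiseless propensity matrix, rank
#'   `latent_rank`, values in (0, 1\]), `clean_interactions` (labels before
#'   flipping), `drug_factors`, `target_factors`, and `diagnostics` (a tibble
#'   flagging all-zero drug/target profiles).
#' @examples
#' sim <- simulate_dti(n_drugs = 20, n_targets = 10, latent_rank = 2, seed = 1)
#' dataset_stats(sim$dataset)
#' @export
simulate_dti <- function(n_drugs = 60, n_targets = 30, latent_rank = 3,
                         n_drug_clusters = 6, n_target_clusters = 5,
                         interaction_density = 0.15, label_flip_rate = 0.05,
                         seed = 1L, noise_sd = 0.25) {
  check_count(n_drugs, "n_drugs")
  check_count(n_targets, "n_targets")
  check_count(latent_rank, "latent_rank")
  check_count(n_drug_clusters, "n_drug_clusters")
  check_count(n_target_clusters, "n_target_clusters")
  if (latent_rank > min(n_drugs, n_targets)) {
    stop_dtimc("latent_rank must be <= min(n_drugs, n_targets)")
  }
  if (interaction_density <= 0 || interaction_density >= 1) {
    stop_dtimc("interaction_density must be in (0, 1)")
  }
  if (label_flip_rate < 0 || label_flip_rate >= 0.5) {
    stop_dtimc("label_flip_rate must be in [0, 0.5)")
  }

  withr::with_seed(as.integer(seed), {
    U <- latent_factors(n_drugs, latent_rank, n_drug_clusters, noise_sd)
    V <- latent_factors(n_targets, latent_rank, n_target_clusters, noise_sd)
    G <- U %*% t(V)              # positive, rank = latent_rank
    P <- G / max(G)              # monotone squashing into (0, 1]

    k_ones <- round(interaction_density * n_drugs * n_targets)
    Y <- matrix(0, n_drugs, n_targets)
    Y[order(P, decreasing = TRUE)[seq_len(k_ones)]] <- 1
    clean <- Y
    if (label_flip_rate > 0) {
      flip <- matrix(runif(n_drugs * n_targets) < label_flip_rate,
                     n_drugs, n_targets)
      Y[flip] <- 1 - Y[flip]
    }

    Sd <- latent_cosine_similarity(U)
    St <- latent_cosine_similarity(V)

    rownames(Y) <- sprintf("D%05d", seq_len(n_drugs))
    colnames(Y) <- sprintf("T%05d", seq_len(n_targets))
    ds <- dti_dataset(Y, Sd, St)
    dimnames(P) <- dimnames(clean) <- dimnames(Y)

    diagnostics <- tibble::tibble(
      side = c(
        rep("drug", sum(rowSums(Y) == 0)),
        rep("target", sum(colSums(Y) == 0))
      ),
      id = c(
        rownames(Y)[rowSums(Y) == 0],
        colnames(Y)[colSums(Y) == 0]
      ),
      issue = "all-zero interaction profile"
    )

    structure(
      list(
        dataset = ds, prob = P, clean_interactions = clean,
        drug_factors = U, target_factors = V, diagnostics = diagnostics
      ),
      class = "dti_sim"
    )
  })
}

latent_factors <- function(n, rank, n_clusters, noise_sd) {
  centroids <- matrix(runif(n_clusters * rank, 0.2, 1.8), n_clusters, rank)
  members <- sample(rep_len(seq_len(n_clusters), n))
  centroids[members, , drop = FALSE] *
    exp(matrix(rnorm(n * rank, sd = noise_sd), n, rank))
}

# (1 + cosine)/2 of latent rows: symmetric, unit diagonal, in [0,1]
latent_cosine_similarity <- function(U) {
  nrm <- sqrt(rowSums(U^2))
  C <- (U %*% t(U)) / outer(nrm, nrm)
  S <- (1 + C) / 2
  S <- symmetrize(pmin(pmax(S, 0), 1))
  diag(S) <- 1
  S
}

#' @export
print.dti_sim <- function(x, ...) {
  print(x$dataset)
  cat(sprintf(
    "  latent rank %d; %d flagged empty profiles\n",
    qr(x$prob)$rank, nrow(x$diagnostics)
  ))
  invisible(x)
}
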