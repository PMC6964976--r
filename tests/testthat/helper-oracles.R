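# Independent reference implementations used as test oracles. These are
# deliberately naive (double loops, full Kronecker systems, step-curve
# enumeration) and share no code with the package internals.

ref_pair_similarity <- function(a, b, kind) {
  n <- length(a)
  switch(kind,
    cosine = {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
    },
    correlation = {
      if (sd(a) == 0 || sd(b) == 0) {
        if (identical(a, b)) 1 else 0 # degenerate; diag convention elsewhere
      } else {
        sum((a - mean(a)) * (b - mean(b))) /
          sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
      }
    },
    hamming = 1 - sum(a != b) / n,
    jaccard = {
      support <- which(a != 0 | b != 0)
      if (length(support) == 0) 0 else sum(a[support] == b[support]) / length(support)
    }
  )
}

ref_similarity <- function(X, side, kind) {
  P <- if (side == "drug") X else t(X)
  k <- nrow(P)
  S <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (kind == "correlation" && i == j && sd(P[i, ]) == 0) {
        S[i, j] <- 0 # constant profile: no self-correlation evidence
      } else if (kind == "correlation" && (sd(P[i, ]) == 0 || sd(P[j, ]) == 0)) {
        S[i, j] <- 0
      } else {
        S[i, j] <- ref_pair_similarity(P[i, ], P[j, ], kind)
      }
    }
  }
  S
}

# AUPR by explicit walk down the ranked list (ties: negatives first)
ref_aupr <- function(scores, labels) {
  ord <- order(-scores, labels)
  y <- labels[ord]
  tp <- 0
  total <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) {
      tp <- tp + 1
      total <- total + tp / i
    }
  }
  total / sum(labels)
}

# AUC by all (positive, negative) pair comparison, ties counted 1/2
ref_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Sylvester solve via full Kronecker vectorization
ref_sylvester <- function(C, L, nu, mu) {
  k <- nrow(C)
  l <- ncol(C)
  K <- nu * diag(k * l) + mu * kronecker(L, diag(k))
  matrix(solve(K, nu * as.vector(C)), k, l)
}

# random symmetric nonnegative similarity with unit diagonal
random_similarity <- function(k) {
  S <- matrix(runif(k * k), k, k)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

random_binary <- function(n, m, density = 0.3) {
  matrix(as.numeric(runif(n * m) < density), n, m)
}

# small graph-consistent dataset for solver tests
small_sim <- function(seed = 1, n = 20, m = 12) {
  simulate_dti(
    n_drugs = n, n_targets = m, latent_rank = 2,
    n_drug_clusters = 3, n_target_clusters = 3,
    interaction_density = 0.2, label_flip_rate = 0, seed = seed
  )
}

# hold-out mask over random pairs
random_mask <- function(n, m, frac_missing, seed) {
  A <- matrix(1, n, m)
  withr::with_seed(seed, {
    A[sample(n * m, round(frac_missing * n * m))] <- 0
  })
  A
}
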