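# Multi-graph regularized solver: Sylvester updates, objective, ADMM loop

test_that("solve_sylvester handles the degenerate cases", {
  C <- matrix(rnorm(12), 4, 3)
  L <- {
    S <- random_similarity(3)
    diag(S) <- 0
    diag(rowSums(S)) - S
  }
  expect_equal(solve_sylvester(C, L, nu = 2, mu = 0), C)
  expect_equal(solve_sylvester(C, matrix(0, 3, 3), nu = 1, mu = 5), C)
  expect_error(solve_sylvester(C, matrix(rnorm(9), 3, 3), 1, 1), "symmetric")
  expect_error(solve_sylvester(C, L[1:2, 1:2], 1, 1),
               class = "dtimc_shape_error")
})

test_that("closed-form Sylvester solution matches the Kronecker system", {
  withr::with_seed(13, {
    for (rep in 1:100) {
      k <- sample(2:20, 1)
      l <- sample(2:20, 1)
      C <- matrix(rnorm(k * l), k, l)
      S <- random_similarity(l)
      diag(S) <- 0
      L <- diag(rowSums(S), l) - S
      nu <- runif(1, 0.2, 3)
      mu <- runif(1, 0, 2)
      T1 <- solve_sylvester(C, L, nu, mu)
      expect_lt(max(abs(T1 - ref_sylvester(C, L, nu, mu))), 1e-10)
      resid <- sqrt(sum((nu * T1 + mu * T1 %*% L - nu * C)^2))
      expect_lte(resid, 1e-10 * sqrt(sum(C^2)))
    }
  })
})

test_that("objective matches an independent term-by-term computation", {
  # all-ones 2x2 instance with unit parameters
  M <- matrix(1, 2, 2)
  X <- Y <- matrix(1, 2, 2)
  Z <- t(X)
  pr <- masked_problem(M)
  gd <- build_graph(matrix(c(0, 1, 1, 0), 2, 2), normalized = FALSE)
  gt <- build_graph(matrix(c(0, 0.5, 0.5, 0), 2, 2), normalized = FALSE)
  par <- mgnnm_params(lam = 1, mu1 = 1, mu2 = 1, nu1 = 1, nu2 = 1)
  # residual 0; ||X||_* = 2 (singular values 2, 0); trace terms by hand;
  # coupling terms 0
  tr_d <- sum(diag(Z %*% gd$laplacian %*% t(Z)))
  tr_t <- sum(diag(Y %*% gt$laplacian %*% t(Y)))
  expect_equal(tr_d, 0) # constant rows are in the Laplacian null space
  expect_equal(tr_t, 0)
  expect_equal(mgnnm_objective(X, Y, Z, pr, gd, gt, par), 2)

  # zero everything -> zero objective
  z <- matrix(0, 2, 2)
  expect_equal(
    mgnnm_objective(z, z, t(z), masked_problem(z), gd, gt, par), 0
  )

  # mu = nu = 0 except the data terms reduces to the plain objective
  withr::with_seed(14, {
    Xr <- matrix(runif(4), 2, 2)
    Yr <- matrix(runif(4), 2, 2)
    Zr <- matrix(runif(4), 2, 2)
    Mr <- random_binary(2, 2)
    par0 <- mgnnm_params(lam = 0.7, mu1 = 0, mu2 = 0, nu1 = 1e-12,
                         nu2 = 1e-12)
    plain <- sum((Mr - Xr)^2) + 0.7 * sum(svd(Xr)$d)
    expect_equal(
      mgnnm_objective(Xr, Yr, Zr, masked_problem(Mr), gd, gt, par0),
      plain,
      tolerance = 1e-8
    )
  })

  # general random instance against naive summation
  withr::with_seed(15, {
    Xr <- matrix(rnorm(6), 2, 3)
    Yr <- matrix(rnorm(6), 2, 3)
    Zr <- matrix(rnorm(6), 3, 2)
    A <- random_binary(2, 3, 0.6)
    Mr <- random_binary(2, 3) * A
    gd2 <- build_graph(random_similarity(2), normalized = FALSE)
    gt2 <- build_graph(random_similarity(3), normalized = FALSE)
    par2 <- mgnnm_params(lam = 0.3, mu1 = 0.4, mu2 = 0.6, nu1 = 1.1,
                         nu2 = 0.9)
    manual <- sum((A * (Mr - Xr))^2) + 0.3 * sum(svd(Xr)$d) +
      0.4 * sum(diag(Zr %*% gd2$laplacian %*% t(Zr))) +
      0.6 * sum(diag(Yr %*% gt2$laplacian %*% t(Yr))) +
      1.1 * sum((t(Zr) - Xr)^2) + 0.9 * sum((Yr - Xr)^2)
    expect_equal(mgnnm_objective(Xr, Yr, Zr, masked_problem(Mr, A), gd2, gt2,
                                 par2), manual)
  })
})

test_that("X-update closed forms hold when lam = 0", {
  withr::with_seed(16, {
    n <- 5
    m <- 4
    Y <- matrix(runif(n * m), n, m)
    Z <- matrix(runif(n * m), m, n)
    M <- random_binary(n, m)

    # empty mask, nu1 = nu2 = 1: X = (t(Z) + Y) / 2
    res <- dtimc:::svs_core(M, matrix(0, n, m), 0,
      aux = list(list(T = t(Z), w = 1), list(T = Y, w = 1)),
      max_iter = 2000, tol = 1e-14, nonneg = FALSE
    )
    expect_lt(max(abs(res$X - (t(Z) + Y) / 2)), 1e-6)

    # full mask: X = (M + t(Z) + Y) / 3
    res2 <- dtimc:::svs_core(M, matrix(1, n, m), 0,
      aux = list(list(T = t(Z), w = 1), list(T = Y, w = 1)),
      max_iter = 2000, tol = 1e-14, nonneg = FALSE
    )
    expect_lt(max(abs(res2$X - (M + t(Z) + Y) / 3)), 1e-6)
  })
})

test_that("with mu1 = mu2 = 0 the fit reduces to plain nuclear norm completion", {
  withr::with_seed(17, {
    for (rep in 1:3) {
      sim <- small_sim(seed = rep, n = 15, m = 10)
      ds <- sim$dataset
      A <- random_mask(15, 10, 0.3, seed = rep)
      pr <- masked_problem(ds$interactions * A, A)
      g <- dti_graphs(ds, X_train = ds$interactions * A, p = 4)
      par <- mgnnm_params(
        lam = 1, mu1 = 0, mu2 = 0, tol = 1e-12, inner_tol = 1e-12,
        max_iter = 2000, inner_max_iter = 200, nonneg = FALSE
      )
      fit <- mgnnm_fit(pr, g$drug, g$target, par)
      ref <- svs_complete(pr, lam = 1, tol = 1e-13, max_iter = 50000,
                          nonneg = FALSE)
      rel <- sqrt(sum((fit$X - ref$X)^2)) / max(sqrt(sum(ref$X^2)), 1e-12)
      expect_lt(rel, 1e-4)
    }
  })
})

test_that("objective history is non-increasing across outer iterations", {
  withr::with_seed(18, {
    for (rep in 1:10) {
      sim <- small_sim(seed = 100 + rep, n = 12, m = 9)
      ds <- sim$dataset
      A <- random_mask(12, 9, 0.3, seed = rep)
      fit <- fit_dti(ds, mgnnm_params(max_iter = 80), mask = A)
      o <- fit$objective
      expect_true(all(diff(o) <= 1e-8 * pmax(abs(o[-length(o)]), 1)),
                  label = sprintf("monotone objective, rep %d", rep))
    }
  })
})

test_that("fit converges on a nuclear-receptor-sized problem", {
  sim <- simulate_dti(n_drugs = 54, n_targets = 26, latent_rank = 3,
                      seed = 1)
  A <- random_mask(54, 26, 0.3, seed = 1)
  fit <- fit_dti(sim$dataset, mgnnm_params(max_iter = 500), mask = A)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 500)
})

test_that("swapping drug and target roles transposes the solution", {
  sim <- small_sim(seed = 19, n = 10, m = 7)
  ds <- sim$dataset
  A <- random_mask(10, 7, 0.25, seed = 19)
  pr <- masked_problem(ds$interactions * A, A)
  g <- dti_graphs(ds, X_train = ds$interactions * A, p = 3)
  par <- mgnnm_params(lam = 0.8, mu1 = 0.4, mu2 = 0.2, nu1 = 1.5, nu2 = 0.7)
  fit <- mgnnm_fit(pr, g$drug, g$target, par)

  pr_t <- masked_problem(t(ds$interactions * A), t(A))
  par_t <- mgnnm_params(lam = 0.8, mu1 = 0.2, mu2 = 0.4, nu1 = 0.7, nu2 = 1.5)
  fit_t <- mgnnm_fit(pr_t, g$target, g$drug, par_t)
  expect_equal(fit_t$X, t(fit$X), tolerance = 1e-10)
})

test_that("graph and problem shapes must agree", {
  pr <- masked_problem(matrix(0, 4, 3))
  g4 <- build_graph(random_similarity(4))
  g3 <- build_graph(random_similarity(3))
  expect_error(mgnnm_fit(pr, g3, g3, mgnnm_params()),
               class = "dtimc_shape_error")
  expect_error(mgnnm_fit(pr, g4, g4, mgnnm_params()),
               class = "dtimc_shape_error")
  expect_s3_class(mgnnm_fit(pr, g4, g3, mgnnm_params(max_iter = 2)),
                  "mgnnm_fit")
})

test_that("predictions are finite scores that rank observed interactions high", {
  sim <- small_sim(seed = 20)
  fit <- fit_dti(sim$dataset, mgnnm_params(max_iter = 100))
  scores <- predict(fit)
  expect_true(all(is.finite(scores)))
  expect_identical(dim(scores), dim(sim$dataset$interactions))
  ones <- scores[sim$dataset$interactions == 1]
  expect_gt(mean(ones), mean(scores))
  td <- tidy(fit)
  expect_equal(nrow(td), length(scores))
})

test_that("parameter constraints are validated", {
  expect_error(mgnnm_params(lam = -1), "lam")
  expect_error(mgnnm_params(mu1 = -0.1), "mu1")
  expect_error(mgnnm_params(nu1 = 0), "nu1")
  expect_s3_class(mgnnm_params(mu1 = 0, mu2 = 0), "mgnnm_params")
})
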