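
# shared argument checks -------------------------------------------------

stop_dtimc <- function(..., class = "dtimc_error") {
  rlang::abort(paste0(...), class = class)
}

check_binary_matrix <- function(X, name = "X") {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop_dtimc(name, " must be a numeric matrix")
  }
  if (anyNA(X) || !all(X %in% c(0, 1))) {
    bad <- which(!(X %in% c(0, 1)))[1]
    stop_dtimc(
      name, " must contain only 0 and 1 (entry ", bad,
      " is ", format(X[bad]), ")",
      class = "dtimc_nonbinary_error"
    )
  }
  invisible(X)
}

check_symmetric <- function(S, name = "S", tol = 1e-10) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop_dtimc(name, " must be a square matrix")
  }
  if (max(abs(S - t(S))) > tol) {
    stop_dtimc(name, " must be symmetric (max asymmetry ",
               format(max(abs(S - t(S)))), ")")
  }
  invisible(S)
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_dtimc(name, " must be a single number")
  }
  if (strict && x <= lower) stop_dtimc(name, " must be > ", lower)
  if (!strict && x < lower) stop_dtimc(name, " must be >= ", lower)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x)) {
    stop_dtimc(name, " must be a single integer")
  }
  if (x < lower) stop_dtimc(name, " must be >= ", lower)
  invisible(as.integer(x))
}

# symmetrize away floating point noise
symmetrize <- function(S) (S + t(S)) / 2

frob2 <- function(X) sum(X^2)

nuclear_norm <- function(X) sum(svd(X, nu = 0, nv = 0)$d)
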