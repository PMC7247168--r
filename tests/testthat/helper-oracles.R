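# Shared fixtures and independent oracles. Every oracle here is coded
# against the definition, not against the package's computational path.

withr_tempfile <- function() tempfile(fileext = ".csv")

# Small random spectra_set (no structure; for plumbing tests).
random_spectra <- function(n = 8, N = 5, seed = 1, wl = NULL) {
  wl <- wl %||% seq(780, by = 2, length.out = N)
  nirsel::with_seed(seed, {
    spectra_set(wl, matrix(rnorm(n * N), n, N), rnorm(n, 27, 4))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive leave-one-out refit of y ~ 1 + xi + xk.
naive_blr_loocv <- function(xi, xk, y) {
  n <- length(y)
  preds <- vapply(seq_len(n), function(j) {
    b <- qr.coef(qr(cbind(1, xi[-j], xk[-j])), y[-j])
    sum(c(1, xi[j], xk[j]) * b)
  }, numeric(1))
  sqrt(mean((preds - y)^2))
}

# Leave-one-out ordinary least squares (with intercept) via per-fold normal
# equations.
loo_ols_predict <- function(X, y) {
  vapply(seq_len(nrow(X)), function(j) {
    Xt <- cbind(1, X[-j, , drop = FALSE])
    b <- solve(crossprod(Xt), crossprod(Xt, y[-j]))
    drop(c(1, X[j, ]) %*% b)
  }, numeric(1))
}

# Random symmetric pair-score matrix with distinct finite off-diagonal
# entries (diagonal NaN), wrapped as a pair_score_matrix on an integer grid.
random_score_matrix <- function(N, seed) {
  nirsel::with_seed(seed, {
    S <- matrix(NaN, N, N)
    v <- runif(N * (N - 1) / 2)
    S[upper.tri(S)] <- v
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    pair_score_matrix(seq_len(N) * 2 + 778, S)
  })
}

# Brute-force periodic points of the functional graph i -> partner_index[i]:
# follow the arrows from every node until a repeat; nodes on the terminal
# cycle are periodic.
periodic_point_indices <- function(partner_index) {
  N <- length(partner_index)
  periodic <- logical(N)
  for (s in seq_len(N)) {
    seen <- integer(0)
    cur <- s
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      cur <- partner_index[cur]
    }
    cyc <- seen[which(seen == cur):length(seen)]
    periodic[cyc] <- TRUE
  }
  which(periodic)
}

# Iterate the image of a partner_map from the full grid, collecting the set
# sequence (used to check nesting/termination independently of run_opwc).
iterate_image <- function(map) {
  sets <- list(map$wavelengths)
  current <- map$wavelengths
  repeat {
    nxt <- project_partners(current, map)
    sets[[length(sets) + 1L]] <- nxt
    if (length(nxt) == length(current)) break
    current <- nxt
  }
  sets
}
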