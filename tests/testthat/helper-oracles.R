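# Independent oracles used by the test suite. These deliberately take
# different algorithmic routes than the package implementation.

# Exhaustive-enumeration betweenness: enumerate every simple path between
# every pair, find the shortest, split credit over ties.
bf_betweenness <- function(W, distance = "inv_abs", tie_tol = 1e-9) {
  p <- nrow(W)
  len <- matrix(Inf, p, p)
  nz <- abs(W) > 0
  len[nz] <- if (distance == "inv_abs") 1 / abs(W[nz]) else 1 - abs(W[nz])
  diag(len) <- Inf
  contrib <- numeric(p)
  all_paths <- function(u, t, visited, d) {
    if (u == t) return(list(list(path = visited, d = d)))
    out <- list()
    for (v in which(is.finite(len[u, ]))) {
      if (!(v %in% visited))
        out <- c(out, all_paths(v, t, c(visited, v), d + len[u, v]))
    }
    out
  }
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    ps <- all_paths(s, t, s, 0)
    if (length(ps) == 0) next
    ds <- vapply(ps, `[[`, numeric(1), "d")
    dmin <- min(ds)
    ks <- which(ds <= dmin + tie_tol * (1 + abs(dmin)))
    for (k in ks) {
      mid <- setdiff(ps[[k]]$path, c(s, t))
      contrib[mid] <- contrib[mid] + 1 / length(ks)
    }
  }
  contrib
}

# Proximal-gradient (ISTA) solver for the graphical lasso primal with
# unpenalized diagonal; a different algorithm family than the package's
# block coordinate descent.
ista_glasso <- function(S, lambda, tol = 1e-12, maxit = 100000) {
  p <- nrow(S)
  Theta <- diag(1 / diag(S))
  obj <- function(Th) {
    ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(Inf)
    -sum(log(ev)) + sum(S * Th) + lambda * sum(abs(Th[row(Th) != col(Th)]))
  }
  f_old <- obj(Theta)
  step <- 0.5
  for (it in seq_len(maxit)) {
    G <- S - solve(Theta)
    repeat {
      Z <- Theta - step * G
      Tn <- sign(Z) * pmax(abs(Z) - step * lambda, 0)
      diag(Tn) <- diag(Z)
      f_new <- obj(Tn)
      if (is.finite(f_new) && f_new <= f_old + 1e-16) break
      step <- step / 2
      if (step < 1e-14) return(Theta)
    }
    delta <- max(abs(Tn - Theta))
    Theta <- Tn
    if (f_old - f_new < tol && delta < 1e-9) break
    f_old <- f_new
    step <- min(step * 1.2, 1)
  }
  Theta
}

# Direct maximum-likelihood fit of the two-equation recursive path model by
# numerical optimization of the Gaussian log-likelihood (independent of the
# package's least-squares route; the model is just-identified so ML = OLS).
ml_path_oracle <- function(df, outcome = "hd7", age_main = TRUE) {
  zs <- function(x) if (length(unique(x)) <= 2) x else as.numeric(scale(x))
  g <- zs(df$gmv); ag <- zs(df$age); m <- zs(df$cognition)
  y <- zs(df[[outcome]]); sx <- df$sex; ed <- zs(df$education)
  Xm <- cbind(1, g, g * ag, if (age_main) ag, sx, ed)
  Xy <- cbind(1, m, g, if (age_main) ag, sx, ed)
  km <- ncol(Xm); ky <- ncol(Xy)
  nll <- function(par) {
    bm <- par[1:km]; by <- par[km + (1:ky)]
    sm <- exp(par[km + ky + 1]); sy <- exp(par[km + ky + 2])
    -sum(stats::dnorm(m, Xm %*% bm, sm, log = TRUE)) -
      sum(stats::dnorm(y, Xy %*% by, sy, log = TRUE))
  }
  fit <- stats::optim(c(rep(0, km + ky), 0, 0), nll, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-15))
  list(a = fit$par[2], a_int = fit$par[3],
       b = fit$par[km + 2], c_prime = fit$par[km + 3])
}

# Partial correlations from a covariance matrix via 2x2 conditional
# covariance blocks (regression characterization), independent of the
# precision-matrix identity.
pcor_by_conditioning <- function(Sigma) {
  p <- nrow(Sigma)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    rest <- setdiff(seq_len(p), c(i, j))
    C <- Sigma[c(i, j), c(i, j)] -
      Sigma[c(i, j), rest] %*% solve(Sigma[rest, rest], Sigma[rest, c(i, j)])
    W[i, j] <- W[j, i] <- C[1, 2] / sqrt(C[1, 1] * C[2, 2])
  }
  W
}

# Random symmetric weight matrix with zero diagonal for small-graph tests.
rand_weighted_graph <- function(p, density = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, p, p)
  ut <- upper.tri(W)
  on_edges <- ut & matrix(stats::runif(p * p) < density, p, p)
  W[on_edges] <- stats::runif(sum(on_edges), 0.05, 0.9) *
    sample(c(-1, 1), sum(on_edges), replace = TRUE)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}
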