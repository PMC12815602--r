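#' Graphical lasso at a fixed penalty
#'
#' Estimates a sparse Gaussian precision matrix by minimizing
#' `-logdet(Theta) + tr(S Theta) + lambda * sum_{i != j} |theta_ij|`
#' (off-diagonal penalty only; the diagonal is unpenalized) by block
#' coordinate descent. At `lambda = 0` the unpenalized maximum-likelihood
#' estimate `solve(S)` is returned.
#'
#' @param S Symmetric correlation (or covariance) matrix, positive
#'   semidefinite.
#' @param lambda Penalty, `>= 0`.
#' @param warm Optional warm-start covariance estimate (as returned in
#'   `$w_cov`) to speed up path fits.
#' @param maxit,tol Outer-loop iteration cap and convergence tolerance
#'   (average absolute change of the working covariance, relative to the
#'   average off-diagonal magnitude of `S`).
#' @return List with `theta` (SPD precision estimate), `w_cov` (its implied
#'   covariance), `kkt_residual` (`max_{i!=j} |s_ij - solve(theta)_ij|`,
#'   which must be `<= lambda` at the optimum), `iterations`, `lambda`.
#' @examples
#' S <- cor(matrix(rnorm(600), 100, 6))
#' fit <- fit_glasso(S, lambda = 0.1)
#' fit$kkt_residual <= 0.1 + 1e-4
#' @export
fit_glasso <- function(S, lambda, warm = NULL, maxit = 500, tol = 1e-9) {
  .check_symmetric(S, tol = 1e-8, what = "S")
  S <- (S + t(S)) / 2
  if (lambda < 0) stop(.bn_error("input", "lambda must be >= 0"))
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    stop(.bn_error("input",
      sprintf("S is not positive semidefinite (min eigenvalue %.3g)", ev_min)))
  p <- nrow(S)
  if (lambda == 0) {
    if (ev_min < 1e-12)
      stop(.bn_error("input", "S must be positive definite when lambda = 0"))
    theta <- chol2inv(chol(S))
    dimnames(theta) <- dimnames(S)
    return(list(theta = theta, w_cov = S, kkt_residual = 0,
                iterations = 0L, converged = TRUE, lambda = 0))
  }
  res <- .glasso_cd(S, lambda, warm_W = warm, maxit = maxit, tol = tol)
  theta <- res$theta
  dimnames(theta) <- dimnames(S)
  kkt <- max(abs(.offdiag(S - solve(theta))))
  if (!res$converged)
    stop(.bn_error("convergence",
      sprintf("graphical lasso did not converge in %d iterations (KKT residual %.3g)",
              maxit, kkt)))
  list(theta = theta, w_cov = res$w_cov, kkt_residual = kkt,
       iterations = res$iterations, converged = res$converged, lambda = lambda)
}

#' Extended Bayesian Information Criterion for a fitted precision matrix
#'
#' `EBIC = -2 * l(Theta; S, n) + E * log(n) + 4 * E * gamma * log(p)` with
#' Gaussian log-likelihood `l = (n/2) * (logdet(Theta) - tr(S Theta))` and
#' `E` the number of nonzero upper-triangle entries. `gamma = 0` recovers the
#' ordinary BIC; larger values penalize dense graphs more strongly.
#'
#' @param theta SPD precision estimate.
#' @param S Correlation matrix used in the fit.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param edge_tol Entries with absolute value at or below this count as zero.
#' @return The EBIC score, with attributes `"loglik"`, `"penalty"` and
#'   `"edges"` for logging.
#' @export
ebic_score <- function(theta, S, n, gamma = 0.5, edge_tol = 1e-8) {
  ok <- tryCatch({ R <- chol(theta); TRUE }, error = function(e) FALSE)
  if (!ok) stop(.bn_error("linalg", "theta is not positive definite"))
  p <- nrow(theta)
  ld <- 2 * sum(log(diag(chol(theta))))
  ll <- (n / 2) * (ld - sum(S * theta))
  E <- sum(abs(theta[upper.tri(theta)]) > edge_tol)
  penalty <- E * log(n) + 4 * E * gamma * log(p)
  structure(-2 * ll + penalty, loglik = ll, penalty = penalty, edges = E)
}

#' Maximum-likelihood precision estimate restricted to a fixed support
#'
#' Fits the Gaussian graphical model whose conditional-independence pattern
#' is given by `support` (logical or 0/1 symmetric matrix) by the
#' neighborhood-regression fixpoint (graphical lasso iterations with zero
#' penalty and the off-support entries clamped to zero). Used to score
#' candidate graphs on the penalty path: scoring the support-restricted MLE
#' rather than the shrunk estimate decouples edge selection from shrinkage.
#'
#' @param S Correlation matrix.
#' @param support Symmetric logical matrix of allowed off-diagonal entries.
#' @param maxit,tol Iteration cap and convergence tolerance.
#' @return The constrained MLE of the precision matrix.
#' @keywords internal
.support_mle <- function(S, support, maxit = 200, tol = 1e-9) {
  p <- nrow(S)
  W <- S
  Beta <- matrix(0, p, p)  # Beta[k, j]: coefficient of node k in column j
  soff <- mean(abs(.offdiag(S)))
  crit <- tol * max(soff, 1e-12)
  for (it in seq_len(maxit)) {
    maxdel <- 0
    for (j in seq_len(p)) {
      nb <- which(support[, j] & seq_len(p) != j)
      w12_new <- numeric(p - 1)
      idx <- setdiff(seq_len(p), j)
      if (length(nb) > 0) {
        b <- solve(W[nb, nb, drop = FALSE], S[nb, j])
        Beta[, j] <- 0; Beta[nb, j] <- b
        w12_new <- W[idx, nb, drop = FALSE] %*% b
      } else {
        Beta[, j] <- 0
      }
      maxdel <- max(maxdel, max(abs(W[idx, j] - w12_new)))
      W[idx, j] <- w12_new
      W[j, idx] <- w12_new
    }
    if (maxdel < crit) break
  }
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    tjj <- 1 / (W[j, j] - sum(W[idx, j] * Beta[idx, j]))
    theta[j, j] <- tjj
    theta[idx, j] <- -Beta[idx, j] * tjj
  }
  (theta + t(theta)) / 2
}

#' Estimate an EBIC-selected partial-correlation network
#'
#' Fits the graphical lasso along a descending log-spaced penalty path
#' (warm-started), scores every candidate graph on the path with the
#' Extended Bayesian Information Criterion, selects the penalty minimizing
#' it, and converts the selected precision matrix into a regularized
#' partial-correlation network. This is the standard sparsity-based
#' estimator used for cross-sectional symptom networks.
#'
#' By default each candidate graph is scored at its support-restricted
#' maximum-likelihood refit, so that the selection criterion judges the
#' graph itself rather than the amount of shrinkage at that penalty;
#' `refit_ebic = FALSE` scores the shrunk glasso estimates directly. The
#' reported edge weights are always the regularized partial correlations at
#' the selected penalty.
#'
#' @param x A `"preprocessed_matrix"` (see [preprocess()]) or a plain numeric
#'   data matrix (columns are nodes; it will be z-scored).
#' @param lambda_grid Optional penalty grid; defaults to `n_lambda`
#'   log-spaced values on `[lambda_max/lambda_min_ratio, lambda_max]` where
#'   `lambda_max` is the largest absolute off-diagonal correlation.
#' @param n_lambda,lambda_min_ratio Path resolution (defaults 100 points down
#'   to `lambda_max / 1000`).
#' @param gamma EBIC hyperparameter (default 0.5, the standard conservative
#'   choice).
#' @param domains Optional named vector mapping nodes to communities; default
#'   uses the canonical cognitive/depression/anxiety labels when the node
#'   names match, which downstream bridge centrality requires.
#' @param edge_tol Partial correlations with `|w| <= edge_tol` are zeroed.
#' @param refit_ebic Score candidate graphs at their support-restricted
#'   maximum-likelihood refit (default) rather than at the shrunk estimate.
#' @return A `"bridgenet_network"` object: `W` (symmetric partial-correlation
#'   matrix, zero diagonal), `theta`, `node_names`, `domains`,
#'   `lambda_selected`, `gamma`, `ebic_value`, `n`, `edge_count`, and `path`
#'   (a data frame with `lambda`, `ebic`, `edges` along the path).
#' @examples
#' spec <- synthetic_spec(n_per_group = c(young = 200, old = 200))
#' net <- ebic_glasso(preprocess(simulate_items(spec, "old")))
#' net
#' @export
ebic_glasso <- function(x, lambda_grid = NULL, n_lambda = 100,
                        lambda_min_ratio = 1/1000, gamma = 0.5,
                        domains = NULL, edge_tol = 1e-8, refit_ebic = TRUE) {
  if (inherits(x, "preprocessed_matrix")) {
    X <- x$values
  } else {
    X <- as.matrix(x)
    X <- .zscore(X)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n < 25)
    stop(.bn_error("insufficient_data",
      sprintf("need at least 25 observations for network estimation, got %d", n)))
  S <- stats::cor(X)
  lam_max <- max(abs(.offdiag(S)))
  if (is.null(lambda_grid)) {
    if (n_lambda < 10)
      stop(.bn_error("input", "lambda grid must have at least 10 values"))
    lambda_grid <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                           length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  fits <- vector("list", length(lambda_grid))
  ebics <- edges <- numeric(length(lambda_grid))
  warm <- NULL
  refit_cache <- new.env(parent = emptyenv())
  for (i in seq_along(lambda_grid)) {
    fits[[i]] <- fit_glasso(S, lambda_grid[i], warm = warm)
    warm <- fits[[i]]$w_cov
    theta_i <- fits[[i]]$theta
    supp <- abs(theta_i) > edge_tol; diag(supp) <- TRUE
    if (refit_ebic) {
      key <- paste0("s", paste(which(supp[upper.tri(supp)]), collapse = ","))
      if (is.null(refit_cache[[key]]))
        refit_cache[[key]] <- ebic_score(.support_mle(S, supp), S, n,
                                         gamma = gamma, edge_tol = edge_tol)
      sc <- refit_cache[[key]]
    } else {
      sc <- ebic_score(theta_i, S, n, gamma = gamma, edge_tol = edge_tol)
    }
    ebics[i] <- as.numeric(sc)
    edges[i] <- sum(supp[upper.tri(supp)])
  }
  best <- min(ebics)
  # among ties, keep the sparsest (largest lambda)
  sel <- which(ebics <= best + 1e-9)[1]
  if ((sel == 1 || sel == length(lambda_grid)) &&
      sum(ebics <= best + 1e-9) == 1)
    warning(sprintf("EBIC minimized at a boundary penalty (lambda = %.4g); consider widening the grid",
                    lambda_grid[sel]))

  theta <- fits[[sel]]$theta
  W <- partial_corr_from_precision(theta)
  W[abs(W) <= edge_tol] <- 0
  diag(W) <- 0
  nodes <- colnames(X) %||% paste0("V", seq_len(p))
  dimnames(W) <- list(nodes, nodes)
  if (is.null(domains)) {
    domains <- if (all(.analysis_nodes %in% nodes)) .node_domains(nodes)
               else stats::setNames(rep("all", p), nodes)
  }
  structure(list(node_names = nodes,
                 domains = domains,
                 W = W,
                 theta = theta,
                 lambda_selected = lambda_grid[sel],
                 gamma = gamma,
                 ebic_value = ebics[sel],
                 n = n,
                 edge_count = sum(abs(W[upper.tri(W)]) > edge_tol),
                 path = data.frame(lambda = lambda_grid, ebic = ebics,
                                   edges = edges)),
            class = "bridgenet_network")
}

#' @export
print.bridgenet_network <- function(x, ...) {
  cat(sprintf("<bridgenet_network> %d nodes, %d edges (n = %d)\n",
              length(x$node_names), x$edge_count, x$n))
  cat(sprintf("  lambda = %.4g (EBIC %.1f, gamma %.2g)\n",
              x$lambda_selected, x$ebic_value, x$gamma))
  invisible(x)
}

#' @export
summary.bridgenet_network <- function(object, ...) {
  ct <- centrality_table(object)
  cat(sprintf("EBIC-selected partial-correlation network (n = %d)\n", object$n))
  cat(sprintf("  %d nodes, %d edges, lambda = %.4g, gamma = %.2g\n",
              length(object$node_names), object$edge_count,
              object$lambda_selected, object$gamma))
  wts <- object$W[upper.tri(object$W)]
  wts <- wts[wts != 0]
  if (length(wts))
    cat(sprintf("  edge weights: %d positive, %d negative, |w| in [%.3f, %.3f]\n",
                sum(wts > 0), sum(wts < 0), min(abs(wts)), max(abs(wts))))
  cat("\nCentrality (top 5 by strength):\n")
  print(utils::head(ct[order(-ct$strength), ], 5), row.names = FALSE)
  invisible(ct)
}

#' @export
coef.bridgenet_network <- function(object, ...) object$W

#' Plot a partial-correlation network
#'
#' Basic circular-layout display: nodes colored by domain, edge width
#' proportional to `|w|`, solid for positive and dashed for negative weights.
#'
#' @param x A `"bridgenet_network"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bridgenet_network <- function(x, ...) {
  p <- length(x$node_names)
  ang <- seq(0, 2 * pi, length.out = p + 1)[seq_len(p)]
  xs <- cos(ang); ys <- sin(ang)
  graphics::plot(xs, ys, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), asp = 1, ...)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    w <- x$W[i, j]
    if (w == 0) next
    graphics::segments(xs[i], ys[i], xs[j], ys[j],
                       lwd = 0.5 + 6 * abs(w),
                       lty = if (w > 0) 1 else 2,
                       col = if (w > 0) "darkgreen" else "darkorange")
  }
  cols <- c(cognitive = "steelblue", depression = "firebrick",
            anxiety = "goldenrod", all = "grey40")
  graphics::points(xs, ys, pch = 21, cex = 2.2,
                   bg = cols[x$domains[x$node_names]])
  graphics::text(1.15 * xs, 1.15 * ys, x$node_names, cex = 0.7)
  invisible(x)
}

#' Serialize / deserialize a network as JSON
#'
#' The JSON object stores nodes, domains, selected penalty, EBIC value,
#' sample size and the weight matrix in row-major order, so a network can be
#' re-read without refitting.
#'
#' @param net A `"bridgenet_network"`.
#' @param path Output (input) file path.
#' @return `path` invisibly for the writer; the reconstructed network for
#'   the reader.
#' @export
write_network_json <- function(net, path) {
  obj <- list(nodes = net$node_names,
              domains = as.list(net$domains),
              lambda = net$lambda_selected,
              gamma = net$gamma,
              ebic = net$ebic_value,
              n = net$n,
              W = as.vector(t(net$W)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$nodes)
  W <- matrix(obj$W, p, p, byrow = TRUE,
              dimnames = list(obj$nodes, obj$nodes))
  structure(list(node_names = obj$nodes,
                 domains = unlist(obj$domains),
                 W = W, theta = NULL,
                 lambda_selected = obj$lambda, gamma = obj$gamma,
                 ebic_value = obj$ebic, n = obj$n,
                 edge_count = sum(abs(W[upper.tri(W)]) > 1e-8),
                 path = NULL),
            class = "bridgenet_network")
}

#' Edge list of a network
#'
#' @param net A `"bridgenet_network"`.
#' @return Data frame with columns `node_i`, `node_j`, `weight` for every
#'   nonzero upper-triangle edge.
#' @export
network_edges <- function(net) {
  idx <- which(upper.tri(net$W) & abs(net$W) > 1e-8, arr.ind = TRUE)
  data.frame(node_i = net$node_names[idx[, 1]],
             node_j = net$node_names[idx[, 2]],
             weight = net$W[idx])
}
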