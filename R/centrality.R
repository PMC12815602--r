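#' Strength centrality
#'
#' Sum of the absolute weights of all edges connected to each node.
#'
#' @param W Symmetric weighted adjacency matrix with zero diagonal.
#' @return Named numeric vector of per-node strengths.
#' @examples
#' W <- matrix(c(0, .5, -.3, .5, 0, 0, -.3, 0, 0), 3)
#' node_strength(W)
#' @export
node_strength <- function(W) {
  .check_symmetric(W)
  rowSums(abs(W))
}

# Dijkstra with tie-tolerant predecessor tracking; lengths in `len` (Inf for
# absent edges). Returns distances, shortest-path counts, predecessor lists
# and the settlement order required by the Brandes accumulation.
.dijkstra <- function(len, s, tie_tol) {
  p <- nrow(len)
  dist <- rep(Inf, p); dist[s] <- 0
  sigma <- numeric(p); sigma[s] <- 1
  preds <- vector("list", p)
  done <- logical(p)
  order_settled <- integer(0)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    order_settled <- c(order_settled, u)
    for (v in which(is.finite(len[u, ]))) {
      if (done[v]) next
      alt <- dist[u] + len[u, v]
      tol <- tie_tol * (1 + abs(alt))
      if (alt < dist[v] - tol) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (abs(alt - dist[v]) <= tol && !(u %in% preds[[v]])) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_settled)
}

#' Weighted betweenness centrality
#'
#' Counts, for every node, the fraction of weighted shortest paths between
#' pairs of other nodes that pass through it (Brandes accumulation; credit is
#' split equally among equal-length shortest paths, with a small relative
#' tolerance deciding length ties). Edge lengths are a decreasing transform
#' of the absolute edge weight: `1/|w|` by default, so strong associations
#' are short, or `1 - |w|`. Disconnected pairs contribute nothing and
#' isolated nodes are legal.
#'
#' @param W Symmetric weighted adjacency with zero diagonal.
#' @param distance Length transform: `"inv_abs"` (default) or
#'   `"one_minus_abs"`.
#' @param normalize Divide by `(p-1)(p-2)/2`, the number of ordered pairs an
#'   intermediary could serve in an undirected graph?
#' @param tie_tol Relative tolerance for treating two path lengths as equal.
#' @return Named numeric vector of betweenness values.
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- .4; W[2, 3] <- W[3, 2] <- .2
#' node_betweenness(W)  # middle node lies on the single A-C shortest path
#' @export
node_betweenness <- function(W, distance = c("inv_abs", "one_minus_abs"),
                             normalize = FALSE, tie_tol = 1e-10) {
  .check_symmetric(W)
  distance <- match.arg(distance)
  p <- nrow(W)
  len <- matrix(Inf, p, p)
  nz <- abs(W) > 0
  len[nz] <- switch(distance,
                    inv_abs = 1 / abs(W[nz]),
                    one_minus_abs = 1 - abs(W[nz]))
  if (distance == "one_minus_abs" && any(len[nz] <= 0))
    stop(.bn_error("input", "one_minus_abs distance requires |w| < 1"))
  diag(len) <- Inf
  bc <- numeric(p)
  for (s in seq_len(p)) {
    dj <- .dijkstra(len, s, tie_tol)
    delta <- numeric(p)
    for (w in rev(dj$order)) {
      for (v in dj$preds[[w]])
        delta[v] <- delta[v] + dj$sigma[v] / dj$sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # undirected: every pair visited from both endpoints
  if (normalize && p > 2) bc <- bc / ((p - 1) * (p - 2) / 2)
  names(bc) <- rownames(W)
  bc
}

#' Bridge expected influence (1-step)
#'
#' Signed sum of a node's edge weights to nodes in other pre-defined
#' communities: the portion of a node's expected influence that crosses
#' community boundaries. In cognitive--affective networks, cross-domain edges
#' are predominantly negative, so bridging symptoms typically show the most
#' negative values; rank by absolute value to identify bridges regardless of
#' sign.
#'
#' @param W Symmetric weighted adjacency with zero diagonal.
#' @param communities Named character vector mapping every node to a
#'   community label (at least two distinct labels).
#' @param two_step Also add, for each cross-community neighbor, the
#'   neighbor's own within-walk influence (2-step variant)? Default `FALSE`
#'   (1-step).
#' @return Named numeric vector of signed bridge-expected-influence values.
#' @examples
#' W <- matrix(0, 3, 3, dimnames = rep(list(c("a1", "a2", "b1")), 2))
#' W["a1", "a2"] <- W["a2", "a1"] <- .3
#' W["a1", "b1"] <- W["b1", "a1"] <- .2
#' bridge_expected_influence(W, c(a1 = "A", a2 = "A", b1 = "B"))
#' @export
bridge_expected_influence <- function(W, communities, two_step = FALSE) {
  .check_symmetric(W)
  nodes <- rownames(W) %||% paste0("V", seq_len(nrow(W)))
  rownames(W) <- colnames(W) <- nodes
  if (!all(nodes %in% names(communities)))
    stop(.bn_error("input",
      sprintf("unlabeled node(s): %s",
              paste(setdiff(nodes, names(communities)), collapse = ", "))))
  comm <- communities[nodes]
  if (length(unique(comm)) < 2)
    stop(.bn_error("input", "need at least 2 community labels"))
  cross <- outer(comm, comm, FUN = "!=")
  bei <- rowSums(W * cross)
  if (two_step) {
    ei1 <- rowSums(W)  # 1-step expected influence of each neighbor
    bei <- bei + as.vector((W * cross) %*% ei1)
  }
  names(bei) <- nodes
  bei
}

#' Centrality table for a network
#'
#' Computes strength, betweenness (raw and normalized) and bridge expected
#' influence for every node of a fitted network.
#'
#' @param x A `"bridgenet_network"`, or a symmetric weight matrix.
#' @param communities Node -> community labels for bridge expected influence;
#'   defaults to the network's domains.
#' @param distance Length transform passed to [node_betweenness()].
#' @return Data frame of class `"centrality_table"` with columns `node`,
#'   `domain`, `strength`, `betweenness`, `betweenness_normalized`, `bei`.
#' @examples
#' spec <- synthetic_spec(n_per_group = c(young = 120, old = 120))
#' ct <- centrality_table(ebic_glasso(preprocess(simulate_items(spec, "old"))))
#' ct[which.max(abs(ct$bei)), ]
#' @export
centrality_table <- function(x, communities = NULL,
                             distance = c("inv_abs", "one_minus_abs")) {
  distance <- match.arg(distance)
  if (inherits(x, "bridgenet_network")) {
    W <- x$W
    if (is.null(communities)) communities <- x$domains
  } else {
    W <- as.matrix(x)
    if (is.null(rownames(W)))
      rownames(W) <- colnames(W) <- paste0("V", seq_len(nrow(W)))
    if (is.null(communities)) communities <- .node_domains(rownames(W))
  }
  bt <- node_betweenness(W, distance = distance, normalize = FALSE)
  p <- nrow(W)
  out <- data.frame(node = rownames(W),
                    domain = unname(communities[rownames(W)]),
                    strength = unname(node_strength(W)),
                    betweenness = unname(bt),
                    betweenness_normalized = unname(bt / ((p - 1) * (p - 2) / 2)),
                    bei = unname(bridge_expected_influence(W, communities)),
                    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' @export
print.centrality_table <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y[sapply(y, is.numeric)] <- lapply(y[sapply(y, is.numeric)], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
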