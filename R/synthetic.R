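#' Build a block-structured sparse precision matrix with a planted bridge
#'
#' Constructs a symmetric positive-definite precision matrix whose implied
#' partial correlations equal the requested values at the specified entries
#' and are zero elsewhere. The sparsity pattern is: a chain of edges within
#' each block (domain) at partial correlation `within_pc`, optional bridge
#' edges from one node to a set of target nodes at `bridge$pc`, and any
#' `extra_edges`. Unit diagonal is used, so the implied partial correlation
#' matrix equals the requested pattern exactly; if the raw construction is
#' not positive definite, the diagonal is inflated by the smallest
#' `delta = 1e-4 * 2^k` achieving a minimum eigenvalue of at least
#' `min_eig`, which attenuates all partial correlations by `1/(1 + delta)`.
#' The attenuated values are then the stored ground truth.
#'
#' @param blocks Named integer vector of block sizes, e.g.
#'   `c(cognitive = 5, depression = 7, anxiety = 7)`.
#' @param within_pc Partial correlation on within-block chain edges.
#' @param bridge Optional `list(node =, targets =, pc =)` planting cross-block
#'   edges from `node` to each target.
#' @param extra_edges Optional data frame with columns `from`, `to`, `pc` for
#'   additional edges (names or indices).
#' @param node_names Optional node names; defaults to `<block><i>`.
#' @param min_eig Minimum eigenvalue demanded of the result.
#' @return The precision matrix, with attributes `"w_true"` (implied partial
#'   correlations after any inflation), `"delta"` (diagonal inflation used)
#'   and `"requested"` (the requested pattern).
#' @examples
#' th <- make_precision_matrix(c(a = 3, b = 3), within_pc = 0.3)
#' attr(th, "delta")
#' @export
make_precision_matrix <- function(blocks, within_pc = 0.35, bridge = NULL,
                                  extra_edges = NULL, node_names = NULL,
                                  min_eig = 1e-6) {
  p <- sum(blocks)
  if (is.null(node_names)) {
    node_names <- unlist(lapply(names(blocks), function(b)
      paste0(b, seq_len(blocks[[b]]))), use.names = FALSE)
  }
  stopifnot(length(node_names) == p)
  P <- matrix(0, p, p, dimnames = list(node_names, node_names))
  set_pc <- function(i, j, v) {
    if (is.character(i)) i <- match(i, node_names)
    if (is.character(j)) j <- match(j, node_names)
    if (anyNA(c(i, j))) stop(.bn_error("input", "unknown node name in edge spec"))
    if (abs(v) >= 0.6)
      stop(.bn_error("input",
        sprintf("requested partial correlation %g outside (-0.6, 0.6)", v)))
    P[i, j] <<- v; P[j, i] <<- v
  }
  offset <- 0L
  for (b in seq_along(blocks)) {
    sz <- blocks[[b]]
    if (sz > 1) for (k in seq_len(sz - 1))
      set_pc(offset + k, offset + k + 1L, within_pc)
    offset <- offset + sz
  }
  if (!is.null(bridge))
    for (t in bridge$targets) set_pc(bridge$node, t, bridge$pc)
  if (!is.null(extra_edges))
    for (r in seq_len(nrow(extra_edges)))
      set_pc(extra_edges$from[r], extra_edges$to[r], extra_edges$pc[r])

  theta <- diag(p) - P
  dimnames(theta) <- dimnames(P)
  delta <- 0
  ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  k <- 0
  while (ev < min_eig) {
    delta <- 1e-4 * 2^k
    if (delta > 1)
      stop(.bn_error("infeasible_spec",
        "requested partial-correlation pattern cannot be made SPD with delta <= 1"))
    ev <- min(eigen(theta + delta * diag(p), symmetric = TRUE,
                    only.values = TRUE)$values)
    k <- k + 1
  }
  if (delta > 0) theta <- theta + delta * diag(p)
  structure(theta,
            w_true = partial_corr_from_precision(theta),
            delta = delta,
            requested = P)
}

#' Partial correlations implied by a precision matrix
#'
#' Applies the Gaussian graphical-model identity
#' `w_ij = -theta_ij / sqrt(theta_ii * theta_jj)` to obtain the weighted
#' adjacency matrix of the partial-correlation network.
#'
#' @param theta A symmetric positive-definite precision matrix.
#' @return Symmetric matrix of partial correlations with zero diagonal.
#' @examples
#' partial_corr_from_precision(matrix(c(2, -0.5, -0.5, 2), 2))
#' @export
partial_corr_from_precision <- function(theta) {
  .check_symmetric(theta, tol = 1e-8, what = "theta")
  ok <- tryCatch({ chol(theta); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop(.bn_error("linalg", "precision matrix is not positive definite"))
  d <- 1 / sqrt(diag(theta))
  Th <- matrix(as.numeric(theta), nrow(theta))  # drop incidental attributes
  W <- -Th * tcrossprod(d)
  diag(W) <- 0
  dimnames(W) <- dimnames(theta)
  W
}

#' Define a synthetic study specification with known ground truth
#'
#' Bundles everything needed to generate item-level data that emulates a
#' two-group (young / older adults) cognitive--affective study: per-group
#' sparse precision matrices over the 19 analysis nodes (5 cognitive domains,
#' 7 depression items, 7 anxiety items) with a planted bridge node per group,
#' ordinal thresholds that zero-inflate the affective items, logistic
#' squashing targets for the cognitive proportions, and path coefficients for
#' the moderated-mediation generator.
#'
#' Default ground truth: heterogeneous positive within-domain edges
#' (partial correlations 0.22--0.42), identical across groups -- a chain plus
#' one chord over the cognitive domains, a chain plus one chord over the
#' depression items, and a ring plus one chord over the anxiety items -- so
#' that node strengths form a shared ladder across groups; one positive
#' depression--anxiety link `ha1`--`hd1` at `+0.32`; a planted bridge node --
#' `hd3` (dysphoria) in the young group, `hd7` (anhedonia) in the old group
#' -- with edges of `-0.28` to memory and fluency; a young-only positive
#' anxiety cross edge `ha3`--memory at `+0.28` (in the old group anxiety
#' reaches cognition only through the depressive items); ordinal thresholds
#' `(0.8, 1.6, 2.4)` on the unit-variance latent scale (about 79% zeros per
#' item); mediation paths `a = 0.142`, `a_int = 0.186`, `b = -0.147`,
#' `c_prime = 0.013` with a null mediation path (`b2 = 0`) for the second
#' outcome. The magnitudes are set above the scale typical of continuous
#' data because ordinal discretization attenuates observed associations; see
#' the package vignette for the full design rationale.
#'
#' @param n_per_group Named vector of group sizes (default
#'   `c(young = 756, old = 1230)`).
#' @param bridge_pc,bridge_targets,anxiety_cross_pc,affective_link_pc
#'   Ground-truth partial correlations of the planted cross-domain
#'   structure. `anxiety_cross_pc` applies to the young group only.
#' @param within_edges Optional data frame (`from`, `to`, `pc`) overriding
#'   the default within-domain edge pattern (shared by all groups).
#' @param bridge_node_by_group Named character vector mapping each group to
#'   its planted bridge node.
#' @param ordinal_thresholds Three strictly increasing cutpoints on the
#'   latent scale; the first must be `>= 0` so that item zero inflation is
#'   induced.
#' @param cognitive_targets Named list of per-group mean targets for the five
#'   cognitive proportions (logistic squashing locations).
#' @param cognitive_scale Slope of the latent-to-proportion logistic map.
#' @param mediation_params Named list of path coefficients for
#'   [simulate_mediation_data()]; missing entries take the defaults above.
#' @param seed Master seed recorded in the spec; group simulations derive
#'   their own seeds from it.
#' @return An object of class `"synthetic_spec"` with elements
#'   `theta_by_group`, `w_true_by_group`, `bridge_node_by_group`, `domains`,
#'   `node_names`, thresholds and mediation parameters.
#' @examples
#' spec <- synthetic_spec(n_per_group = c(young = 50, old = 50))
#' spec$bridge_node_by_group
#' @export
synthetic_spec <- function(n_per_group = c(young = 756, old = 1230),
                           bridge_pc = -0.28,
                           bridge_targets = c("memory", "fluency"),
                           anxiety_cross_pc = 0.28,
                           affective_link_pc = 0.32,
                           within_edges = NULL,
                           bridge_node_by_group = c(young = "hd3", old = "hd7"),
                           ordinal_thresholds = c(0.8, 1.6, 2.4),
                           cognitive_targets = NULL,
                           cognitive_scale = 0.7,
                           mediation_params = list(),
                           seed = 1L) {
  if (length(ordinal_thresholds) != 3 || any(diff(ordinal_thresholds) <= 0))
    stop(.bn_error("input", "ordinal_thresholds must be 3 strictly increasing values"))
  if (ordinal_thresholds[1] < 0)
    stop(.bn_error("input", "first ordinal threshold must be >= 0 (zero inflation)"))
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups)))
    stop(.bn_error("input", "n_per_group must be a named vector"))
  miss <- setdiff(groups, names(bridge_node_by_group))
  if (length(miss) > 0 && !all(miss %in% "middle"))
    stop(.bn_error("input",
      sprintf("no bridge node defined for group(s): %s", paste(miss, collapse = ", "))))

  if (is.null(cognitive_targets)) {
    cognitive_targets <- list(
      young  = c(memory = 0.93, fluency = 0.89, language = 0.94,
                 visuospatial = 0.98, orientation = 0.97),
      middle = c(memory = 0.88, fluency = 0.84, language = 0.93,
                 visuospatial = 0.95, orientation = 0.95),
      old    = c(memory = 0.82, fluency = 0.78, language = 0.92,
                 visuospatial = 0.91, orientation = 0.93))
  }
  mp <- utils::modifyList(list(a = 0.142, a_int = 0.186, b = -0.147,
                               c_prime = 0.013, b2 = 0, c_prime2 = -0.029,
                               age_main = -0.3, gamma_sex = 0.1,
                               gamma_edu = 0.1, error_sd = NULL), mediation_params)

  blocks <- c(cognitive = 5L, depression = 7L, anxiety = 7L)
  if (is.null(within_edges)) within_edges <- .default_within_edges()
  theta_by_group <- list()
  w_true_by_group <- list()
  for (g in groups) {
    bnode <- if (g %in% names(bridge_node_by_group)) bridge_node_by_group[[g]] else NA
    bridge <- if (!is.na(bnode))
      list(node = bnode, targets = bridge_targets, pc = bridge_pc) else NULL
    extra <- rbind(within_edges,
                   data.frame(from = "ha1", to = "hd1", pc = affective_link_pc))
    if (g == "young" && !is.na(anxiety_cross_pc) && anxiety_cross_pc != 0)
      extra <- rbind(extra,
                     data.frame(from = "ha3", to = "memory", pc = anxiety_cross_pc))
    th <- make_precision_matrix(blocks, within_pc = 0, bridge = bridge,
                                extra_edges = extra, node_names = .analysis_nodes)
    theta_by_group[[g]] <- th
    w_true_by_group[[g]] <- attr(th, "w_true")
    if (max(abs(.offdiag(w_true_by_group[[g]]))) > 0.6)
      stop(.bn_error("input", "ground-truth |partial correlation| exceeds 0.6"))
  }
  spec <- structure(list(
    node_names = .analysis_nodes,
    domains = .node_domains(),
    n_per_group = n_per_group,
    theta_by_group = theta_by_group,
    w_true_by_group = w_true_by_group,
    bridge_node_by_group = bridge_node_by_group,
    ordinal_thresholds = ordinal_thresholds,
    cognitive_targets = cognitive_targets,
    cognitive_scale = cognitive_scale,
    mediation_params = mp,
    seed = as.integer(seed),
    rng = "Mersenne-Twister/Inversion"),
    class = "synthetic_spec")

  # planted-bridge property: the designated bridge node must have the
  # maximal |BEI| among affective nodes in the ground truth
  for (g in groups) {
    bnode <- if (g %in% names(bridge_node_by_group)) bridge_node_by_group[[g]] else NA
    if (is.na(bnode)) next
    bei <- bridge_expected_influence(w_true_by_group[[g]], spec$domains)
    aff <- names(spec$domains)[spec$domains != "cognitive"]
    if (names(which.max(abs(bei[aff])))[1] != bnode)
      stop(.bn_error("infeasible_spec",
        sprintf("planted bridge '%s' is not the max-|BEI| affective node in group %s",
                bnode, g)))
  }
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(x$n_per_group),
                                 x$n_per_group), collapse = ", "), "\n")
  cat("  bridges:", paste(sprintf("%s->%s", names(x$bridge_node_by_group),
                                  x$bridge_node_by_group), collapse = ", "), "\n")
  cat("  thresholds:", paste(x$ordinal_thresholds, collapse = ", "),
      " seed:", x$seed, "\n")
  invisible(x)
}

# Default within-domain edge pattern (identical across groups): chains with
# heterogeneous weights plus one chord per domain and a ring closure on the
# anxiety block. The weight ladder gives nodes distinct strengths shared by
# both groups; the chords shorten within-domain detours so that betweenness
# concentrates on the (group-specific) cross-domain crossing points.
.default_within_edges <- function() {
  ch <- function(ord, v) data.frame(from = ord[-length(ord)], to = ord[-1], pc = v)
  rbind(
    ch(.cognitive_nodes, c(0.40, 0.26, 0.30, 0.22)),
    data.frame(from = "memory", to = "language", pc = 0.24),
    ch(.depression_nodes, c(0.34, 0.30, 0.34, 0.24, 0.42, 0.34)),
    data.frame(from = "hd5", to = "hd7", pc = 0.30),
    ch(.anxiety_nodes, c(0.34, 0.30, 0.36, 0.24, 0.26, 0.22)),
    data.frame(from = c("ha7", "ha3"), to = c("ha1", "ha6"), pc = c(0.28, 0.26)))
}

.edu_probs <- list(young  = c(0.017, 0.041, 0.081, 0.861),
                   middle = c(0.15, 0.06, 0.06, 0.73),
                   old    = c(0.295, 0.077, 0.031, 0.597))
.age_range <- list(young = c(18, 45, 33.5, 6.9),
                   middle = c(46, 64, 55, 5.5),
                   old = c(65, 100, 79.3, 7.4))

.rtruncnorm <- function(n, lo, hi, mu, sd) {
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

#' Simulate an item-level dataset for one group
#'
#' Draws latent scores from the group's Gaussian graphical model
#' `N(0, Theta^-1)`, discretizes the 14 affective columns through the ordinal
#' thresholds into 0--3 scores (zero-inflated by construction), maps the 5
#' cognitive columns through a monotone logistic squashing to (0, 1) with
#' group-specific locations (older groups score lower), and attaches
#' demographic covariates (sex ~ Bernoulli(0.43), group-specific education
#' distribution, age drawn within the group's age band). Deterministic given
#' the seed.
#'
#' @param spec A [synthetic_spec()] object.
#' @param group Group name (must appear in `spec$n_per_group`).
#' @param n Number of participants; defaults to `spec$n_per_group[group]`.
#' @param seed Seed; defaults to a seed derived from `spec$seed` and the
#'   group index.
#' @return An `"item_dataset"` data frame; attribute `"latent"` holds the
#'   untransformed latent draws.
#' @examples
#' spec <- synthetic_spec(n_per_group = c(young = 40, old = 40))
#' ds <- simulate_items(spec, "old")
#' mean(ds$hd1 == 0)
#' @export
simulate_items <- function(spec, group, n = NULL, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!group %in% names(spec$n_per_group))
    stop(.bn_error("input", sprintf("unknown group '%s'", group)))
  if (is.null(n)) n <- spec$n_per_group[[group]]
  if (n < 1) stop(.bn_error("input", "n must be >= 1"))
  if (is.null(seed))
    seed <- .derive_seed(spec$seed, match(group, names(spec$n_per_group)))
  theta <- spec$theta_by_group[[group]]
  Sigma <- solve(theta)
  R <- chol(Sigma)
  p <- length(spec$node_names)

  .with_seed(seed, {
    latent <- matrix(stats::rnorm(n * p), n, p) %*% R
    colnames(latent) <- spec$node_names
    items <- latent[, c(.depression_nodes, .anxiety_nodes), drop = FALSE]
    items[] <- findInterval(items, spec$ordinal_thresholds)
    targ <- spec$cognitive_targets[[group]]
    cog <- sapply(.cognitive_nodes, function(v)
      stats::plogis(stats::qlogis(targ[[v]]) +
                    spec$cognitive_scale * latent[, v]))
    sex <- stats::rbinom(n, 1, 0.43)
    edu <- sample(0:3, n, replace = TRUE, prob = .edu_probs[[group]])
    ar <- .age_range[[group]]
    age <- round(.rtruncnorm(n, ar[1], ar[2], ar[3], ar[4]), 1)
    df <- data.frame(subject_id = sprintf("%s_%05d", group, seq_len(n)),
                     group = group, sex = sex, education = edu, age = age,
                     cog, items,
                     ace_r_total = rowMeans(cog),
                     stringsAsFactors = FALSE)
    structure(df, n_dropped = 0L, drop_reasons = character(0),
              latent = latent,
              class = c("item_dataset", "data.frame"))
  })
}

#' Simulate the full multi-group study
#'
#' Calls [simulate_items()] for every group in the spec and binds the rows.
#'
#' @inheritParams simulate_items
#' @return An `"item_dataset"` with all groups.
#' @export
simulate_study <- function(spec) {
  parts <- lapply(names(spec$n_per_group), function(g) {
    d <- simulate_items(spec, g)
    attr(d, "latent") <- NULL
    d
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  structure(out, n_dropped = 0L, drop_reasons = character(0),
            class = c("item_dataset", "data.frame"))
}

#' Simulate moderated-mediation data with known path coefficients
#'
#' Generates data from the recursive two-equation system underlying the
#' gray-matter-volume -> cognition -> depressive-symptom model:
#' `cognition = a*gmv + a_int*gmv*age + age_main*age + gamma_sex*sex_z +
#' gamma_edu*edu_z + e1` and `outcome = b*cognition + c_prime*gmv + e2`,
#' with `gmv` and `age` standard normal. A second outcome (`hd3`) is
#' generated with its own paths (`b2`, `c_prime2`), defaulting to a null
#' mediation path `b2 = 0`. Unless error SDs are supplied they are derived so
#' that every structural outcome has unit population variance, making the
#' path coefficients exactly standardized.
#'
#' @param params Named list of paths: `a`, `a_int`, `b`, `c_prime`, and
#'   optionally `b2`, `c_prime2`, `age_main`, `gamma_sex`, `gamma_edu`,
#'   `error_sd` (length 3: mediator, outcome, second outcome).
#' @param n Sample size.
#' @param seed Seed (deterministic output).
#' @return Data frame with columns `gmv`, `age`, `cognition`, `hd7`, `hd3`,
#'   `sex`, `education`.
#' @examples
#' d <- simulate_mediation_data(list(a = 0.142, a_int = 0.186,
#'                                   b = -0.147, c_prime = 0.013), n = 200)
#' round(coef(lm(cognition ~ gmv * age, d)), 2)
#' @export
simulate_mediation_data <- function(params, n = 733, seed = 1L) {
  mp <- utils::modifyList(list(a = 0.142, a_int = 0.186, b = -0.147,
                               c_prime = 0.013, b2 = 0, c_prime2 = -0.029,
                               age_main = -0.3, gamma_sex = 0.1,
                               gamma_edu = 0.1, error_sd = NULL), params)
  edu_p <- c(0.18, 0.06, 0.06, 0.70)
  edu_mu <- sum(0:3 * edu_p)
  edu_sd <- sqrt(sum((0:3 - edu_mu)^2 * edu_p))
  sex_p <- 0.43

  var_m_struct <- mp$a^2 + mp$a_int^2 + mp$age_main^2 +
    mp$gamma_sex^2 + mp$gamma_edu^2
  var_y_struct <- mp$b^2 + mp$c_prime^2 + 2 * mp$a * mp$b * mp$c_prime
  var_y2_struct <- mp$b2^2 + mp$c_prime2^2 + 2 * mp$a * mp$b2 * mp$c_prime2
  if (is.null(mp$error_sd)) {
    if (min(1 - var_m_struct, 1 - var_y_struct, 1 - var_y2_struct) <= 0)
      stop(.bn_error("infeasible_spec",
        "structural variance exceeds 1; cannot derive unit-variance error SDs"))
    mp$error_sd <- sqrt(c(1 - var_m_struct, 1 - var_y_struct, 1 - var_y2_struct))
  }
  if (any(mp$error_sd <= 0))
    stop(.bn_error("input", "error SDs must be > 0"))

  .with_seed(seed, {
    gmv <- stats::rnorm(n)
    age <- stats::rnorm(n)
    sex <- stats::rbinom(n, 1, sex_p)
    edu <- sample(0:3, n, replace = TRUE, prob = edu_p)
    sex_z <- (sex - sex_p) / sqrt(sex_p * (1 - sex_p))
    edu_z <- (edu - edu_mu) / edu_sd
    cognition <- mp$a * gmv + mp$a_int * gmv * age + mp$age_main * age +
      mp$gamma_sex * sex_z + mp$gamma_edu * edu_z +
      stats::rnorm(n, sd = mp$error_sd[1])
    hd7 <- mp$b * cognition + mp$c_prime * gmv + stats::rnorm(n, sd = mp$error_sd[2])
    hd3 <- mp$b2 * cognition + mp$c_prime2 * gmv + stats::rnorm(n, sd = mp$error_sd[3])
    data.frame(gmv = gmv, age = age, cognition = cognition,
               hd7 = hd7, hd3 = hd3, sex = sex, education = edu)
  })
}
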