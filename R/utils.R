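# Internal helpers shared across modules.

# Canonical node order: 5 cognitive domains then 14 affective items.
.cognitive_nodes <- c("memory", "fluency", "language", "visuospatial", "orientation")
.depression_nodes <- paste0("hd", 1:7)
.anxiety_nodes <- paste0("ha", 1:7)
.analysis_nodes <- c(.cognitive_nodes, .depression_nodes, .anxiety_nodes)

.node_domains <- function(nodes = .analysis_nodes) {
  dom <- ifelse(nodes %in% .cognitive_nodes, "cognitive",
         ifelse(nodes %in% .depression_nodes, "depression",
         ifelse(nodes %in% .anxiety_nodes, "anxiety", "covariate")))
  names(dom) <- nodes
  dom
}

# Run code under a fixed, named RNG without disturbing the caller's stream.
# The generator algorithm is pinned (Mersenne-Twister / inversion) so that
# seeded output is reproducible across platforms.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Column-wise z-scoring with the sample-SD (n-1) convention.
.zscore <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  zero <- s < 1e-12
  if (any(zero)) {
    stop(.bn_error("degenerate_input",
      sprintf("zero-variance column(s): %s",
              paste(colnames(x)[zero], collapse = ", "))))
  }
  scale(x, center = m, scale = s)
}

.bn_error <- function(class, message) {
  structure(class = c(paste0("bridgenet_", class), "error", "condition"),
            list(message = message, call = sys.call(-1)))
}

.check_symmetric <- function(W, tol = 1e-10, what = "W") {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop(.bn_error("input", sprintf("%s must be a square matrix", what)))
  if (max(abs(W - t(W))) > tol)
    stop(.bn_error("input", sprintf("%s is not symmetric (tolerance %g)", what, tol)))
  invisible(TRUE)
}

.offdiag <- function(M) M[row(M) != col(M)]

# Deterministically derive stage seeds from one master seed, keeping the
# result inside 32-bit integer range.
.derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset) * 9973L) %% 2147483647L
}
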