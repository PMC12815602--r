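#' Fit a moderated-mediation path model with percentile-bootstrap inference
#'
#' Estimates the recursive two-equation path model in which cognition
#' mediates the association between gray-matter volume (GMV) and a
#' depressive symptom, with age moderating the GMV -> cognition path:
#' \deqn{M: cognition = a \cdot gmv + a_{int} \cdot gmv \cdot age + ...}
#' \deqn{Y: outcome = b \cdot cognition + c' \cdot gmv + ...}
#' both controlling for sex and education (and, by default, the age main
#' effect — an interaction without its main effect is malformed; set
#' `age_main = FALSE` to drop it). Equations are estimated by least squares;
#' in a fully observed just-identified recursive system this equals the
#' maximum-likelihood path solution. All continuous variables are z-scored
#' on entry, so coefficients are standardized; the indirect effect at mean
#' age is `a * b` and the index of moderated mediation — the change in the
#' indirect effect per SD of age — is `a_int * b`.
#'
#' Inference is by case-resampling bootstrap: both equations are refit
#' jointly on each resample and percentile confidence intervals are taken
#' over the resampled path products. A residual bootstrap is available via
#' `boot = "residual"`.
#'
#' @param data Data frame containing the treatment, moderator, mediator,
#'   outcome and control columns (see [simulate_mediation_data()]).
#' @param outcome Outcome column (e.g. `"hd7"` anhedonia or `"hd3"`
#'   dysphoria).
#' @param mediator,treatment,moderator Column names (defaults `"cognition"`,
#'   `"gmv"`, `"age"`).
#' @param controls Control columns (default sex and education; binary
#'   columns are left unscaled, numeric ones are z-scored).
#' @param n_boot Number of bootstrap resamples (5000 conventionally; a
#'   warning is logged below 1000).
#' @param seed Seed for the resampling stream.
#' @param age_main Keep the moderator's main effect in both equations?
#' @param boot `"case"` (default) or `"residual"`.
#' @param conf_level Confidence level for percentile intervals.
#' @return Object of class `"moderated_mediation"` with elements `paths`
#'   (a data frame with estimate, percentile CI, bootstrap and
#'   normal-approximation p per path), `a`, `a_int`, `b`, `c_prime`,
#'   `indirect_at_mean_age`, `imm`, `conditional_indirects` (at -1/0/+1 SD
#'   of age), `control_paths`, `draws` (per-resample path draws), `n_boot`,
#'   `seed`, `n`.
#' @examples
#' d <- simulate_mediation_data(list(), n = 300, seed = 2)
#' fit <- moderated_mediation(d, outcome = "hd7", n_boot = 200, seed = 2)
#' fit
#' @export
moderated_mediation <- function(data, outcome = "hd7", mediator = "cognition",
                                treatment = "gmv", moderator = "age",
                                controls = c("sex", "education"),
                                n_boot = 5000, seed = 1L, age_main = TRUE,
                                boot = c("case", "residual"),
                                conf_level = 0.95) {
  boot <- match.arg(boot)
  cols <- c(outcome, mediator, treatment, moderator, controls)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0)
    stop(.bn_error("schema",
      sprintf("missing column(s): %s", paste(miss, collapse = ", "))))
  df <- stats::na.omit(as.data.frame(data)[cols])
  n <- nrow(df)
  if (n < 50)
    stop(.bn_error("insufficient_data",
      sprintf("moderated mediation needs n >= 50, got %d", n)))
  if (n_boot < 1000)
    warning(sprintf("n_boot = %d is below the conventional 1000; intervals may be unstable", n_boot))

  # z-score continuous variables (binary 0/1 columns left as codes)
  zs <- function(x) if (length(unique(x)) <= 2) x else as.numeric(scale(x))
  for (cl in cols) df[[cl]] <- zs(df[[cl]])
  tm <- df[[treatment]] * df[[moderator]]

  Xm <- cbind(`(Intercept)` = 1, tr = df[[treatment]], tm = tm)
  Xy <- cbind(`(Intercept)` = 1, med = df[[mediator]], tr = df[[treatment]])
  if (age_main) {
    Xm <- cbind(Xm, mod = df[[moderator]])
    Xy <- cbind(Xy, mod = df[[moderator]])
  }
  for (cl in controls) {
    Xm <- cbind(Xm, df[[cl]]); colnames(Xm)[ncol(Xm)] <- cl
    Xy <- cbind(Xy, df[[cl]]); colnames(Xy)[ncol(Xy)] <- cl
  }
  for (X in list(Xm, Xy)) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop(.bn_error("collinearity",
        sprintf("rank-deficient design; aliased column(s): %s",
                paste(aliased, collapse = ", "))))
    }
  }
  m <- df[[mediator]]; y <- df[[outcome]]
  cm <- stats::lm.fit(Xm, m)$coefficients
  cy <- stats::lm.fit(Xy, y)$coefficients

  a <- unname(cm["tr"]); a_int <- unname(cm["tm"])
  b <- unname(cy["med"]); c_prime <- unname(cy["tr"])

  km <- ncol(Xm); ky <- ncol(Xy)
  idx <- .with_seed(seed,
    matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot))
  if (boot == "case") {
    bc <- .path_boot(Xm, m, Xy, y, idx)
  } else {
    em <- m - Xm %*% cm; ey <- y - Xy %*% cy
    bc <- matrix(NA_real_, n_boot, km + ky)
    for (r in seq_len(n_boot)) {
      ms <- as.vector(Xm %*% cm) + em[idx[, r]]
      Xys <- Xy; Xys[, "med"] <- ms
      ys <- as.vector(Xys %*% cy) + ey[idx[, r]]
      bc[r, ] <- c(stats::lm.fit(Xm, ms)$coefficients,
                   stats::lm.fit(Xys, ys)$coefficients)
    }
  }
  colnames(bc) <- c(paste0("m.", colnames(Xm)), paste0("y.", colnames(Xy)))
  draws <- data.frame(a = bc[, "m.tr"], a_int = bc[, "m.tm"],
                      b = bc[, "y.med"], c_prime = bc[, "y.tr"])
  draws$indirect <- draws$a * draws$b
  draws$imm <- draws$a_int * draws$b

  alpha <- (1 - conf_level) / 2
  ci <- function(x) unname(stats::quantile(x, c(alpha, 1 - alpha)))
  pboot <- function(x) min(1, 2 * min(mean(x <= 0), mean(x >= 0)))
  pnorm2 <- function(est, x) 2 * stats::pnorm(-abs(est) / stats::sd(x))

  ests <- c(a = a, a_int = a_int, b = b, c_prime = c_prime,
            indirect = a * b, imm = a_int * b)
  path_names <- c("a (GMV -> cognition)",
                  "a_int (GMV x age -> cognition)",
                  "b (cognition -> outcome)",
                  "c_prime (GMV -> outcome, direct)",
                  "indirect via cognition (mean age)",
                  "index of moderated mediation")
  paths <- data.frame(path = path_names, estimate = unname(ests))
  cis <- t(sapply(names(ests), function(k) ci(draws[[k]])))
  paths$ci_lo <- cis[, 1]; paths$ci_hi <- cis[, 2]
  paths$p_boot <- sapply(names(ests), function(k) pboot(draws[[k]]))
  paths$p_normal <- sapply(names(ests), function(k) pnorm2(ests[[k]], draws[[k]]))
  rownames(paths) <- names(ests)

  cond <- lapply(c(`-1` = -1, `0` = 0, `1` = 1), function(z) {
    d <- (draws$a + draws$a_int * z) * draws$b
    list(age_z = z, estimate = (a + a_int * z) * b, ci = ci(d), p_boot = pboot(d))
  })

  ctrl_idx <- setdiff(colnames(Xy), c("(Intercept)", "med", "tr"))
  structure(list(outcome = outcome,
                 paths = paths,
                 a = a, a_int = a_int, b = b, c_prime = c_prime,
                 indirect_at_mean_age = a * b,
                 imm = a_int * b,
                 conditional_indirects = cond,
                 control_paths = cy[ctrl_idx],
                 mediator_controls = cm[setdiff(colnames(Xm),
                                                c("(Intercept)", "tr", "tm"))],
                 draws = draws,
                 n_boot = n_boot, seed = seed, n = n,
                 boot = boot, conf_level = conf_level,
                 age_main = age_main,
                 call = match.call()),
            class = "moderated_mediation")
}

#' @export
print.moderated_mediation <- function(x, digits = 3, ...) {
  cat(sprintf("Moderated mediation: gmv -> cognition -> %s (n = %d, %d %s-bootstrap resamples)\n\n",
              x$outcome, x$n, x$n_boot, x$boot))
  tab <- x$paths
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.moderated_mediation <- function(object, ...) {
  print(object)
  cat("\nConditional indirect effects:\n")
  for (ci in object$conditional_indirects)
    cat(sprintf("  age = %+d SD: %.4f [%.4f, %.4f]\n",
                ci$age_z, ci$estimate, ci$ci[1], ci$ci[2]))
  invisible(object)
}

#' @export
coef.moderated_mediation <- function(object, ...) {
  stats::setNames(object$paths$estimate, rownames(object$paths))
}

#' @export
confint.moderated_mediation <- function(object, parm, level = 0.95, ...) {
  alpha <- (1 - level) / 2
  keep <- if (missing(parm)) rownames(object$paths) else parm
  t(sapply(keep, function(k)
    stats::quantile(object$draws[[k]], c(alpha, 1 - alpha))))
}

#' Conditional indirect effect at a given age
#'
#' Evaluates `(a + a_int * age_z) * b` at the requested (z-scored) age with a
#' percentile CI from the stored bootstrap draws.
#'
#' @param fit A fitted [moderated_mediation()] object.
#' @param age_z Age in SD units; values outside \[-3, 3\] trigger an
#'   extrapolation warning.
#' @return List with `age_z`, `estimate`, `ci`, `p_boot`.
#' @export
conditional_indirect <- function(fit, age_z) {
  stopifnot(inherits(fit, "moderated_mediation"))
  if (abs(age_z) > 3)
    warning(sprintf("age_z = %.2f is outside [-3, 3]: extrapolation", age_z))
  d <- (fit$draws$a + fit$draws$a_int * age_z) * fit$draws$b
  alpha <- (1 - fit$conf_level) / 2
  list(age_z = age_z,
       estimate = (fit$a + fit$a_int * age_z) * fit$b,
       ci = unname(stats::quantile(d, c(alpha, 1 - alpha))),
       p_boot = min(1, 2 * min(mean(d <= 0), mean(d >= 0))))
}
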