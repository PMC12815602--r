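#' Descriptive group comparison of demographic, cognitive and affective variables
#'
#' For every analysis variable in the dataset, compares the two groups with a
#' Welch (or pooled-variance) t-test for continuous variables and a
#' chi-square test for categorical variables (sex, categorical education).
#' Raw p-values are adjusted across all rows with the Benjamini--Hochberg
#' false-discovery-rate procedure.
#'
#' @param ds An `"item_dataset"` or data frame containing `group_var` and the
#'   analysis variables.
#' @param group_var Name of the grouping column; it must take exactly two
#'   values in the data.
#' @param welch Use the Welch (unequal-variance) t-test (default) rather than
#'   the pooled-variance test.
#' @param categorical Character vector of columns to treat as categorical
#'   (percentages + chi-square). Defaults to `"sex"`, plus `"education"` when
#'   education has 6 or fewer distinct values.
#' @return A data frame of class `"descriptive_comparison"` with one row per
#'   variable: group summaries (mean and SD, or percentage), the test
#'   statistic, degrees of freedom, raw and BH-adjusted p-values.
#' @examples
#' spec <- synthetic_spec(n_per_group = c(young = 80, old = 80))
#' tab <- descriptive_compare(simulate_study(spec))
#' head(tab)
#' @export
descriptive_compare <- function(ds, group_var = "group", welch = TRUE,
                                categorical = NULL) {
  df <- as.data.frame(ds)
  if (!group_var %in% names(df))
    stop(.bn_error("schema", sprintf("missing grouping column '%s'", group_var)))
  g <- as.factor(df[[group_var]])
  g <- droplevels(g)
  if (nlevels(g) != 2)
    stop(.bn_error("input",
      sprintf("descriptive_compare needs exactly two groups, got %d", nlevels(g))))
  if (min(table(g)) < 2)
    stop(.bn_error("insufficient_data", "each group needs at least 2 rows"))

  vars <- setdiff(names(df), c(group_var, "subject_id"))
  if (is.null(categorical)) {
    categorical <- intersect("sex", vars)
    if ("education" %in% vars &&
        length(unique(stats::na.omit(df$education))) <= 6)
      categorical <- c(categorical, "education")
  }

  rows <- lapply(vars, function(v) {
    x <- df[[v]]
    if (v %in% categorical) {
      tab <- table(g, x)
      stat <- tryCatch(stats::chisq.test(tab, correct = FALSE),
                       warning = function(w) suppressWarnings(stats::chisq.test(tab, correct = FALSE)))
      # percentage summary: share of the highest category (binary) or modal level
      lev <- colnames(tab)[ncol(tab)]
      pct <- prop.table(tab, 1)[, ncol(tab)] * 100
      if (all(tab == tab[, rep(1, ncol(tab))])) { # identical distributions
        stat$statistic <- 0; stat$p.value <- 1
      }
      data.frame(variable = v, type = "categorical",
                 summary1 = pct[1], sd1 = NA_real_,
                 summary2 = pct[2], sd2 = NA_real_,
                 statistic = unname(stat$statistic),
                 df = unname(stat$parameter),
                 p = stat$p.value, stringsAsFactors = FALSE)
    } else {
      x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
      if (stats::sd(x1) < 1e-12 && stats::sd(x2) < 1e-12) {
        # degenerate: no within-group variability
        same <- abs(mean(x1) - mean(x2)) < 1e-12
        tt <- list(statistic = if (same) 0 else Inf * sign(mean(x1) - mean(x2)),
                   parameter = NA_real_, p.value = if (same) 1 else 0)
      } else {
        tt <- stats::t.test(x1, x2, var.equal = !welch)
      }
      data.frame(variable = v, type = "continuous",
                 summary1 = mean(x1), sd1 = stats::sd(x1),
                 summary2 = mean(x2), sd2 = stats::sd(x2),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "groups") <- levels(g)
  class(out) <- c("descriptive_comparison", "data.frame")
  out
}

#' Write a descriptive comparison table to disk
#'
#' @param tab A `"descriptive_comparison"` table.
#' @param path Output path; `.json` extension writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(tab, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(tab), path, digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  }
  invisible(path)
}
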