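#' Read and validate a participant-level item table
#'
#' Reads a delimited text file with one row per participant holding the group
#' label, demographic covariates, the 14 affective items (`hd1`--`hd7`,
#' `ha1`--`ha7`, each scored 0--3) and the 5 cognitive-domain proportions
#' (`memory`, `fluency`, `language`, `visuospatial`, `orientation`, each in
#' \[0, 1\]). Optional columns `subject_id`, `ace_r_total` and `gmv_tiv` are
#' carried through when present.
#'
#' Rows that fail validation (missing demographic or clinical fields, items
#' outside 0--3, cognitive scores outside \[0, 1\], or a group label
#' inconsistent with age) are dropped; the number dropped is recorded in the
#' `"n_dropped"` attribute. Listwise deletion is the only missing-data
#' strategy, mirroring exclusion of participants with incomplete records.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator: `","` (default) or `"\t"`.
#' @param education_levels Ordered labels used to convert a categorical
#'   education column to integer ranks 0--3. A numeric education column
#'   (e.g. years of education) is used as-is.
#' @return A data frame of class `"item_dataset"` with attributes
#'   `"n_dropped"` (rows removed) and `"drop_reasons"`.
#' @seealso [validate_item_table()] for validating an in-memory data frame,
#'   [simulate_items()] for synthetic datasets with known ground truth.
#' @examples
#' path <- system.file("extdata", "synthetic_items_small.csv", package = "bridgenet")
#' ds <- read_item_table(path)
#' table(ds$group)
#' @export
read_item_table <- function(path, sep = ",",
                            education_levels = c("None", "GCSE", "A level", "University")) {
  if (!file.exists(path))
    stop(.bn_error("input", sprintf("file not found: %s", path)))
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           fileEncoding = "UTF-8", check.names = FALSE)
  names(raw) <- tolower(names(raw))
  validate_item_table(raw, education_levels = education_levels)
}

#' Validate an in-memory participant table
#'
#' Applies the schema and row-level checks described in
#' [read_item_table()] to a data frame.
#'
#' @param df A data frame with the required columns.
#' @inheritParams read_item_table
#' @return A validated `"item_dataset"` data frame.
#' @export
validate_item_table <- function(df,
                                education_levels = c("None", "GCSE", "A level", "University")) {
  required <- c("group", "sex", "education", "age", .analysis_nodes)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop(.bn_error("schema",
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", "))))

  # education: categorical labels -> integer ranks 0-3; numeric kept
  if (!is.numeric(df$education)) {
    edu <- trimws(as.character(df$education))
    rank <- match(edu, education_levels) - 1L
    bad <- !is.na(edu) & is.na(rank)
    if (any(bad))
      stop(.bn_error("parse",
        sprintf("unrecognized education label in row(s) %s",
                paste(utils::head(which(bad), 5), collapse = ", "))))
    df$education <- rank
  }

  numeric_cols <- c("sex", "education", "age", .analysis_nodes,
                    intersect(c("ace_r_total", "gmv_tiv"), names(df)))
  for (cl in numeric_cols) {
    if (!is.numeric(df[[cl]])) {
      conv <- suppressWarnings(as.numeric(df[[cl]]))
      bad <- !is.na(df[[cl]]) & is.na(conv)
      if (any(bad))
        stop(.bn_error("parse",
          sprintf("non-numeric value in column '%s', row(s) %s", cl,
                  paste(utils::head(which(bad), 5), collapse = ", "))))
      df[[cl]] <- conv
    }
  }
  df$group <- tolower(trimws(as.character(df$group)))

  reasons <- character(0)
  drop <- rep(FALSE, nrow(df))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    if (any(bad & !drop)) reasons <<- c(reasons, sprintf("%s (%d)", why, sum(bad & !drop)))
    drop <<- drop | bad
  }
  flag(rowSums(is.na(df[required])) > 0, "missing demographic or clinical field")
  flag(!df$group %in% c("young", "middle", "old"), "unknown group label")
  items <- as.matrix(df[c(.depression_nodes, .anxiety_nodes)])
  flag(rowSums(is.na(items) | items < 0 | items > 3 | items != round(items)) > 0,
       "affective item outside {0,1,2,3}")
  cog <- as.matrix(df[.cognitive_nodes])
  flag(rowSums(is.na(cog) | cog < 0 | cog > 1) > 0, "cognitive score outside [0,1]")
  # group label must be consistent with age: young <= 45, old >= 65
  flag((df$group == "young" & df$age > 45) | (df$group == "old" & df$age < 65),
       "group label inconsistent with age")

  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    stop(.bn_error("input", "no rows left after validation"))
  structure(out,
            n_dropped = sum(drop),
            drop_reasons = reasons,
            class = c("item_dataset", "data.frame"))
}

#' @export
print.item_dataset <- function(x, ...) {
  cat(sprintf("<item_dataset> %d participants (%d dropped at validation)\n",
              nrow(x), attr(x, "n_dropped") %||% 0L))
  print(table(group = x$group))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess analysis variables for network estimation
#'
#' Extracts the 19 analysis columns (5 cognitive + 14 affective) in canonical
#' order, optionally residualizes each on a set of covariates (ordinary least
#' squares with intercept) to remove confounding, and z-scores every column
#' using the sample-SD convention. Residualization followed by
#' re-standardization keeps the 19-node topology while accounting for
#' covariates such as sex and years of education.
#'
#' @param x An `"item_dataset"` (or plain data frame with the analysis
#'   columns), or an existing `"preprocessed_matrix"` (the operation is
#'   idempotent).
#' @param covariates Character vector of covariate column names (default
#'   `c("sex", "education")`). Ignored when `residualize = FALSE` and
#'   `covariates_as_nodes = FALSE`.
#' @param residualize Replace each analysis column by its OLS residuals on
#'   the covariates before re-standardizing?
#' @param covariates_as_nodes Instead of residualizing, append the z-scored
#'   covariates as additional columns, so they enter the network as nodes
#'   (community label `"covariate"` downstream). Mutually exclusive with
#'   `residualize`.
#' @return An object of class `"preprocessed_matrix"`: a list with `values`
#'   (n x 19 matrix, each column mean 0 / SD 1), `node_names`,
#'   `covariate_names`, `covariate_values`, `residualized`, and `scaling`
#'   (the centers/scales applied).
#' @examples
#' spec <- synthetic_spec(n_per_group = c(young = 60, old = 60))
#' ds <- simulate_items(spec, "young")
#' pm <- preprocess(ds)
#' round(colMeans(pm$values), 12)
#' @export
preprocess <- function(x, covariates = c("sex", "education"),
                       residualize = TRUE, covariates_as_nodes = FALSE) {
  if (covariates_as_nodes && residualize && !inherits(x, "preprocessed_matrix"))
    residualize <- FALSE
  if (inherits(x, "preprocessed_matrix")) {
    vals <- x$values
    Z <- x$covariate_values
    covariates <- x$covariate_names
    residualize <- x$residualized
  } else {
    df <- as.data.frame(x)
    miss <- setdiff(.analysis_nodes, names(df))
    if (length(miss) > 0)
      stop(.bn_error("schema",
        sprintf("missing analysis column(s): %s", paste(miss, collapse = ", "))))
    vals <- as.matrix(df[.analysis_nodes])
    storage.mode(vals) <- "double"
    if (residualize || covariates_as_nodes) {
      miss_cov <- setdiff(covariates, names(df))
      if (length(miss_cov) > 0)
        stop(.bn_error("schema",
          sprintf("missing covariate column(s): %s", paste(miss_cov, collapse = ", "))))
      Z <- as.matrix(df[covariates])
      storage.mode(Z) <- "double"
    } else {
      Z <- matrix(numeric(0), nrow(vals), 0)
      covariates <- character(0)
    }
    if (covariates_as_nodes) {
      vals <- cbind(vals, Z)
      Z <- matrix(numeric(0), nrow(vals), 0)
      covariates <- character(0)
    }
  }
  if (residualize && ncol(Z) > 0) {
    qrz <- qr(cbind(`(Intercept)` = 1, Z))
    vals <- qr.resid(qrz, vals)
  }
  center <- colMeans(vals)
  scale_ <- apply(vals, 2, stats::sd)
  vals <- .zscore(vals)
  structure(list(values = vals,
                 node_names = colnames(vals),
                 covariate_names = covariates,
                 covariate_values = Z,
                 residualized = residualize,
                 scaling = list(center = center, scale = scale_)),
            class = "preprocessed_matrix")
}

#' @export
print.preprocessed_matrix <- function(x, ...) {
  cat(sprintf("<preprocessed_matrix> %d x %d (z-scored%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$residualized)
                paste0(", residualized on ", paste(x$covariate_names, collapse = "+"))
              else ""))
  invisible(x)
}
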