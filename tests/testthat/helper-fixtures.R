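# Fixtures built in code, plus a lazily computed cache of study-scale
# simulation runs shared by the acceptance tests and the heavier property
# tests (so the expensive two-group fits are paid for once per test run).

item_columns <- c("memory", "fluency", "language", "visuospatial", "orientation",
                  paste0("hd", 1:7), paste0("ha", 1:7))

# A tiny valid in-memory item table (3 rows by default).
tiny_item_df <- function(n = 3, group = "young") {
  set.seed(99)
  df <- data.frame(group = group, sex = rep_len(c(0, 1), n),
                   education = rep_len(0:3, n),
                   age = if (group == "young") seq(25, 40, length.out = n)
                         else seq(66, 80, length.out = n))
  for (cl in item_columns[1:5]) df[[cl]] <- seq(0.5, 0.9, length.out = n)
  for (cl in item_columns[6:19]) df[[cl]] <- rep_len(c(0, 1, 2), n)
  df
}

write_item_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Correlation matrix of a chain-graph Gaussian model.
chain_S <- function(p, pc = 0.3) {
  th <- make_precision_matrix(stats::setNames(as.integer(p), "v"), within_pc = pc,
                              node_names = paste0("v", seq_len(p)))
  stats::cov2cor(solve(unclass(th)))
}

# ---- shared study-scale runs ----------------------------------------------
# For each seed: simulate both groups at the reference sizes, fit the
# EBIC-glasso network, and record support recovery, centrality outcomes,
# cross-group rank correlations and the old-group permutation test.
.study_cache <- new.env(parent = emptyenv())

study_scale_runs <- function(n_runs = 100) {
  key <- paste0("runs", n_runs)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  spec <- synthetic_spec()
  out <- vector("list", n_runs)
  for (s in seq_len(n_runs)) {
    res <- list(seed = s)
    cents <- list()
    for (g in c("young", "old")) {
      ds <- simulate_items(spec, g, seed = s * 1000L + match(g, c("young", "old")))
      net <- suppressWarnings(ebic_glasso(preprocess(ds)))
      Wt <- spec$w_true_by_group[[g]]
      ut <- upper.tri(Wt)
      te <- abs(Wt[ut]) > 1e-8
      ee <- abs(net$W[ut]) > 1e-8
      detected_signs_ok <- sign(net$W[ut][te & ee]) == sign(Wt[ut][te & ee])
      ct <- centrality_table(net)
      aff <- ct$domain != "cognitive"
      res[[g]] <- list(
        sens = sum(ee & te) / sum(te),
        fpr = sum(ee & !te) / sum(!te),
        sign_ok = detected_signs_ok,
        top_bei = ct$node[aff][which.max(abs(ct$bei[aff]))],
        edge_path = net$path$edges,
        ebic_path = net$path$ebic,
        ebic_selected = net$ebic_value)
      cents[[g]] <- ct
    }
    res$rho_strength <- centrality_rank_correlation(
      cents$young$strength, cents$old$strength)$rho
    res$rho_betweenness <- centrality_rank_correlation(
      cents$young$betweenness, cents$old$betweenness)$rho
    res$old_perm_p <- domain_permutation_test(
      cents$old, "betweenness", n_perm = 1000, seed = s + 5000L,
      sidedness = "one_sided_greater")$p_value
    out[[s]] <- res
  }
  .study_cache[[key]] <- out
  out
}
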