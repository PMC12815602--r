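test_that("a well-formed table reads with no rows dropped", {
  path <- write_item_csv(tiny_item_df(3))
  ds <- read_item_table(path)
  expect_s3_class(ds, "item_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(attr(ds, "n_dropped"), 0L)
})

test_that("rows with missing clinical fields are dropped and counted", {
  df <- tiny_item_df(3)
  df$education[2] <- NA
  ds <- read_item_table(write_item_csv(df))
  expect_equal(nrow(ds), 2)
  expect_equal(attr(ds, "n_dropped"), 1L)
})

test_that("schema violations name the missing column", {
  df <- tiny_item_df(3)
  names(df)[names(df) == "hd7"] <- "hd8"
  expect_error(read_item_table(write_item_csv(df)),
               "hd7", class = "bridgenet_schema")
})

test_that("non-numeric item cells raise a parse error with the row index", {
  df <- tiny_item_df(3)
  df$hd1 <- as.character(df$hd1)
  df$hd1[2] <- "two"
  expect_error(read_item_table(write_item_csv(df)),
               "hd1.*2", class = "bridgenet_parse")
})

test_that("categorical education maps to ranks and bad labels error", {
  df <- tiny_item_df(4)
  df$education <- c("None", "GCSE", "A level", "University")
  ds <- validate_item_table(df)
  expect_equal(ds$education, 0:3)
  df$education[1] <- "PhD"
  expect_error(validate_item_table(df), class = "bridgenet_parse")
})

test_that("rows violating item range, group label or age consistency drop", {
  df <- tiny_item_df(5)
  df$hd3[1] <- 4            # out of 0-3
  df$memory[2] <- 1.4       # out of [0,1]
  df$group <- "young"
  df$age[3] <- 60           # young but age > 45
  df$group[4] <- "elder"    # unknown label
  ds <- validate_item_table(df)
  expect_equal(nrow(ds), 1)
  expect_equal(attr(ds, "n_dropped"), 4L)
})

test_that("z-scoring uses the sample-SD convention", {
  df <- tiny_item_df(3)
  df$memory <- c(0.1, 0.2, 0.3)  # linear column -> z-scores (-1, 0, 1)
  pm <- preprocess(df, residualize = FALSE)
  expect_equal(unname(pm$values[, "memory"]), c(-1, 0, 1), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(pm$values))), 1e-8)
  expect_lt(max(abs(apply(pm$values, 2, sd) - 1)), 1e-8)
})

test_that("zero-variance and covariate-degenerate columns are rejected by name", {
  df <- tiny_item_df(6)
  df$fluency <- 0.5
  expect_error(preprocess(df, residualize = FALSE),
               "fluency", class = "bridgenet_degenerate_input")
  # analysis column exactly equal to a covariate: residuals vanish
  df2 <- tiny_item_df(30)
  set.seed(1)
  df2$education <- rnorm(30)
  df2$language <- df2$education
  expect_error(preprocess(df2, covariates = "education"),
               "language", class = "bridgenet_degenerate_input")
})

test_that("residualization makes analysis columns orthogonal to covariates", {
  set.seed(7)
  n <- 200
  df <- tiny_item_df(n)
  df$education <- rnorm(n)
  df$sex <- rbinom(n, 1, 0.5)
  for (cl in item_columns) df[[cl]] <- 0.6 * df$education + rnorm(n)
  pm <- preprocess(df)
  expect_lt(max(abs(cor(pm$values, cbind(df$education, df$sex)))), 1e-8)
})

test_that("preprocessing is idempotent", {
  set.seed(8)
  df <- tiny_item_df(60)
  for (cl in item_columns) df[[cl]] <- rnorm(60)
  pm1 <- preprocess(df)
  pm2 <- preprocess(pm1)
  expect_lt(max(abs(pm1$values - pm2$values)), 1e-10)
})

test_that("identical groups give zero statistics and adjusted p of 1", {
  df <- rbind(transform(tiny_item_df(10), group = "young"),
              transform(tiny_item_df(10), group = "old"))
  df$age <- 50  # keep the two copies identical on every compared column
  tab <- descriptive_compare(df)
  expect_true(all(abs(tab$statistic) < 1e-12))
  expect_true(all(tab$p_adj == 1))
})

test_that("a one-SD mean shift at n=500 is detected after FDR adjustment", {
  set.seed(11)
  n <- 500
  df <- tiny_item_df(2 * n)
  df$group <- rep(c("young", "old"), each = n)
  df$age <- rep(c(30, 70), each = n)
  for (cl in item_columns) df[[cl]] <- rnorm(2 * n)
  df$memory <- rnorm(2 * n, mean = rep(c(0, 1), each = n))
  tab <- descriptive_compare(df)
  expect_lt(tab$p_adj[tab$variable == "memory"], 0.001)
})

test_that("comparison is symmetric in group order up to the sign of t", {
  set.seed(12)
  df <- tiny_item_df(80)
  df$group <- rep(c("young", "old"), 40)
  df$age <- ifelse(df$group == "young", 30, 70)
  for (cl in item_columns) df[[cl]] <- rnorm(80)
  t1 <- descriptive_compare(df)  # factor levels default to old < young
  df2 <- df
  df2$group <- factor(df2$group, levels = c("young", "old"))
  t2 <- descriptive_compare(df2)
  cont <- t1$type == "continuous"
  expect_equal(t1$statistic[cont], -t2$statistic[cont], tolerance = 1e-10)
  expect_equal(t1$p, t2$p, tolerance = 1e-10)
})

test_that("BH adjustment is monotone in the raw p-values", {
  set.seed(13)
  df <- tiny_item_df(60)
  df$group <- rep(c("young", "old"), 30)
  df$age <- ifelse(df$group == "young", 30, 70)
  for (cl in item_columns) df[[cl]] <- rnorm(60)
  tab <- descriptive_compare(df)
  ord <- order(tab$p)
  expect_true(all(diff(tab$p_adj[ord]) >= -1e-15))
})

test_that("BH controls the false-discovery proportion over null variables", {
  set.seed(14)
  reps <- 300
  fdp <- replicate(reps, {
    df <- data.frame(group = rep(c("a", "b"), each = 30))
    for (k in 1:20) df[[paste0("v", k)]] <- rnorm(60)
    tab <- descriptive_compare(df)
    disc <- sum(tab$p_adj < 0.05)
    if (disc == 0) 0 else disc / max(disc, 1)
  })
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("two groups are required and tiny groups are rejected", {
  df <- tiny_item_df(6)
  df$group <- c("young", "middle", "old", "young", "middle", "old")
  expect_error(descriptive_compare(df), class = "bridgenet_input")
  df2 <- tiny_item_df(3)
  df2$group <- c("young", "young", "old")
  expect_error(descriptive_compare(df2), class = "bridgenet_insufficient_data")
})

test_that("covariates can enter the analysis matrix as nodes", {
  spec <- synthetic_spec(n_per_group = c(old = 200))
  ds <- simulate_items(spec, "old")
  pm <- preprocess(ds, covariates_as_nodes = TRUE)
  expect_equal(ncol(pm$values), 21)
  expect_true(all(c("sex", "education") %in% colnames(pm$values)))
  expect_false(pm$residualized)
  expect_lt(max(abs(colMeans(pm$values))), 1e-8)
  net <- suppressWarnings(ebic_glasso(pm))
  expect_equal(unname(net$domains[c("sex", "education")]),
               c("covariate", "covariate"))
  ct <- centrality_table(net)
  expect_equal(nrow(ct), 21)
})
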