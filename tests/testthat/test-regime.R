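make_panel <- function(sites, feature_cols, k = NULL) {
  structure(list(sites = sites, feature_cols = feature_cols, k = k),
            class = "gage_panel")
}

test_that("chained predictive mean matching imputes from observed donors", {
  df <- data.frame(a = c(1, 1, 1, 1), b = c(2, 2, 2, NA))
  p <- make_panel(df, c("a", "b"))
  out <- impute_missing(p, seed = 1)
  expect_equal(out$sites$b[4], 2)       # only one donor value exists

  complete <- make_panel(data.frame(a = 1:4, b = 4:1), c("a", "b"))
  expect_identical(impute_missing(complete, seed = 1), complete)

  allna <- make_panel(data.frame(a = 1:4, b = NA_real_), c("a", "b"))
  expect_error(impute_missing(allna, seed = 1), "imputation error")
})

test_that("PMM beats column-mean fill on correlated panels (2% MCAR)", {
  set.seed(42)
  n <- 300
  z <- rnorm(n)
  X <- sapply(1:5, function(j) z + rnorm(n, 0, 0.3))
  colnames(X) <- paste0("V", 1:5)
  truth <- X
  nmiss <- round(0.02 * length(X))
  holes <- sample(length(X), nmiss)
  X[holes] <- NA
  p <- make_panel(as.data.frame(X), colnames(X))
  imp <- as.matrix(impute_missing(p, seed = 7)$sites[colnames(X)])
  rmse_pmm <- sqrt(mean((imp[holes] - truth[holes])^2))
  meanfill <- X
  for (j in 1:5) meanfill[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
  rmse_mean <- sqrt(mean((meanfill[holes] - truth[holes])^2))
  expect_lt(rmse_pmm, rmse_mean)
})

test_that("dimension reduction projects onto orthogonal max-variance directions", {
  set.seed(1)
  basis <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
  scores_true <- matrix(rnorm(200), 100, 2) %*% diag(c(3, 1))
  X <- scores_true %*% t(basis)
  red <- reduce_dimensions(X, 2, scale. = FALSE)
  # rank-2 data: two components reconstruct exactly
  recon <- red$scores %*% t(red$rotation)
  recon <- sweep(recon, 2, -colMeans(X))
  expect_equal(recon, X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lte(sum(red$variance_fraction), 1 + 1e-12)
  expect_true(all(diff(red$variance_fraction) <= 1e-12))
  cv <- cov(red$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_error(reduce_dimensions(matrix(1, 10, 3), 2), "degenerate")
})

test_that("Ward clustering separates tight pairs and collapses duplicates", {
  X <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10, 10.1))
  w <- cluster_ward(X, 2)
  expect_equal(w$labels$k2[1], w$labels$k2[2])
  expect_equal(w$labels$k2[3], w$labels$k2[4])
  expect_false(w$labels$k2[1] == w$labels$k2[3])

  dup <- matrix(1, 6, 2)
  wd <- cluster_ward(dup, 2)
  expect_true(all(wd$hclust$height == 0))
  expect_error(cluster_ward(X, 10), "value error")
})

test_that("Ward cuts attain the exhaustive minimum-SSE partition for small separated data", {
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(2:3, 1)
    centers <- matrix(c(0, 0, 8, 0, 0, 8), 3, 2, byrow = TRUE)[1:k, , drop = FALSE]
    n <- 7
    lab <- sample(rep(1:k, length.out = n))
    X <- centers[lab, , drop = FALSE] + matrix(rnorm(2 * n, 0, 0.5), n, 2)
    w <- cluster_ward(X, k)
    got <- partition_sse(X, w$labels[[paste0("k", k)]])
    best <- brute_min_sse_partition(X, k)
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("cuts are nested: coarser solutions merge whole finer classes", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  w <- cluster_ward(X, c(2, 4, 8))
  for (pair in list(c("k4", "k2"), c("k8", "k4"))) {
    fine <- w$labels[[pair[1]]]; coarse <- w$labels[[pair[2]]]
    for (g in unique(fine))
      expect_length(unique(coarse[fine == g]), 1)
  }
})

test_that("elbow candidates track curvature of the within-cluster SSE profile", {
  # fabricate a merge history with a sharp elbow at k = 4:
  # m[k] = SSE cost of merging k+1 -> k clusters, large for k <= 3 only
  m <- c(45, 40, 35, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  inc <- rev(m)                                    # merge order: low to high
  hc <- structure(list(height = sqrt(2 * inc),
                       merge = matrix(0, 9, 2),
                       order = 1:10),
                  class = "hclust")
  cand <- select_cluster_counts(hc, k_max = 8)
  expect_equal(cand[1], 4L)
  # linear decline in SSE: zero curvature, no candidates
  hc2 <- structure(list(height = sqrt(2 * rep(1, 9)), merge = matrix(0, 9, 2),
                        order = 1:10), class = "hclust")
  expect_length(select_cluster_counts(hc2, k_max = 8), 0)
})

test_that("reference screening applies all four rules with strict DOR", {
  s <- data.frame(
    site_id = 1:7,
    disturbance = c("low", "low", "very low", "moderate", "low", "low", NA),
    dor_percent = c(2, 4.0, 1, 1, 3.9, 2, 2),
    record_start = c(2005, 2000, 2000, 2000, 1995, 1994, 2000),
    record_end = c(2010, 2010, 2010, 2010, 2015, 2010, 2010),
    max_consec_ja_days = c(62, 62, 59, 62, 60, 62, 62))
  p <- make_panel(s, character(0))
  out <- screen_reference_sites(p)
  expect_equal(out$sites$site_id, c(1L, 5L))   # 1995/2015 endpoints inclusive
  log <- attr(out, "screen_log")
  expect_equal(log$reason[log$site_id == 2], "DOR >= 4%")
  expect_equal(log$reason[log$site_id == 3], "fewer than 60 consecutive days")
  expect_equal(log$reason[log$site_id == 6], "record outside 1995-2015")
  expect_equal(log$reason[log$site_id == 7], "missing attribute")
})

test_that("class extrapolation: low OOB on separable panels, chance on permuted labels", {
  cfg <- generator_config(n_reaches = 400, seed = 51)
  net <- attach_physical_attributes(generate_dendritic_network(cfg), cfg)
  p <- generate_gage_panel(net, n_sites = 300, k_clusters = 4, separation = 8,
                           seed = 52)
  m <- fit_class_extrapolator(p, seed = 53)
  expect_lte(m$oob_error, 0.05)
  expect_true(all(m$importance >= 0 & m$importance <= 1))
  expect_equal(max(m$importance), 1)

  set.seed(54)
  perm <- sample(p$sites$true_label)
  mp <- fit_class_extrapolator(p, labels = perm, seed = 55)
  null_err <- 1 - 1 / 4
  se <- sqrt(null_err * (1 - null_err) / 300)
  expect_lt(abs(mp$oob_error - null_err), 5 * se)

  one <- p; one$sites$true_label <- 1L
  expect_error(fit_class_extrapolator(one, seed = 1), "degenerate")
})

test_that("membership probabilities are vote fractions summing to one", {
  cfg <- generator_config(n_reaches = 300, seed = 61)
  net <- attach_physical_attributes(generate_dendritic_network(cfg), cfg)
  p <- generate_gage_panel(net, n_sites = 200, k_clusters = 3, separation = 7,
                           seed = 62)
  m <- fit_class_extrapolator(p, seed = 63)
  a <- predict_class_membership(m, p$network)
  pv <- as.matrix(a[paste0("prob_", m$levels)])
  expect_equal(unname(rowSums(pv)), rep(1, nrow(pv)), tolerance = 1e-9)
  expect_true(all(a$predominant_prob >= 1 / 3 - 1e-12))
  expect_gt(median(a$predominant_prob), compute_expected_probability(3))
  # labels equal the arg-max of the vote vector
  expect_identical(a$label, m$levels[max.col(pv, ties.method = "first")])
})

test_that("expected probability is 1/k rounded to two decimals", {
  expect_identical(compute_expected_probability(2), 0.5)
  expect_identical(compute_expected_probability(1), 1)
  expect_identical(compute_expected_probability(30), 0.03)
  expect_identical(compute_expected_probability(8), 0.13)
  expect_error(compute_expected_probability(0), "value error")
})

test_that("temperature regressor is accurate on noiseless panels and guards qwsa", {
  cfg <- generator_config(n_reaches = 400, seed = 71)
  net <- attach_physical_attributes(generate_dendritic_network(cfg), cfg)
  p <- generate_temperature_sites(net, n_sites = 500, noise_sd = 0, seed = 72)
  m <- fit_temperature_regressor(p, seed = 73)
  expect_gte(m$oob_r2, 0.9)
  expect_false("qwsa" %in% m$features)
  expect_error(fit_temperature_regressor(p, seed = 73,
                                         features = p$feature_cols),
               "guard error")
  # constant target predicts the constant
  pc <- p; pc$sites$july_august_temp <- 15
  mc <- suppressWarnings(fit_temperature_regressor(pc, seed = 74))
  pred <- predict_temperature(mc, net)
  expect_equal(unname(pred), rep(15, length(pred)), tolerance = 1e-9)
})

test_that("probability diagnostics summarise per-solution accuracy", {
  a <- data.frame(COMID = 1:3, label = c("1", "2", "1"),
                  predominant_prob = c(0.7, 0.6, 0.8))
  attr(a, "k") <- 2; attr(a, "oob_error") <- 0.1
  class(a) <- c("class_assignment", "data.frame")
  d <- summarize_assignment_probabilities(list(W2 = a))
  expect_equal(d$median_prob, 0.7)
  expect_equal(d$oob_error_pct + d$accuracy_pct, 100)
  expect_equal(d$expected_prob, 0.5)
  expect_equal(d$n, 3L)
})
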