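#' Impute missing panel entries by chained predictive mean matching
#'
#' Iterates over incomplete feature columns; each is regressed (ordinary
#' least squares) on the other features over its observed rows, and every
#' missing entry is replaced by the observed value of one of the `k_donors`
#' nearest neighbours in predicted value, drawn at random. Deterministic
#' given `seed`.
#'
#' @param panel a `gage_panel`
#' @param k_donors donor pool size (default 5)
#' @param max_iter number of chained passes (default 5)
#' @param seed integer seed
#' @return the panel with a complete feature matrix
#' @export
impute_missing <- function(panel, k_donors = 5, max_iter = 5, seed) {
  stopifnot(inherits(panel, "gage_panel"))
  if (missing(seed)) stop("config error: seed is required", call. = FALSE)
  cols <- panel$feature_cols
  X <- as.matrix(panel$sites[cols])
  M <- is.na(X)
  if (!any(M)) return(panel)
  all_missing <- colSums(!M) == 0L
  if (any(all_missing))
    stop("imputation error: column(s) entirely missing: ",
         paste(cols[all_missing], collapse = ", "), call. = FALSE)
  set.seed(seed)
  # initial fill: column means of observed values
  for (j in which(colSums(M) > 0L))
    X[M[, j], j] <- mean(X[!M[, j], j])
  incomplete <- which(colSums(M) > 0L)
  for (iter in seq_len(max_iter)) {
    for (j in incomplete) {
      obs <- !M[, j]
      Z <- cbind(1, X[, -j, drop = FALSE])
      fit <- stats::lm.fit(Z[obs, , drop = FALSE], X[obs, j])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred <- drop(Z %*% beta)
      yobs <- X[obs, j]
      pobs <- pred[obs]
      for (i in which(M[, j])) {
        d <- abs(pobs - pred[i])
        donors <- order(d)[seq_len(min(k_donors, length(d)))]
        X[i, j] <- yobs[sample_vec(donors, 1L)]
      }
    }
  }
  panel$sites[cols] <- as.data.frame(X)
  panel
}

#' Principal-component reduction of a hydrologic statistics matrix
#'
#' Projects a complete site-by-statistic matrix onto the `n_components`
#' orthonormal directions of maximal variance (columns centred; scaled to
#' unit variance by default, as statistics are on heterogeneous scales).
#'
#' @param x complete numeric matrix (sites x statistics)
#' @param n_components number of component scores to keep
#' @param scale. scale columns to unit variance before projection
#' @return list with `scores` (sites x n_components), `variance_fraction`
#'   (non-increasing, sums to <= 1) and `rotation`
#' @export
reduce_dimensions <- function(x, n_components, scale. = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("value error: matrix must be complete (impute first)", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0))
    stop("degenerate-input error: constant matrix", call. = FALSE)
  if (scale. && any(sds == 0)) {
    x <- x[, sds > 0, drop = FALSE]   # constant columns carry no information
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(p$x))
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       variance_fraction = vf[seq_len(k)],
       rotation = p$rotation[, seq_len(k), drop = FALSE])
}

#' Ward minimum-variance clustering with nested cuts
#'
#' Agglomerates sites by Ward's minimum-variance criterion (squared
#' Euclidean merge cost via the standard Lance-Williams recursive update)
#' and cuts the single dendrogram at each requested class count. Because all
#' cuts come from one merge history, coarser solutions merge whole classes
#' of finer ones (nesting).
#'
#' @param scores numeric matrix (sites x features)
#' @param k_list integer vector of class counts to cut at
#' @return object of class `ward_solutions`: list with `hclust` (the merge
#'   history), `k_list`, `labels` (named list, one integer vector per k) and
#'   `parent` (named list mapping each finer solution's classes to the next
#'   coarser solution's classes)
#' @export
cluster_ward <- function(scores, k_list) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k_list <- sort(unique(as.integer(k_list)))
  if (any(k_list > n)) stop("value error: k exceeds number of sites", call. = FALSE)
  if (any(k_list < 1)) stop("value error: k must be >= 1", call. = FALSE)
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  labels <- lapply(k_list, function(k) stats::cutree(hc, k))
  names(labels) <- paste0("k", k_list)
  parent <- list()
  if (length(k_list) > 1L) {
    for (i in seq_len(length(k_list) - 1L)) {
      fine <- labels[[i + 1L]]; coarse <- labels[[i]]
      map <- tapply(coarse, fine, function(v) v[1])
      parent[[paste0("k", k_list[i + 1L], "_to_k", k_list[i])]] <-
        as.integer(map)
    }
  }
  structure(list(hclust = hc, k_list = k_list, labels = labels,
                 parent = parent, n = n),
            class = "ward_solutions")
}

#' @export
print.ward_solutions <- function(x, ...) {
  cat("<ward_solutions> n =", x$n, " cuts at k =",
      paste(x$k_list, collapse = ", "), "\n")
  invisible(x)
}

# within-cluster SSE profile over k = 1..k_max, from Ward merge heights:
# each ward.D2 merge at height h increases the SSE by h^2 / 2
ward_wss_profile <- function(hc, k_max) {
  n <- length(hc$height) + 1L
  inc <- hc$height^2 / 2
  total <- sum(inc)
  # WSS at k clusters: the first n-k merges have been performed
  vapply(seq_len(k_max), function(k) {
    if (k >= n) 0
    else if (k == 1L) total
    else total - sum(inc[(n - k + 1L):(n - 1L)])
  }, numeric(1))
}

#' Elbow candidates for the number of clusters
#'
#' Computes the within-cluster sum-of-squares profile over `k = 1..k_max`
#' from the Ward merge heights and returns the local maxima of its second
#' difference (curvature) as candidate class counts, largest curvature
#' first. A linear decline has no curvature and yields no candidates; the
#' list is advisory and the user's `k_list` remains authoritative.
#'
#' @param ward a `ward_solutions` or `hclust` object
#' @param k_max largest class count to consider
#' @return integer vector of candidate k, ordered by decreasing curvature;
#'   the profile is attached as attribute `"wss"`
#' @export
select_cluster_counts <- function(ward, k_max = 15) {
  hc <- if (inherits(ward, "ward_solutions")) ward$hclust else ward
  stopifnot(inherits(hc, "hclust"))
  k_max <- min(k_max, length(hc$height))
  wss <- ward_wss_profile(hc, k_max + 1L)
  ks <- 2:k_max
  d2 <- wss[ks - 1L] - 2 * wss[ks] + wss[ks + 1L]
  is_max <- vapply(seq_along(ks), function(i) {
    left <- if (i == 1L) TRUE else d2[i] > d2[i - 1L]
    right <- if (i == length(ks)) TRUE else d2[i] > d2[i + 1L]
    left && right && d2[i] > .Machine$double.eps * max(abs(wss), 1)
  }, logical(1))
  cand <- ks[is_max][order(d2[is_max], decreasing = TRUE)]
  attr(cand, "wss") <- wss
  cand
}

#' Screen temperature sites for reference (least-disturbed) condition
#'
#' Keeps sites satisfying all of: land-disturbance score "very low" or
#' "low"; degree of regulation strictly below 4% of annual discharge stored
#' by upstream dams; period of record within 1995 to 2015 (inclusive both
#' ends); at least 60 consecutive days of July-August record. Sites with a
#' missing screening attribute are excluded, with the reason logged.
#'
#' @param panel a `gage_panel` whose sites carry `disturbance`,
#'   `dor_percent`, `record_start`, `record_end`, `max_consec_ja_days`
#' @return the panel with `sites` filtered to reference sites; the excluded
#'   site ids and their first failing rule are in `attr(, "screen_log")`
#' @export
screen_reference_sites <- function(panel) {
  stopifnot(inherits(panel, "gage_panel"))
  s <- panel$sites
  need <- c("disturbance", "dor_percent", "record_start", "record_end",
            "max_consec_ja_days")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("schema error: sites lack screening attribute(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  reason <- rep(NA_character_, nrow(s))
  mark <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  has_na <- Reduce(`|`, lapply(s[need], is.na))
  reason <- mark(has_na, "missing attribute")
  reason <- mark(!s$disturbance %in% c("very low", "low"), "disturbance")
  reason <- mark(!(s$dor_percent < 4), "DOR >= 4%")
  reason <- mark(!(s$record_start >= 1995 & s$record_end <= 2015),
                 "record outside 1995-2015")
  reason <- mark(!(s$max_consec_ja_days >= 60), "fewer than 60 consecutive days")
  keep <- is.na(reason)
  log <- data.frame(site_id = s$site_id[!keep], reason = reason[!keep])
  panel$sites <- s[keep, , drop = FALSE]
  attr(panel, "screen_log") <- log
  panel
}

#' Fit a random-forest class extrapolator
#'
#' Trains a bagged classification-tree ensemble on the panel's feature
#' columns to predict class labels, reporting the out-of-bag
#' misclassification rate and per-feature importance normalised to `[0, 1]`
#' (min-max scaled, most important = 1).
#'
#' @param panel a `gage_panel` with a complete feature matrix
#' @param labels integer class label per site; defaults to the panel's
#'   `true_label` column
#' @param seed integer seed
#' @param ntree ensemble size (default 500)
#' @return object of class `class_extrapolator`: list with `model`,
#'   `oob_error` (fraction), `importance` (named, in `[0, 1]`),
#'   `feature_cols`, `levels`, `k`
#' @export
fit_class_extrapolator <- function(panel, labels = NULL, seed, ntree = 500) {
  stopifnot(inherits(panel, "gage_panel"))
  if (missing(seed)) stop("config error: seed is required", call. = FALSE)
  if (is.null(labels)) labels <- panel$sites$true_label
  if (is.null(labels)) stop("value error: no labels supplied", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("degenerate error: need at least 2 classes", call. = FALSE)
  if (any(tab < 5L))
    stop("value error: every class needs at least 5 sites", call. = FALSE)
  X <- panel$sites[panel$feature_cols]
  if (anyNA(X))
    stop("value error: features incomplete; run impute_missing first",
         call. = FALSE)
  y <- factor(labels, levels = sort(unique(labels)))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = ntree,
                                   importance = FALSE)
  imp <- rf$importance[, "MeanDecreaseGini"]
  rng <- range(imp)
  imp_norm <- if (diff(rng) == 0) stats::setNames(rep(1, length(imp)), names(imp))
              else (imp - rng[1]) / diff(rng)
  structure(list(model = rf,
                 oob_error = unname(rf$err.rate[ntree, "OOB"]),
                 importance = imp_norm,
                 feature_cols = panel$feature_cols,
                 levels = levels(y), k = length(levels(y))),
            class = "class_extrapolator")
}

#' Extrapolate class membership to every reach
#'
#' Applies a fitted [fit_class_extrapolator()] model to the reach feature
#' table. The probability vector of a reach is the fraction of trees voting
#' for each class; the label is the arg-max, ties broken towards the lowest
#' class index. Reaches with missing features are labelled
#' `"unclassified"` with `NA` probabilities.
#'
#' @param model a `class_extrapolator`
#' @param net a `stream_network` whose reach table carries the model's
#'   feature columns
#' @return data.frame of class `class_assignment`: `COMID`, `label`,
#'   `predominant_prob` and one `prob_<class>` column per class; attributes
#'   `k` and `oob_error` carry the model diagnostics
#' @export
predict_class_membership <- function(model, net) {
  stopifnot(inherits(model, "class_extrapolator"))
  feats <- model$feature_cols
  miss <- setdiff(feats, names(net$reaches))
  if (length(miss))
    stop("schema error: reach table lacks feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- net$reaches[feats]
  ok <- stats::complete.cases(X)
  n <- nrow(X)
  k <- model$k
  votes <- matrix(NA_real_, n, k, dimnames = list(NULL, model$levels))
  if (any(ok))
    votes[ok, ] <- stats::predict(
      model$model, X[ok, , drop = FALSE], type = "vote")
  label <- rep("unclassified", n)
  pred <- rep(NA_real_, n)
  if (any(ok)) {
    amax <- apply(votes[ok, , drop = FALSE], 1, which.max)  # first max: lowest index
    label[ok] <- model$levels[amax]
    pred[ok] <- votes[ok, , drop = FALSE][cbind(seq_len(sum(ok)), amax)]
  }
  out <- data.frame(COMID = net$reaches$comid, label = label,
                    predominant_prob = pred)
  pv <- as.data.frame(votes)
  names(pv) <- paste0("prob_", model$levels)
  out <- cbind(out, pv)
  class(out) <- c("class_assignment", "data.frame")
  attr(out, "k") <- k
  attr(out, "oob_error") <- model$oob_error
  out
}

#' Expected probability of predominant class assignment
#'
#' The chance level against which vote-fraction probabilities are judged:
#' `1/k` for a `k`-class solution, reported rounded to two decimals.
#' Rounding is half-up (0.125 reports as 0.13), the convention of the
#' published diagnostic tables, not IEEE round-half-even.
#'
#' @param k class count (>= 1)
#' @return `1/k` rounded half-up to two decimals
#' @export
compute_expected_probability <- function(k) {
  if (any(k < 1)) stop("value error: k must be >= 1", call. = FALSE)
  floor(100 / k + 0.5) / 100
}

#' Fit a random-forest summer temperature regressor
#'
#' Trains a bagged regression-tree ensemble predicting mean July-August
#' water temperature from reach covariates. `qwsa` (mean annual flow per
#' unit drainage area) must not be among the features: temperature is a
#' function of river size, and including a size-standardised discharge term
#' is explicitly guarded against.
#'
#' @param panel a `gage_panel` of (typically screened) temperature sites
#'   with a `july_august_temp` column
#' @param seed integer seed
#' @param features feature columns; defaults to the panel's features minus
#'   `qwsa`. Supplying a set containing `qwsa` is an error.
#' @param ntree ensemble size (default 500)
#' @return object of class `temperature_model`: list with `model`,
#'   `oob_r2`, `oob_mse`, `features`
#' @export
fit_temperature_regressor <- function(panel, seed,
                                      features = setdiff(panel$feature_cols, "qwsa"),
                                      ntree = 500) {
  stopifnot(inherits(panel, "gage_panel"))
  if (missing(seed)) stop("config error: seed is required", call. = FALSE)
  if ("qwsa" %in% features)
    stop("guard error: qwsa must be excluded from temperature features",
         call. = FALSE)
  if (!"july_august_temp" %in% names(panel$sites))
    stop("schema error: sites lack july_august_temp", call. = FALSE)
  X <- panel$sites[features]
  y <- panel$sites$july_august_temp
  if (anyNA(X) || anyNA(y))
    stop("value error: features/target incomplete", call. = FALSE)
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = ntree)
  structure(list(model = rf,
                 oob_r2 = rf$rsq[ntree],
                 oob_mse = rf$mse[ntree],
                 features = features),
            class = "temperature_model")
}

#' Predict July-August temperature for every reach
#'
#' @param model a `temperature_model`
#' @param net a `stream_network` with the model's feature columns
#' @return named numeric vector, comid -> predicted temperature (degrees C);
#'   `NA` where features are missing
#' @export
predict_temperature <- function(model, net) {
  stopifnot(inherits(model, "temperature_model"))
  X <- net$reaches[model$features]
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok))
    out[ok] <- stats::predict(model$model,
                                                   X[ok, , drop = FALSE])
  stats::setNames(out, as.character(net$reaches$comid))
}

#' Summarise class-assignment probability diagnostics
#'
#' One row per cluster solution: class count, number of assigned reaches,
#' out-of-bag error and its complement (accuracy), the median probability of
#' the predominant class over reaches, and the expected (chance)
#' probability `1/k`.
#'
#' @param assignments a named list of [predict_class_membership()] results
#' @return data.frame with columns `solution`, `k`, `n`, `oob_error_pct`,
#'   `accuracy_pct`, `median_prob`, `expected_prob`
#' @export
summarize_assignment_probabilities <- function(assignments) {
  if (inherits(assignments, "class_assignment"))
    assignments <- list(assignments)
  rows <- lapply(seq_along(assignments), function(i) {
    a <- assignments[[i]]
    k <- attr(a, "k")
    oob <- attr(a, "oob_error")
    ok <- a$label != "unclassified"
    data.frame(solution = names(assignments)[i] %||% paste0("solution", i),
               k = k, n = sum(ok),
               oob_error_pct = 100 * oob,
               accuracy_pct = 100 - 100 * oob,
               median_prob = stats::median(a$predominant_prob[ok]),
               expected_prob = compute_expected_probability(k))
  })
  do.call(rbind, rows)
}
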