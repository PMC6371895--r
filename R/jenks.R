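#' Fisher-Jenks optimal univariate breaks
#'
#' Exact dynamic-programming (Fisher) solution of the natural-breaks
#' problem: partition the sorted values into `k` contiguous classes
#' minimising the total within-class sum of squared deviations about class
#' means. Deterministic; ties in the optimal split position are broken
#' towards the smallest split index.
#'
#' @param values finite numeric vector, `length(values) >= k`
#' @param k number of classes, `>= 2`
#' @return object of class `jenks_result`: list with `k`, `breaks` (the
#'   maximum value of each of the first `k - 1` classes, ascending),
#'   `classes` (class index per input value, in input order), `ssd`
#'   (minimised within-class sum of squared deviations), `gvf` and
#'   `tabular_accuracy` (see [break_diagnostics()])
#' @export
jenks_breaks <- function(values, k) {
  if (any(!is.finite(values))) stop("value error: values must be finite", call. = FALSE)
  n <- length(values)
  if (k < 2) stop("value error: k must be >= 2", call. = FALSE)
  if (k > n) stop("value error: k exceeds number of values", call. = FALSE)
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  # ssd of sorted segment i..j (1-based, inclusive)
  seg_ssd <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # D[c, i]: min total ssd of first i values in c classes
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)              # start index of the last class
  D[1, ] <- vapply(seq_len(n), function(i) seg_ssd(1, i), numeric(1))
  B[1, ] <- 1L
  for (cl in 2:k) {
    for (i in cl:n) {
      js <- cl:i                     # candidate starts of the last class
      segs <- {
        s <- cs[i] - cs[js - 1]
        s2 <- cs2[i] - cs2[js - 1]
        s2 - s^2 / (i - js + 1)
      }
      tot <- D[cl - 1, js - 1] + segs
      best <- which.min(tot)         # first minimum -> smallest start
      D[cl, i] <- tot[best]
      B[cl, i] <- js[best]
    }
  }
  # recover class boundaries
  bounds <- integer(k + 1)           # bounds[c]..bounds[c+1]-1 is class c
  bounds[k + 1] <- n + 1L
  i <- n
  for (cl in k:1) {
    bounds[cl] <- B[cl, i]
    i <- B[cl, i] - 1L
  }
  cls_sorted <- rep(seq_len(k), diff(bounds))
  classes <- integer(n)
  classes[ord] <- cls_sorted
  breaks <- x[bounds[2:k] - 1L]      # max value of each non-terminal class
  diag <- break_diagnostics(values, breaks)
  structure(list(k = k, breaks = breaks, classes = classes,
                 ssd = D[k, n], gvf = diag[["gvf"]],
                 tabular_accuracy = diag[["tabular_accuracy"]]),
            class = "jenks_result")
}

#' @export
print.jenks_result <- function(x, ...) {
  cat("<jenks_result> k =", x$k,
      " gvf =", round(x$gvf, 4),
      " tabular accuracy =", round(x$tabular_accuracy, 4), "\n")
  cat("  class maxima:", paste(signif(x$breaks, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Goodness-of-variance-fit and tabular accuracy of a univariate partition
#'
#' `gvf = 1 - SDCM / SDAM` where SDAM is the sum of squared deviations about
#' the grand mean and SDCM the sum of squared deviations about class means.
#' Tabular accuracy is the absolute-deviation analogue:
#' `1 - (sum |x - class mean|) / (sum |x - grand mean|)`. Constant data
#' (zero total deviation) scores 1 by convention.
#'
#' @param values finite numeric vector
#' @param breaks ascending interior boundaries (values `<= breaks[1]` form
#'   class 1, etc.; each break is interpreted as the maximum of its class,
#'   i.e. right-closed)
#' @return named numeric vector `c(gvf = , tabular_accuracy = )`
#' @export
break_diagnostics <- function(values, breaks) {
  if (is.unsorted(breaks)) stop("value error: breaks must be ascending", call. = FALSE)
  cls <- findInterval(values, breaks, left.open = TRUE) + 1L
  gm <- mean(values)
  sdam <- sum((values - gm)^2)
  adam <- sum(abs(values - gm))
  cm <- tapply(values, cls, mean)
  dev <- values - cm[as.character(cls)]
  sdcm <- sum(dev^2)
  adcm <- sum(abs(dev))
  gvf <- if (sdam == 0) 1 else 1 - sdcm / sdam
  ta <- if (adam == 0) 1 else 1 - adcm / adam
  c(gvf = gvf, tabular_accuracy = ta)
}

#' Select a parsimonious class count from Jenks diagnostics
#'
#' Runs [jenks_breaks()] across `k_range` and returns the smallest `k` at
#' which both goodness-of-variance-fit and tabular accuracy have plateaued:
#' the gain from `k` to `k + 1` is below `plateau_delta` on both
#' diagnostics. If no plateau occurs in range, the largest `k` is returned
#' with a warning.
#'
#' @param values finite numeric vector
#' @param k_range integer range of class counts to scan (within 2..20)
#' @param plateau_delta plateau threshold on the diagnostic gain (default
#'   0.02)
#' @return the selected `k`, with the per-`k` diagnostics attached as
#'   attribute `"diagnostics"` (data.frame: k, gvf, tabular_accuracy)
#' @export
select_parsimonious_k <- function(values, k_range = 2:20, plateau_delta = 0.02) {
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > 20)
    stop("value error: k_range must lie within 2..20", call. = FALSE)
  res <- lapply(k_range, function(k) jenks_breaks(values, k))
  diag <- data.frame(k = k_range,
                     gvf = vapply(res, `[[`, numeric(1), "gvf"),
                     tabular_accuracy = vapply(res, `[[`, numeric(1),
                                               "tabular_accuracy"))
  sel <- NA_integer_
  for (i in seq_len(nrow(diag) - 1L)) {
    if (diag$k[i + 1L] == diag$k[i] + 1L &&
        diag$gvf[i + 1L] - diag$gvf[i] < plateau_delta &&
        diag$tabular_accuracy[i + 1L] - diag$tabular_accuracy[i] < plateau_delta) {
      sel <- diag$k[i]
      break
    }
  }
  if (is.na(sel)) {
    warning("no diagnostic plateau within k_range; returning max(k_range)")
    sel <- max(k_range)
  }
  attr(sel, "diagnostics") <- diag
  sel
}

#' Assign fixed-interval classes
#'
#' Lower-inclusive / upper-exclusive binning of values against ascending
#' thresholds (the convention shared by the size, gradient and temperature
#' layers). `NA` values map to `"unclassified"`.
#'
#' @param values numeric vector
#' @param thresholds strictly ascending interior thresholds
#' @param labels class labels, one more than thresholds
#' @return character vector of labels, one per value
#' @export
assign_interval_classes <- function(values, thresholds, labels) {
  bin_classes(values, thresholds, labels)
}
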