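#' Packaged default class thresholds
#'
#' Discharge-based size classes, Rosgen-style gradient classes and average
#' summer (July-August) temperature classes, as shipped with the national
#' classification. Bins are lower-inclusive / upper-exclusive throughout,
#' with the last bin open above.
#'
#' @return a list with elements `size` (breaks in m^3/s and the eight class
#'   labels HW, SC, LC, SR, MR, MS, LR, GR), `gradient` (dimensionless
#'   rise/run breaks, labels VL, L, M, MH, H, S) and `temperature` (degrees
#'   C, labels VC, CD, CC, CL, CW, W)
#' @export
default_thresholds <- function() {
  list(
    size = list(breaks = c(0.057, 0.283, 1.133, 5.663, 22.65, 70.79, 283.2),
                labels = c("HW", "SC", "LC", "SR", "MR", "MS", "LR", "GR")),
    gradient = list(breaks = c(0.001, 0.005, 0.02, 0.04, 0.1),
                    labels = c("VL", "L", "M", "MH", "H", "S")),
    temperature = list(breaks = c(10, 15, 18, 21, 24),
                       labels = c("VC", "CD", "CC", "CL", "CW", "W"))
  )
}

size_class_labels <- function() default_thresholds()$size$labels

#' Derive discharge size-class thresholds from order medians
#'
#' Computes the median discharge of each Strahler order present in the
#' network and takes mid-points between medians of consecutive orders as the
#' class thresholds: `breaks[i] = (median(order_i) + median(order_{i+1})) / 2`.
#'
#' @param net a `stream_network` with orders and discharge on every reach
#' @return object of class `size_thresholds`: list with `medians`
#'   (named by order), `breaks` (ascending, m^3/s) and `labels` (the first
#'   `length(breaks) + 1` of the standard eight size labels)
#' @export
derive_size_thresholds <- function(net) {
  r <- net$reaches
  if (anyNA(r$strahler_order) || anyNA(r$mean_annual_q))
    stop("derivation error: order or discharge missing on some reaches",
         call. = FALSE)
  ords <- sort(unique(r$strahler_order))
  if (length(ords) < 2)
    stop("derivation error: fewer than 2 stream orders present", call. = FALSE)
  med <- vapply(ords, function(o) stats::median(r$mean_annual_q[r$strahler_order == o]),
                numeric(1))
  names(med) <- as.character(ords)
  if (any(diff(med) <= 0)) {
    bad <- ords[which(diff(med) <= 0)]
    stop("data error: order medians not strictly increasing at order(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  breaks <- (med[-length(med)] + med[-1]) / 2
  labels <- size_class_labels()[seq_len(length(breaks) + 1)]
  structure(list(medians = med, breaks = unname(breaks), labels = labels),
            class = "size_thresholds")
}

#' @export
print.size_thresholds <- function(x, ...) {
  cat("<size_thresholds>", length(x$labels), "classes\n")
  cat("  medians by order:", paste(names(x$medians),
      signif(x$medians, 4), sep = "=", collapse = " "), "\n")
  cat("  breaks (m^3/s):", paste(signif(x$breaks, 4), collapse = ", "), "\n")
  invisible(x)
}

# lower-inclusive / upper-exclusive binning shared by all univariate layers;
# NA maps to "unclassified"
bin_classes <- function(x, breaks, labels) {
  if (length(labels) != length(breaks) + 1L)
    stop("value error: need one more label than breaks", call. = FALSE)
  if (is.unsorted(breaks, strictly = TRUE))
    stop("value error: thresholds must be strictly ascending", call. = FALSE)
  idx <- findInterval(x, breaks, left.open = FALSE) + 1L
  out <- ifelse(is.na(x), "unclassified", labels[idx])
  out
}

#' Assign discharge size classes
#'
#' Bins every reach's mean annual discharge into a size class. Bins are
#' lower-inclusive / upper-exclusive; the last bin is open above. Reaches
#' with missing discharge are labelled `"unclassified"`.
#'
#' @param net a `stream_network`
#' @param thresholds a [derive_size_thresholds()] result, or `NULL` to use
#'   the packaged national defaults
#' @return data.frame of class `class_assignment` with columns `COMID`,
#'   `size_class`, `StreamOrde`, `Q_m3s`
#' @export
assign_size_classes <- function(net, thresholds = NULL) {
  q <- net$reaches$mean_annual_q
  if (any(q < 0, na.rm = TRUE))
    stop("value error: negative discharge", call. = FALSE)
  if (is.null(thresholds)) {
    def <- default_thresholds()$size
    breaks <- def$breaks; labels <- def$labels
  } else {
    stopifnot(inherits(thresholds, "size_thresholds"))
    breaks <- thresholds$breaks; labels <- thresholds$labels
  }
  out <- data.frame(COMID = net$reaches$comid,
                    size_class = bin_classes(q, breaks, labels),
                    StreamOrde = net$reaches$strahler_order,
                    Q_m3s = q)
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Assign gradient classes
#'
#' Bins every reach's slope (rise/run) into the six gradient classes, with
#' the same lower-inclusive boundary convention as the size layer. Missing
#' slope yields `"unclassified"`.
#'
#' @param net a `stream_network`
#' @return data.frame of class `class_assignment` with columns `COMID`,
#'   `gradient_class`, `slope`
#' @export
assign_gradient_classes <- function(net) {
  s <- net$reaches$slope
  if (any(s < 0, na.rm = TRUE))
    stop("value error: negative slope", call. = FALSE)
  def <- default_thresholds()$gradient
  out <- data.frame(COMID = net$reaches$comid,
                    gradient_class = bin_classes(s, def$breaks, def$labels),
                    slope = s)
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Combined size-and-gradient layer table
#'
#' Convenience wrapper producing the layer export schema: COMID, size class,
#' gradient class, order, discharge, slope.
#'
#' @inheritParams assign_size_classes
#' @return data.frame with columns `COMID`, `size_class`, `gradient_class`,
#'   `StreamOrde`, `Q_m3s`, `slope`
#' @export
size_gradient_table <- function(net, thresholds = NULL) {
  sz <- assign_size_classes(net, thresholds)
  gr <- assign_gradient_classes(net)
  data.frame(COMID = sz$COMID, size_class = sz$size_class,
             gradient_class = gr$gradient_class,
             StreamOrde = sz$StreamOrde, Q_m3s = sz$Q_m3s, slope = gr$slope)
}
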