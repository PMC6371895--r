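#' Flood-stage parameters
#'
#' Bankfull depth is modelled as `a * A^b * P^c` with `A` drainage area
#' (km^2) and `P` mean annual precipitation (mm); flood height is a fixed
#' multiple of bankfull depth (default 5x). The coefficient defaults are
#' demonstration values for synthetic terrain; applications should supply
#' regionally calibrated coefficients.
#'
#' @param a,b,c bankfull-depth coefficients (`a > 0`)
#' @param multiplier flood height as a multiple of bankfull depth (`> 0`)
#' @return list of class `flood_stage_params`
#' @export
flood_stage_params <- function(a = 0.2, b = 0.3, c = 0.05, multiplier = 5) {
  if (a <= 0) stop("value error: coefficient a must be positive", call. = FALSE)
  if (multiplier <= 0) stop("value error: multiplier must be positive", call. = FALSE)
  structure(list(a = a, b = b, c = c, multiplier = multiplier),
            class = "flood_stage_params")
}

#' Flood height above the channel
#'
#' `multiplier * a * A^b * P^c`: the empirical bankfull depth scaled to a
#' flood stage. Monotone increasing in both area and precipitation when
#' `b, c > 0`.
#'
#' @param area drainage area, km^2 (`> 0`)
#' @param precip mean annual precipitation, mm (`> 0`)
#' @param params a [flood_stage_params()]
#' @return flood height in metres
#' @export
flood_stage <- function(area, precip, params = flood_stage_params()) {
  stopifnot(inherits(params, "flood_stage_params"))
  if (any(area <= 0) || any(precip <= 0))
    stop("value error: area and precipitation must be positive", call. = FALSE)
  params$multiplier * params$a * area^params$b * precip^params$c
}

#' Delineate a valley bottom by flood-height intersection
#'
#' Floods outward from the stream cells: a cell joins the valley bottom when
#' it is 4-connected to the stream and its elevation does not exceed the
#' elevation of the stream cell it floods from plus the flood height.
#' Waterbody cells are excluded from the mask (no delineation in inundated
#' areas). Per-reach summaries follow the area/length bookkeeping: valley
#' width is valley-bottom area divided by valley-bottom length.
#'
#' @param dem a DEM tile as produced by [make_dem_tile()]: list with `elev`
#'   matrix, `stream` (row/col matrix), `waterbody` logical matrix,
#'   `cell_size` in metres
#' @param flood_height height above the local stream elevation, metres
#' @return list with `mask` (logical matrix), `vb_area_m2`, `vb_length_m`,
#'   `vb_width_m` (area / length) and `coverage` (fraction of stream cells
#'   whose cross-section is covered)
#' @export
delineate_valley_bottom <- function(dem, flood_height) {
  elev <- dem$elev
  nr <- nrow(elev); nc <- ncol(elev)
  st <- dem$stream
  if (any(st[, 1] < 1 | st[, 1] > nr | st[, 2] < 1 | st[, 2] > nc))
    stop("extent error: stream cell outside grid", call. = FALSE)
  wb <- dem$waterbody
  # multi-source flood fill carrying each seed's stream elevation
  best <- matrix(-Inf, nr, nc)     # highest threshold that reached the cell
  mask <- matrix(FALSE, nr, nc)
  qr <- integer(0); qc <- integer(0); qe <- numeric(0)
  for (i in seq_len(nrow(st))) {
    r <- st[i, 1]; cc <- st[i, 2]
    if (wb[r, cc]) next
    mask[r, cc] <- TRUE
    best[r, cc] <- elev[r, cc]
    qr <- c(qr, r); qc <- c(qc, cc); qe <- c(qe, elev[r, cc])
  }
  while (length(qr)) {
    r <- qr[1]; cc <- qc[1]; se <- qe[1]
    qr <- qr[-1]; qc <- qc[-1]; qe <- qe[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (wb[r2, c2]) next
      if (elev[r2, c2] <= se + flood_height && se > best[r2, c2]) {
        best[r2, c2] <- se
        mask[r2, c2] <- TRUE
        qr <- c(qr, r2); qc <- c(qc, c2); qe <- c(qe, se)
      }
    }
  }
  cs <- dem$cell_size
  covered <- vapply(seq_len(nrow(st)),
                    function(i) mask[st[i, 1], st[i, 2]], logical(1))
  vb_length <- sum(covered) * cs
  vb_area <- sum(mask) * cs^2
  list(mask = mask,
       vb_area_m2 = vb_area,
       vb_length_m = vb_length,
       vb_width_m = if (vb_length > 0) vb_area / vb_length else 0,
       coverage = mean(covered))
}

#' Predict river width for every reach
#'
#' Fits a bagged regression-tree ensemble to log10 river width observed at
#' sites, using discharge-driven reach covariates, and extrapolates width to
#' all reaches. Predictions are back-transformed and therefore strictly
#' positive.
#'
#' @param observations data.frame with columns `comid` and `width_m`
#'   (observed width in metres, `> 0`)
#' @param net a `stream_network` after [attach_physical_attributes()]
#' @param seed integer seed
#' @param ntree ensemble size (default 500)
#' @return list of class `width_model`: `widths` (named by comid, metres),
#'   `oob_r2` (on the log scale), `model`, `features`
#' @export
estimate_river_width <- function(observations, net, seed, ntree = 500) {
  if (missing(seed)) stop("config error: seed is required", call. = FALSE)
  if (nrow(observations) < 30)
    stop("insufficient-data error: need at least 30 width observations",
         call. = FALSE)
  if (any(observations$width_m <= 0))
    stop("value error: widths must be positive", call. = FALSE)
  feats <- c("mean_annual_q", "ws_area_km2", "precip_ws", "slope")
  miss <- setdiff(feats, names(net$reaches))
  if (length(miss))
    stop("schema error: network lacks feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rows <- match(observations$comid, net$reaches$comid)
  if (anyNA(rows))
    stop("integrity error: observation comid(s) not in network", call. = FALSE)
  X <- net$reaches[rows, feats]
  X$mean_annual_q <- log10(X$mean_annual_q + 1e-6)
  y <- log10(observations$width_m)
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = ntree)
  Xall <- net$reaches[feats]
  Xall$mean_annual_q <- log10(Xall$mean_annual_q + 1e-6)
  pred <- 10^stats::predict(rf, Xall)
  structure(list(widths = stats::setNames(pred, as.character(net$reaches$comid)),
                 oob_r2 = rf$rsq[ntree], model = rf, features = feats),
            class = "width_model")
}

#' Classify valley confinement
#'
#' Rule engine over the valley-bottom summaries. Let `cov` be the fraction
#' of (non-inundated) reach length covered by valley bottom and
#' `r = vb_width / river_width`. A fully inundated reach is
#' `"unclassified"`. Otherwise: `cov >= 0.5` and `r >= 4` is
#' `"unconfined"`; `0.25 <= cov < 0.5` with `r >= 4`, or `cov >= 0.5` with
#' `2 <= r < 4`, is `"moderately confined"`; everything else is
#' `"confined"`. Coverage boundaries are inclusive on their lower side.
#'
#' @param inputs a `confinement_inputs` data.frame (see
#'   [generate_valley_inputs()]) with columns `river_width_m`, `vb_width_m`,
#'   `vb_length_coverage`, `inundated_fraction`
#' @return character vector of classes, one per row
#' @export
classify_confinement <- function(inputs) {
  cov <- inputs$vb_length_coverage
  rw <- inputs$river_width_m
  vw <- inputs$vb_width_m
  inun <- inputs$inundated_fraction
  if (any(cov < 0 | cov > 1, na.rm = TRUE) ||
      any(inun < 0 | inun > 1, na.rm = TRUE))
    stop("value error: fractions must lie in [0, 1]", call. = FALSE)
  if (any(rw == 0 & vw > 0, na.rm = TRUE))
    stop("value error: zero river width with positive valley width",
         call. = FALSE)
  r <- ifelse(rw > 0, vw / rw, 0)
  out <- rep("confined", length(cov))
  mod <- (cov >= 0.25 & cov < 0.5 & r >= 4) | (cov >= 0.5 & r >= 2 & r < 4)
  out[mod] <- "moderately confined"
  out[cov >= 0.5 & r >= 4] <- "unconfined"
  out[inun == 1] <- "unclassified"
  out[is.na(cov) | is.na(r) | is.na(inun)] <- "unclassified"
  out
}

#' Valley-confinement layer table
#'
#' Export schema of the confinement layer: class plus the bookkeeping
#' quantities (reach length, river width, valley-bottom width and length
#' coverage, the width ratio).
#'
#' @param inputs a `confinement_inputs` data.frame with a `comid` column
#' @return data.frame with `COMID`, `conf_class`, `reach_length_km`,
#'   `river_width_m`, `vb_width_m`, `vbl_rl_ratio`, `vba_rwa_ratio`
#' @export
confinement_table <- function(inputs) {
  cls <- classify_confinement(inputs)
  data.frame(COMID = inputs$comid,
             conf_class = cls,
             reach_length_km = inputs$reach_length_km,
             river_width_m = inputs$river_width_m,
             vb_width_m = inputs$vb_width_m,
             vbl_rl_ratio = inputs$vb_length_coverage,
             vba_rwa_ratio = ifelse(inputs$river_width_m > 0,
                                    inputs$vb_width_m / inputs$river_width_m, 0))
}
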