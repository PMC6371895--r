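# size-safe sampling: never falls back to sample(1:x) for length-1 vectors
sample_vec <- function(x, n) x[sample.int(length(x), n)]

#' Generator configuration
#'
#' Parameters of the seeded synthetic-network generator. The generator grows
#' a dendritic tree by tip branching, then inserts channel divergences
#' (parallel main/secondary channels that rejoin downstream) and
#' map-boundary style splits (a reach cut into two segments sharing an
#' ecological unit id). Physical attributes follow drainage-area scaling
#' laws: discharge Q = c * A^b with multiplicative lognormal noise, slope
#' S = k * A^(-theta).
#'
#' @param n_reaches total reach count (>= 1)
#' @param branch_prob probability a growing tip bifurcates instead of
#'   extending as a chain
#' @param divergence_rate fraction of reaches around which a divergence
#'   diamond is inserted (each insertion adds two channel reaches)
#' @param split_rate fraction of reaches split at an artificial boundary
#'   (each split adds one reach and one ecological unit)
#' @param misflag_rate fraction of inserted divergences whose main/secondary
#'   flags are left unset, emulating hydrography products that fail to
#'   designate some divergences (these give rise to the generic divergence
#'   class D downstream)
#' @param discharge_law named vector `c(c=, b=, sd=)`: Q = c * A^b * exp(e),
#'   e ~ N(0, sd^2); A is accumulated drainage area in km^2, Q in m^3/s
#' @param slope_law named vector `c(k=, theta=)`: S = k * A^(-theta)
#' @param seed integer seed (mandatory)
#' @return list of class `generator_config`
#' @export
generator_config <- function(n_reaches = 500, branch_prob = 0.7,
                             divergence_rate = 0.03, split_rate = 0.04,
                             misflag_rate = 0.1,
                             discharge_law = c(c = 0.01, b = 0.9, sd = 0.1),
                             slope_law = c(k = 0.05, theta = 0.5),
                             seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("config error: seed is required", call. = FALSE)
  if (n_reaches < 1) stop("config error: n_reaches must be >= 1", call. = FALSE)
  probs <- c(branch_prob, divergence_rate, split_rate, misflag_rate)
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  if (discharge_law[["c"]] <= 0 || slope_law[["k"]] <= 0)
    stop("config error: scaling-law coefficients must be positive",
         call. = FALSE)
  structure(list(n_reaches = as.integer(n_reaches), branch_prob = branch_prob,
                 divergence_rate = divergence_rate, split_rate = split_rate,
                 misflag_rate = misflag_rate, discharge_law = discharge_law,
                 slope_law = slope_law, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic dendritic stream network
#'
#' Grows a tree upstream from a single outlet by repeatedly extending or
#' bifurcating a randomly chosen tip, then inserts divergence diamonds and
#' split reaches per the configured rates. Strahler orders are computed
#' (divergence-aware, on the fully flagged topology) and stored; flags of
#' misdesignated divergences are then erased so that their downstream
#' junctions look inconsistent, as in real hydrography.
#'
#' @param config a [generator_config()]
#' @return a `stream_network` with orders, local catchment areas
#'   (`local_area_km2`) and an eco-unit id on split reaches. Ground-truth
#'   bookkeeping (which reaches were inserted as divergences or splits) is
#'   kept in `attr(net, "truth")`.
#' @export
generate_dendritic_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_total <- config$n_reaches
  n_div <- round(config$divergence_rate * n_total / 3)
  n_split <- round(config$split_rate * n_total)
  n_base <- max(1L, n_total - 2L * n_div - n_split)
  # recompute insertions if n_total is too small to host them
  while (n_base + 2L * n_div + n_split > n_total && (n_div > 0L || n_split > 0L)) {
    if (n_div > 0L) n_div <- n_div - 1L else n_split <- n_split - 1L
  }

  edges_from <- integer(0); edges_to <- integer(0)
  n <- 1L
  tips <- 1L
  while (n < n_base) {
    tip <- if (length(tips) == 1L) tips else sample(tips, 1L)
    if (stats::runif(1) < config$branch_prob && n + 2L <= n_base) {
      kids <- c(n + 1L, n + 2L)
      edges_from <- c(edges_from, kids); edges_to <- c(edges_to, tip, tip)
      tips <- c(setdiff(tips, tip), kids)
      n <- n + 2L
    } else {
      kid <- n + 1L
      edges_from <- c(edges_from, kid); edges_to <- c(edges_to, tip)
      tips <- c(setdiff(tips, tip), kid)
      n <- n + 1L
    }
  }

  flag <- rep("none", n_base)
  eco <- rep(NA_integer_, n_base)
  div_members <- integer(0)
  misflagged <- integer(0)

  # divergence diamonds: replace edge p->q with p->M->q and p->C->q
  if (n_div > 0L && length(edges_from)) {
    cand <- seq_along(edges_from)
    pick <- sample_vec(cand, min(n_div, length(cand)))
    misflag <- stats::runif(length(pick)) < config$misflag_rate
    for (j in seq_along(pick)) {
      e <- pick[j]
      p <- edges_from[e]; q <- edges_to[e]   # p flows to q
      m <- n + 1L; cc <- n + 2L; n <- n + 2L
      flag <- c(flag, "main", "secondary")
      eco <- c(eco, NA_integer_, NA_integer_)
      edges_from[e] <- m; edges_to[e] <- q
      edges_from <- c(edges_from, p, p, cc)
      edges_to <- c(edges_to, m, cc, q)
      div_members <- c(div_members, m, cc)
      if (misflag[j]) misflagged <- c(misflagged, m, cc)
    }
  }

  # splits: cut reach r into r -> r2, both sharing an eco unit
  split_pairs <- NULL
  if (n_split > 0L) {
    eligible <- setdiff(which(flag == "none"), div_members)
    pick <- sample_vec(eligible, min(n_split, length(eligible)))
    unit <- 0L
    for (r in pick) {
      r2 <- n + 1L; n <- n + 1L
      unit <- unit + 1L
      flag <- c(flag, "none")
      eco[r] <- unit
      eco <- c(eco, unit)
      # r2 takes r's downstream edges; r flows into r2
      take <- which(edges_from == r)
      edges_from[take] <- r2
      edges_from <- c(edges_from, r); edges_to <- c(edges_to, r2)
      split_pairs <- rbind(split_pairs, c(up = r, down = r2))
    }
  }

  reaches <- data.frame(
    comid = seq_len(n),
    strahler_order = NA_integer_,
    length_km = exp(stats::rnorm(n, log(1.5), 0.5)),
    slope = NA_real_,
    mean_annual_q = NA_real_,
    divergence_flag = flag,
    eco_unit_id = eco,
    inundated_fraction = 0,
    local_area_km2 = exp(stats::rnorm(n, log(2), 0.6))
  )
  # split halves share the parent's length
  if (!is.null(split_pairs)) {
    half <- reaches$length_km[split_pairs[, "up"]] / 2
    reaches$length_km[split_pairs[, "up"]] <- half
    reaches$length_km[split_pairs[, "down"]] <- half
  }
  edges <- data.frame(from = edges_from, to = edges_to)
  net <- stream_network(reaches, edges)
  ords <- compute_strahler_order(net)
  net$reaches$strahler_order <- as.integer(ords[as.character(net$reaches$comid)])
  # erase flags of misdesignated divergences (orders stay as computed)
  if (length(misflagged))
    net$reaches$divergence_flag[match(misflagged, net$reaches$comid)] <- "none"
  attr(net, "truth") <- list(divergence_reaches = div_members,
                             misflagged = misflagged,
                             split_pairs = split_pairs,
                             config = config)
  net
}

#' Attach physically scaled attributes to a generated network
#'
#' Accumulates drainage area downstream, then draws discharge and slope from
#' the configured power laws, plus a small set of emulated landscape
#' predictors (watershed elevation, a latitude-like coordinate propagated
#' smoothly along the network, watershed precipitation and `qwsa`, the mean
#' annual flow divided by drainage area).
#'
#' @param net output of [generate_dendritic_network()]
#' @param config the same [generator_config()]
#' @return the network with columns `ws_area_km2`, `mean_annual_q`, `slope`,
#'   `elev_ws`, `lat`, `precip_ws`, `qwsa` filled; scaling-law ground truth
#'   appended to `attr(net, "truth")`.
#' @export
attach_physical_attributes <- function(net, config) {
  stopifnot(inherits(net, "stream_network"), inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  A <- accumulate_upstream(net, "local_area_km2")
  A <- A[as.character(net$reaches$comid)]
  dl <- config$discharge_law; sl <- config$slope_law
  n <- nrow(net$reaches)
  eps <- if (dl[["sd"]] > 0) exp(stats::rnorm(n, 0, dl[["sd"]])) else rep(1, n)
  net$reaches$ws_area_km2 <- as.numeric(A)
  net$reaches$mean_annual_q <- dl[["c"]] * A^dl[["b"]] * eps
  net$reaches$slope <- sl[["k"]] * A^(-sl[["theta"]])
  # latitude-like coordinate: outlet value propagated upstream with drift
  lat <- numeric(n)
  ord_rows <- topo_order(net)
  downs <- attr(net, "downs")
  for (i in rev(ord_rows)) {   # downstream before upstream
    d <- downs[[i]]
    lat[i] <- if (!length(d)) stats::runif(1, 32, 46)
              else lat[d[1]] + stats::rnorm(1, 0, 0.08)
  }
  net$reaches$lat <- lat
  net$reaches$elev_ws <- pmax(0, 2200 - 380 * log10(A + 1) +
                                   stats::rnorm(n, 0, 60))
  net$reaches$precip_ws <- pmax(100, 1800 - 28 * (lat - 30) * 2 +
                                     stats::rnorm(n, 0, 80))
  net$reaches$qwsa <- net$reaches$mean_annual_q / net$reaches$ws_area_km2
  truth <- attr(net, "truth") %||% list()
  truth$discharge_law <- dl
  truth$slope_law <- sl
  attr(net, "truth") <- truth
  net
}

#' Generate a synthetic gage panel with clustered hydrologic signatures
#'
#' Every reach is assigned a latent hydrologic class; its 13 "component
#' score" features are drawn from the corresponding Gaussian mixture
#' component (unit within-cluster standard deviation, centers separated by
#' `separation`). Gage sites are a random sample of reaches carrying the
#' reach's features, so that class extrapolation from sites to reaches is
#' learnable. A fraction of feature entries can be knocked out completely at
#' random to exercise imputation.
#'
#' @param net a `stream_network` (after [attach_physical_attributes()])
#' @param n_sites number of gage sites (<= reach count)
#' @param k_clusters number of latent classes (>= 2, <= 13)
#' @param separation distance between any two cluster centers, in units of
#'   the within-cluster standard deviation
#' @param missing_frac fraction of site feature entries set missing (MCAR)
#' @param seed integer seed
#' @return object of class `gage_panel`: list with `sites` (data.frame:
#'   `site_id`, `comid`, `PC1..PC13`, `true_label`, screening attributes),
#'   `k`, `feature_cols`, `reach_truth` (comid -> true label) and `network`
#'   (the input network with the same feature columns and `true_label`
#'   attached to every reach).
#' @export
generate_gage_panel <- function(net, n_sites = 200, k_clusters = 4,
                                separation = 6, missing_frac = 0, seed) {
  stopifnot(inherits(net, "stream_network"))
  if (missing(seed)) stop("config error: seed is required", call. = FALSE)
  if (k_clusters < 2) stop("config error: k_clusters must be >= 2", call. = FALSE)
  if (k_clusters > 13) stop("config error: k_clusters must be <= 13", call. = FALSE)
  n <- nrow(net$reaches)
  if (n_sites > n) stop("config error: n_sites exceeds reach count", call. = FALSE)
  set.seed(seed)
  d <- 13L
  # centers on a scaled simplex: pairwise distance exactly `separation`
  centers <- diag(d)[seq_len(k_clusters), , drop = FALSE] * separation / sqrt(2)
  lab <- sample.int(k_clusters, n, replace = TRUE)
  feats <- centers[lab, , drop = FALSE] + matrix(stats::rnorm(n * d), n, d)
  colnames(feats) <- paste0("PC", seq_len(d))
  for (j in seq_len(d)) net$reaches[[paste0("PC", j)]] <- feats[, j]
  net$reaches$true_label <- lab

  rows <- sort(sample.int(n, n_sites))
  sites <- data.frame(site_id = seq_len(n_sites),
                      comid = net$reaches$comid[rows])
  sf <- feats[rows, , drop = FALSE]
  if (missing_frac > 0) {
    nm <- round(missing_frac * length(sf))
    sf[sample.int(length(sf), nm)] <- NA_real_
  }
  sites <- cbind(sites, as.data.frame(sf))
  sites$true_label <- lab[rows]
  sites$disturbance <- sample(c("very low", "low", "moderate", "high", "very high"),
                              n_sites, replace = TRUE,
                              prob = c(.25, .25, .2, .15, .15))
  sites$dor_percent <- stats::runif(n_sites, 0, 10)
  sites$record_start <- sample(1990:2010, n_sites, replace = TRUE)
  sites$record_end <- sites$record_start + sample(3:8, n_sites, replace = TRUE)
  sites$max_consec_ja_days <- ifelse(stats::runif(n_sites) < 0.8,
                                     sample(60:62, n_sites, replace = TRUE),
                                     sample(30:59, n_sites, replace = TRUE))
  structure(list(sites = sites, k = k_clusters,
                 feature_cols = paste0("PC", seq_len(d)),
                 reach_truth = data.frame(comid = net$reaches$comid,
                                          true_label = lab),
                 network = net),
            class = "gage_panel")
}

#' @export
print.gage_panel <- function(x, ...) {
  cat("<gage_panel> ", nrow(x$sites), " sites, ",
      length(x$feature_cols), " features",
      if (!is.null(x$k)) paste0(", ", x$k, " latent classes"), "\n", sep = "")
  invisible(x)
}

# screening attribute mixtures shared by the temperature-site generator;
# kept as a function so the enumeration oracle in the tests can restate it
temperature_site_attribute_spec <- function() {
  list(disturbance_levels = c("very low", "low", "moderate", "high", "very high"),
       disturbance_probs = c(.25, .25, .2, .15, .15),
       dor_range = c(0, 10),
       start_years = 1990:2010,
       durations = 3:8,
       p_long_record = 0.8,
       long_days = 60:62,
       short_days = 30:59)
}

#' Generate synthetic stream temperature monitoring sites
#'
#' Sites are placed on reaches (several sites may share a reach, as real
#' monitoring stations do). The true mean July-August temperature is a known
#' smooth function of reach covariates (watershed elevation, latitude,
#' discharge) plus Gaussian noise. Disturbance scores, degree of regulation
#' and record windows are drawn from fixed mixtures so reference screening
#' has both keeps and rejects: disturbance is 50% low/very-low, DOR is
#' uniform on 0-10%, record start years 1990-2010 with 3-8 year durations,
#' and 80% of sites have >= 60 consecutive July-August days.
#'
#' @param net a `stream_network` after [attach_physical_attributes()]
#' @param n_sites number of sites (>= 1), sampled over reaches with
#'   replacement
#' @param noise_sd standard deviation of temperature noise, degrees C
#' @param seed integer seed
#' @return object of class `gage_panel` with `sites` carrying
#'   `july_august_temp` and the screening attributes; `truth` holds the
#'   coefficient vector of the noiseless temperature surface.
#' @export
generate_temperature_sites <- function(net, n_sites = 200, noise_sd = 1, seed) {
  stopifnot(inherits(net, "stream_network"))
  if (missing(seed)) stop("config error: seed is required", call. = FALSE)
  if (n_sites < 1) stop("config error: n_sites must be >= 1", call. = FALSE)
  need <- c("elev_ws", "lat", "mean_annual_q", "precip_ws", "qwsa")
  miss <- setdiff(need, names(net$reaches))
  if (length(miss))
    stop("schema error: network lacks covariate(s): ",
         paste(miss, collapse = ", "), " (attach_physical_attributes first)",
         call. = FALSE)
  set.seed(seed)
  spec <- temperature_site_attribute_spec()
  rows <- sample.int(nrow(net$reaches), n_sites, replace = TRUE)
  r <- net$reaches[rows, ]
  coefs <- c(intercept = 28, elev = -0.006, lat = -0.45, logq = 1.5)
  true_t <- coefs[["intercept"]] + coefs[["elev"]] * r$elev_ws +
    coefs[["lat"]] * (r$lat - 30) + coefs[["logq"]] * log10(r$mean_annual_q + 0.01)
  sites <- data.frame(
    site_id = seq_len(n_sites), comid = r$comid,
    elev_ws = r$elev_ws, lat = r$lat, precip_ws = r$precip_ws,
    mean_annual_q = r$mean_annual_q, qwsa = r$qwsa,
    july_august_temp = true_t + stats::rnorm(n_sites, 0, noise_sd),
    disturbance = sample(spec$disturbance_levels, n_sites, replace = TRUE,
                         prob = spec$disturbance_probs),
    dor_percent = stats::runif(n_sites, spec$dor_range[1], spec$dor_range[2]),
    record_start = sample(spec$start_years, n_sites, replace = TRUE)
  )
  sites$record_end <- sites$record_start +
    sample(spec$durations, n_sites, replace = TRUE)
  sites$max_consec_ja_days <- ifelse(
    stats::runif(n_sites) < spec$p_long_record,
    sample(spec$long_days, n_sites, replace = TRUE),
    sample(spec$short_days, n_sites, replace = TRUE))
  structure(list(sites = sites, k = NULL,
                 feature_cols = c("elev_ws", "lat", "precip_ws",
                                  "mean_annual_q", "qwsa"),
                 truth = list(coefficients = coefs, true_temp = true_t,
                              noise_sd = noise_sd),
                 network = net),
            class = "gage_panel")
}

#' Generate synthetic valley-confinement inputs
#'
#' Per-reach river widths follow a hydraulic-geometry law
#' w = alpha * Q^beta with lognormal noise; valley-bottom length coverage and
#' width ratio are drawn from a three-component mixture whose components sit
#' inside the unconfined, moderately confined and confined regions of the
#' rule space, guaranteeing all classes occur. A small share of reaches is
#' partially or fully inundated.
#'
#' @param net a `stream_network` after [attach_physical_attributes()]
#' @param seed integer seed
#' @param width_law named vector `c(alpha=, beta=, sd=)` of the width law
#' @return data.frame of class `confinement_inputs` with columns `comid`,
#'   `reach_length_km`, `river_width_m`, `vb_width_m`, `vb_length_coverage`,
#'   `inundated_fraction`, `true_component`
#' @export
generate_valley_inputs <- function(net, seed,
                                   width_law = c(alpha = 10, beta = 0.5, sd = 0.15)) {
  stopifnot(inherits(net, "stream_network"))
  if (missing(seed)) stop("config error: seed is required", call. = FALSE)
  if (!"mean_annual_q" %in% names(net$reaches) ||
      anyNA(net$reaches$mean_annual_q))
    stop("schema error: network lacks discharge (attach_physical_attributes first)",
         call. = FALSE)
  set.seed(seed)
  n <- nrow(net$reaches)
  q <- net$reaches$mean_annual_q
  w <- width_law[["alpha"]] * q^width_law[["beta"]] *
    exp(stats::rnorm(n, 0, width_law[["sd"]]))
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.45, 0.25, 0.30))
  cov <- numeric(n); ratio <- numeric(n)
  u <- comp == 1L                                    # unconfined region
  cov[u] <- stats::runif(sum(u), 0.6, 1)
  ratio[u] <- stats::runif(sum(u), 4.5, 10)
  m <- comp == 2L                                    # moderately confined
  m_a <- m & stats::runif(n) < 0.5
  m_b <- m & !m_a
  cov[m_a] <- stats::runif(sum(m_a), 0.25, 0.49)
  ratio[m_a] <- stats::runif(sum(m_a), 4.5, 9)
  cov[m_b] <- stats::runif(sum(m_b), 0.55, 0.95)
  ratio[m_b] <- stats::runif(sum(m_b), 2, 3.9)
  cc <- comp == 3L                                   # confined
  cov[cc] <- stats::runif(sum(cc), 0, 0.2)
  ratio[cc] <- stats::runif(sum(cc), 0, 1.9)
  inun <- rep(0, n)
  roll <- stats::runif(n)
  inun[roll < 0.05] <- 1
  part <- roll >= 0.05 & roll < 0.10
  inun[part] <- stats::runif(sum(part), 0.1, 0.9)
  out <- data.frame(comid = net$reaches$comid,
                    reach_length_km = net$reaches$length_km,
                    river_width_m = w,
                    vb_width_m = ratio * w,
                    vb_length_coverage = cov,
                    inundated_fraction = inun,
                    true_component = comp)
  attr(out, "width_law") <- width_law
  class(out) <- c("confinement_inputs", "data.frame")
  out
}

#' Build a synthetic DEM tile with known valley geometry
#'
#' The stream runs along the middle row at elevation 0; valley walls rise
#' according to the tile type. Used to exercise the flood-height
#' valley-bottom delineation against closed-form widths.
#'
#' @param type `"vshape"` (walls rise linearly at `side_slope` per metre of
#'   lateral distance), `"flat"` (plane at stream elevation) or `"canyon"`
#'   (vertical walls of height `wall_height` one cell off the stream)
#' @param nrow,ncol grid dimensions
#' @param cell_size cell edge length in metres
#' @param side_slope rise per metre for `"vshape"`
#' @param wall_height wall height in metres for `"canyon"`
#' @return list with `elev` (matrix), `stream` (two-column matrix of
#'   row/col stream cells), `waterbody` (logical matrix), `cell_size`
#' @export
make_dem_tile <- function(type = c("vshape", "flat", "canyon"),
                          nrow = 21, ncol = 21, cell_size = 1,
                          side_slope = 0.5, wall_height = 100) {
  type <- match.arg(type)
  mid <- as.integer((nrow + 1L) %/% 2L)
  dist_m <- abs(row(matrix(0, nrow, ncol)) - mid) * cell_size
  elev <- switch(type,
    flat = matrix(0, nrow, ncol),
    vshape = dist_m * side_slope,
    canyon = ifelse(dist_m == 0, 0, wall_height))
  stream <- cbind(row = rep(mid, ncol), col = seq_len(ncol))
  list(elev = elev, stream = stream,
       waterbody = matrix(FALSE, nrow, ncol), cell_size = cell_size)
}
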