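# Fixtures are built in code; oracles here are independent restatements of
# the operations they check (brute force / enumeration), never calls into
# the implementation path under test.

# compact network builder: orders and edges given explicitly
tiny_net <- function(comid, order, edges = NULL, q = NA_real_, slope = NA_real_,
                     flag = "none", eco = NA_integer_, length_km = 1,
                     validate = TRUE) {
  n <- length(comid)
  reaches <- data.frame(
    comid = comid,
    strahler_order = rep_len(order, n),
    length_km = rep_len(length_km, n),
    slope = rep_len(slope, n),
    mean_annual_q = rep_len(q, n),
    divergence_flag = rep_len(flag, n),
    eco_unit_id = rep_len(eco, n),
    inundated_fraction = 0
  )
  if (is.null(edges)) edges <- data.frame(from = integer(0), to = integer(0))
  edges <- as.data.frame(edges)
  names(edges) <- c("from", "to")
  stream_network(reaches, edges, validate = validate)
}

# network holding all four divergence situations: a plain junction, a
# properly flagged diamond (D1/D2 rejoining -> DU) and an unflagged diamond
# whose downstream junction is Strahler-inconsistent (-> D)
divergence_showcase_net <- function() {
  #  1,2 -> 3 (plain order-2 junction)
  #  3 -> 4(main), 3 -> 5(secondary), 4,5 -> 6 (DU)
  #  6 -> 7, 6 -> 8 (unflagged divergence), 7,8 -> 9 (non-sensical), 9 -> 10
  tiny_net(
    comid = 1:10,
    order = c(1, 1, 2, 2, 2, 2, 2, 2, 2, 2),
    flag = c("none", "none", "none", "main", "secondary",
             "none", "none", "none", "none", "none"),
    edges = rbind(c(1, 3), c(2, 3), c(3, 4), c(3, 5), c(4, 6), c(5, 6),
                  c(6, 7), c(6, 8), c(7, 9), c(8, 9), c(9, 10))
  )
}

# brute-force upstream reach count by DFS over the raw edge table
brute_upstream_count <- function(edges, comid) {
  seen <- integer(0)
  frontier <- comid
  while (length(frontier)) {
    ups <- edges$from[edges$to %in% frontier]
    new <- setdiff(ups, seen)
    seen <- c(seen, new)
    frontier <- new
  }
  length(seen)
}

# brute-force Strahler order on a dendritic (flag-free) edge table
brute_strahler <- function(edges, comids) {
  memo <- new.env()
  rec <- function(cid) {
    key <- as.character(cid)
    if (!is.null(memo[[key]])) return(memo[[key]])
    ups <- edges$from[edges$to == cid]
    val <- if (!length(ups)) 1L else {
      o <- vapply(ups, rec, integer(1))
      m <- max(o)
      if (sum(o == m) >= 2L) m + 1L else m
    }
    memo[[key]] <- val
    val
  }
  vapply(comids, rec, integer(1))
}

# exhaustive contiguous-partition search for the Jenks objective
brute_jenks_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0L, cuts[, j], n)
    tot <- sum(vapply(seq_len(k),
                      function(i) ssd(x[(b[i] + 1L):b[i + 1L]]), numeric(1)))
    if (tot < best) best <- tot
  }
  best
}

# exhaustive minimum within-cluster-SSE partition (any partition, not just
# contiguous) of n points into k non-empty groups
brute_min_sse_partition <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- Inf
  labels <- integer(n)
  sse <- function(lab) {
    tot <- 0
    for (g in unique(lab)) {
      pts <- X[lab == g, , drop = FALSE]
      ctr <- colMeans(pts)
      tot <- tot + sum(sweep(pts, 2, ctr)^2)
    }
    tot
  }
  rec <- function(i, maxlab) {
    if (i > n) {
      if (maxlab == k) {
        v <- sse(labels)
        if (v < best) best <<- v
      }
      return(invisible())
    }
    for (g in seq_len(min(maxlab + 1L, k))) {
      labels[i] <<- g
      rec(i + 1L, max(maxlab, g))
    }
  }
  rec(1L, 0L)
  best
}

# within-cluster SSE of a given labelling
partition_sse <- function(X, lab) {
  X <- as.matrix(X)
  tot <- 0
  for (g in unique(lab)) {
    pts <- X[lab == g, , drop = FALSE]
    tot <- tot + sum(sweep(pts, 2, colMeans(pts))^2)
  }
  tot
}

# independent restatement of the confinement rules, one point at a time
confinement_oracle <- function(cov, ratio, inundated = 0) {
  mapply(function(cv, r, iu) {
    if (iu == 1) return("unclassified")
    if (cv >= 0.5 && r >= 4) return("unconfined")
    if (cv >= 0.25 && cv < 0.5 && r >= 4) return("moderately confined")
    if (cv >= 0.5 && r >= 2 && r < 4) return("moderately confined")
    "confined"
  }, cov, ratio, inundated)
}

# expected reference-screening pass rate by enumeration of the generator's
# attribute mixtures (all draws independent)
expected_kept_fraction <- function(spec = temperature_site_attribute_spec()) {
  p_dist <- sum(spec$disturbance_probs[spec$disturbance_levels %in%
                                         c("very low", "low")])
  p_dor <- (4 - spec$dor_range[1]) / diff(spec$dor_range)
  grid <- expand.grid(start = spec$start_years, dur = spec$durations)
  p_window <- mean(grid$start >= 1995 & grid$start + grid$dur <= 2015)
  p_days <- spec$p_long_record * mean(spec$long_days >= 60) +
    (1 - spec$p_long_record) * mean(spec$short_days >= 60)
  p_dist * p_dor * p_window * p_days
}

# independent junction coding from the raw from-to table and stored orders
brute_bifurcation_codes <- function(net) {
  edges <- net$edges
  ords <- stats::setNames(net$reaches$strahler_order,
                          as.character(net$reaches$comid))
  vapply(net$reaches$comid, function(cid) {
    ups <- sort(edges$from[edges$to == cid])
    d <- ords[[as.character(cid)]]
    uo <- unname(ords[as.character(ups)])
    if (length(uo) > 4) uo <- sort(uo, decreasing = TRUE)[1:4]
    if (length(uo) <= 1) return(paste0(d, "_0"))
    toks <- if (length(uo) == 2) sort(uo)
            else c(uo[uo == d], sort(uo[uo != d], decreasing = TRUE))
    paste0(d, ".", paste0(toks, collapse = ""))
  }, character(1))
}
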