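#' Construct a stream reach network
#'
#' Bundles a reach attribute table and a "from-to" edge table into a validated
#' directed network object. Reaches are the atomic flowline segments of a
#' hydrographic network (NHDPlus-style), identified by a unique integer
#' `comid`; edges point upstream -> downstream.
#'
#' @param reaches data.frame with at least columns `comid`,
#'   `strahler_order`, `length_km`, `slope`, `mean_annual_q`,
#'   `divergence_flag` (one of `"none"`, `"main"`, `"secondary"`),
#'   `eco_unit_id` (NA where a reach is not part of a split unit) and
#'   `inundated_fraction`. Additional numeric columns are carried along as
#'   reach-level predictors.
#' @param edges data.frame with integer columns `from` and `to`
#'   (upstream comid, downstream comid).
#' @param validate if `TRUE` (default), reject networks violating the basic
#'   invariants (duplicate comids, self loops, dangling edge references,
#'   cycles).
#' @return An object of class `stream_network`: a list with elements
#'   `reaches` and `edges`, plus precomputed adjacency indices.
#' @export
stream_network <- function(reaches, edges, validate = TRUE) {
  stopifnot(is.data.frame(reaches), is.data.frame(edges))
  req <- c("comid", "strahler_order", "length_km", "slope", "mean_annual_q",
           "divergence_flag", "eco_unit_id", "inundated_fraction")
  miss <- setdiff(req, names(reaches))
  if (length(miss))
    stop("schema error: reach table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(c("from", "to") %in% names(edges)))
    stop("schema error: edge table must have columns 'from' and 'to'",
         call. = FALSE)
  reaches$comid <- as.integer(reaches$comid)
  edges <- data.frame(from = as.integer(edges$from), to = as.integer(edges$to))
  if (anyDuplicated(reaches$comid))
    stop("integrity error: duplicate COMID in reach table: ",
         paste(unique(reaches$comid[duplicated(reaches$comid)]), collapse = ", "),
         call. = FALSE)
  if (validate) {
    if (nrow(edges) && any(edges$from == edges$to))
      stop("integrity error: self-loop edge(s) present", call. = FALSE)
    unknown <- setdiff(unique(c(edges$from, edges$to)), reaches$comid)
    if (length(unknown))
      stop("integrity error: from-to table references absent COMID(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_flag <- setdiff(unique(as.character(reaches$divergence_flag)),
                      c("none", "main", "secondary"))
  if (length(bad_flag))
    stop("value error: unknown divergence flag(s): ",
         paste(bad_flag, collapse = ", "), call. = FALSE)
  net <- structure(list(reaches = reaches, edges = edges),
                   class = "stream_network")
  net <- rebuild_indices(net)
  if (validate && length(find_cycles(net)))
    stop("topology error: network contains cycles", call. = FALSE)
  net
}

# Adjacency lists by row index, recomputed whenever tables change.
rebuild_indices <- function(net) {
  n <- nrow(net$reaches)
  idx <- seq_len(n)
  names(idx) <- as.character(net$reaches$comid)
  fi <- idx[as.character(net$edges$from)]
  ti <- idx[as.character(net$edges$to)]
  ups <- vector("list", n)
  downs <- vector("list", n)
  if (length(fi)) {
    ups_split <- split(fi, ti)
    downs_split <- split(ti, fi)
    ups[as.integer(names(ups_split))] <- ups_split
    downs[as.integer(names(downs_split))] <- downs_split
  }
  attr(net, "index") <- idx
  attr(net, "ups") <- ups
  attr(net, "downs") <- downs
  net
}

comid_row <- function(net, comid) {
  i <- attr(net, "index")[as.character(comid)]
  if (anyNA(i))
    stop("lookup error: unknown COMID: ",
         paste(comid[is.na(i)], collapse = ", "), call. = FALSE)
  unname(i)
}

#' @export
print.stream_network <- function(x, ...) {
  cat("<stream_network> ", nrow(x$reaches), " reaches, ",
      nrow(x$edges), " edges\n", sep = "")
  ords <- table(x$reaches$strahler_order)
  if (length(ords))
    cat("  Strahler orders:", paste(names(ords), ords, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Number of reaches in a network
#' @param net a `stream_network`
#' @return integer count
#' @export
n_reaches <- function(net) nrow(net$reaches)

# Topological order of reach row indices (upstream before downstream);
# NULL if the graph has a cycle.
topo_order <- function(net) {
  n <- nrow(net$reaches)
  ups <- attr(net, "ups")
  downs <- attr(net, "downs")
  indeg <- vapply(ups, length, integer(1))
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (w in downs[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) return(NULL)
  out
}

# Reach comids that belong to at least one cycle (empty if acyclic).
find_cycles <- function(net) {
  n <- nrow(net$reaches)
  ups <- attr(net, "ups")
  downs <- attr(net, "downs")
  indeg <- vapply(ups, length, integer(1))
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    seen <- seen + 1L
    for (w in downs[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen == n) integer(0) else net$reaches$comid[indeg > 0L]
}

#' Read a stream network from CSV tables
#'
#' Reads a reach attribute table and a from-to topology table in the NHDPlus
#' V2 flowline export dialect. Discharge is stored internally in m^3/s;
#' if the config declares the input unit as `cfs` it is converted at ingest
#' (1 cfs = 0.0283168 m^3/s).
#'
#' @param reach_table_path CSV with header
#'   `COMID,StreamOrde,LENGTHKM,slope,Q0001A,Divergence,EcoUnitID,InundatedFrac`
#'   plus free predictor columns.
#' @param fromto_path CSV with header `FROMCOMID,TOCOMID`.
#' @param config a list with element `discharge_unit` (`"m3s"` or `"cfs"`),
#'   or the path to a YAML file holding that field. Default `"m3s"`.
#' @return a validated [stream_network]
#' @export
read_network <- function(reach_table_path, fromto_path,
                         config = list(discharge_unit = "m3s")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  unit <- config$discharge_unit %||% "m3s"
  if (!unit %in% c("m3s", "cfs"))
    stop("config error: unknown discharge unit tag: ", unit, call. = FALSE)
  if (!file.exists(reach_table_path))
    stop("file not found: ", reach_table_path, call. = FALSE)
  if (!file.exists(fromto_path))
    stop("file not found: ", fromto_path, call. = FALSE)
  rt <- utils::read.csv(reach_table_path, check.names = FALSE)
  ft <- utils::read.csv(fromto_path, check.names = FALSE)
  req <- c("COMID", "StreamOrde", "LENGTHKM", "slope", "Q0001A",
           "Divergence", "EcoUnitID", "InundatedFrac")
  miss <- setdiff(req, names(rt))
  if (length(miss))
    stop("schema error: reach table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(c("FROMCOMID", "TOCOMID") %in% names(ft)))
    stop("schema error: from-to table missing FROMCOMID/TOCOMID", call. = FALSE)
  q <- rt$Q0001A
  if (unit == "cfs") q <- q * 0.0283168
  reaches <- data.frame(
    comid = as.integer(rt$COMID),
    strahler_order = as.integer(rt$StreamOrde),
    length_km = rt$LENGTHKM,
    slope = rt$slope,
    mean_annual_q = q,
    divergence_flag = as.character(rt$Divergence),
    eco_unit_id = suppressWarnings(as.integer(rt$EcoUnitID)),
    inundated_fraction = rt$InundatedFrac
  )
  extra <- setdiff(names(rt), req)
  for (cn in extra) reaches[[cn]] <- rt[[cn]]
  edges <- data.frame(from = as.integer(ft$FROMCOMID),
                      to = as.integer(ft$TOCOMID))
  stream_network(reaches, edges)
}

#' Write a stream network to CSV tables
#'
#' Inverse of [read_network()]; discharge is written in m^3/s.
#'
#' @param net a `stream_network`
#' @param reach_table_path,fromto_path output CSV paths
#' @return invisibly, the two paths
#' @export
write_network <- function(net, reach_table_path, fromto_path) {
  r <- net$reaches
  out <- data.frame(
    COMID = r$comid, StreamOrde = r$strahler_order, LENGTHKM = r$length_km,
    slope = r$slope, Q0001A = r$mean_annual_q, Divergence = r$divergence_flag,
    EcoUnitID = r$eco_unit_id, InundatedFrac = r$inundated_fraction
  )
  extra <- setdiff(names(r), c("comid", "strahler_order", "length_km", "slope",
                               "mean_annual_q", "divergence_flag",
                               "eco_unit_id", "inundated_fraction"))
  for (cn in extra) out[[cn]] <- r[[cn]]
  utils::write.csv(out, reach_table_path, row.names = FALSE)
  utils::write.csv(data.frame(FROMCOMID = net$edges$from,
                              TOCOMID = net$edges$to),
                   fromto_path, row.names = FALSE)
  invisible(c(reach_table_path, fromto_path))
}

#' Validate network topology
#'
#' Reports cycles, orphan reaches (reaches touching no edge, in networks of
#' more than one reach), and multi-downstream reaches none of whose children
#' carry a divergence flag. The report is empty iff the structural invariants
#' hold.
#'
#' @param net a `stream_network`
#' @return a list of class `topology_report` with elements `cycles`,
#'   `orphans`, `missing_divergence_flags` (comid vectors)
#' @export
validate_topology <- function(net) {
  cyc <- find_cycles(net)
  touched <- unique(c(net$edges$from, net$edges$to))
  orphans <- if (nrow(net$reaches) > 1L)
    setdiff(net$reaches$comid, touched) else integer(0)
  downs <- attr(net, "downs")
  flag <- as.character(net$reaches$divergence_flag)
  multi <- which(vapply(downs, length, integer(1)) > 1L)
  bad <- integer(0)
  for (i in multi) {
    kids <- downs[[i]]
    if (!any(flag[kids] %in% c("main", "secondary")))
      bad <- c(bad, net$reaches$comid[i])
  }
  structure(list(cycles = cyc, orphans = orphans,
                 missing_divergence_flags = bad),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  if (topology_clean(x)) {
    cat("topology OK\n")
  } else {
    if (length(x$cycles)) cat("cycles involving:", x$cycles, "\n")
    if (length(x$orphans)) cat("orphan reaches:", x$orphans, "\n")
    if (length(x$missing_divergence_flags))
      cat("divergence without flagged children below:",
          x$missing_divergence_flags, "\n")
  }
  invisible(x)
}

#' Is a topology report empty?
#' @param report result of [validate_topology()]
#' @return `TRUE` when no issue was found
#' @export
topology_clean <- function(report) {
  all(vapply(report, length, integer(1)) == 0L)
}

#' Immediate upstream reaches
#'
#' @param net a `stream_network`
#' @param comid reach identifier (must exist)
#' @return integer vector of the comids flowing directly into `comid`,
#'   sorted ascending for determinism; empty for headwaters.
#' @export
upstream_of <- function(net, comid) {
  i <- comid_row(net, comid)
  sort(net$reaches$comid[attr(net, "ups")[[i]]])
}

#' Immediate downstream reaches
#' @inheritParams upstream_of
#' @return integer vector of comids receiving flow from `comid`, sorted
#'   ascending (more than one only below a divergence).
#' @export
downstream_of <- function(net, comid) {
  i <- comid_row(net, comid)
  sort(net$reaches$comid[attr(net, "downs")[[i]]])
}

#' Compute Strahler stream order
#'
#' Headwaters get order 1. At a junction, if two or more upstream reaches
#' share the maximal order the downstream order is that maximum plus one,
#' otherwise the maximum propagates. Channels flagged as divergence children
#' (main or secondary) inherit their parent's order, and junctions whose
#' upstream reaches carry divergence flags do not increment (the rejoining
#' channels descend from a single parent channel).
#'
#' @param net an acyclic `stream_network`
#' @return named integer vector, comid -> order
#' @export
compute_strahler_order <- function(net) {
  ord_rows <- topo_order(net)
  if (is.null(ord_rows))
    stop("topology error: network contains cycles", call. = FALSE)
  ups <- attr(net, "ups")
  flag <- as.character(net$reaches$divergence_flag)
  res <- integer(nrow(net$reaches))
  for (i in ord_rows) {
    u <- ups[[i]]
    if (!length(u)) {
      res[i] <- 1L
    } else {
      o <- res[u]
      m <- max(o)
      if (flag[i] %in% c("main", "secondary")) {
        res[i] <- m                               # divergent channel inherits
      } else if (any(flag[u] %in% c("main", "secondary"))) {
        res[i] <- m                               # re-merge of one channel
      } else if (sum(o == m) >= 2L) {
        res[i] <- m + 1L
      } else {
        res[i] <- m
      }
    }
  }
  stats::setNames(res, as.character(net$reaches$comid))
}

#' Accumulate a reach attribute downstream
#'
#' The accumulated value at a reach is its local value plus the accumulated
#' values routed from its immediate upstream reaches. At divergences the
#' parent's accumulation is routed `main_fraction` (default 1, i.e. 100%)
#' down the main (D1) channel and the remainder split equally over secondary
#' channels, so nothing is double counted when channels rejoin. When no child
#' of a divergence is flagged main, the lowest-comid child stands in as the
#' main channel.
#'
#' @param net a `stream_network`
#' @param field name of a numeric reach column
#' @param main_fraction fraction of the parent's accumulation routed down the
#'   main channel at a divergence, in `[0, 1]`
#' @return named numeric vector, comid -> accumulated value
#' @export
accumulate_upstream <- function(net, field, main_fraction = 1) {
  if (!field %in% names(net$reaches))
    stop("schema error: no reach column named '", field, "'", call. = FALSE)
  x <- net$reaches[[field]]
  if (!is.numeric(x))
    stop("schema error: reach column '", field, "' is not numeric",
         call. = FALSE)
  if (anyNA(x))
    stop("schema error: reach column '", field, "' has missing values",
         call. = FALSE)
  ord_rows <- topo_order(net)
  if (is.null(ord_rows))
    stop("topology error: network contains cycles", call. = FALSE)
  ups <- attr(net, "ups")
  downs <- attr(net, "downs")
  flag <- as.character(net$reaches$divergence_flag)
  comid <- net$reaches$comid
  # share of parent p's accumulation reaching child row i
  share <- function(p, i) {
    kids <- downs[[p]]
    if (length(kids) == 1L) return(1)
    mains <- kids[flag[kids] == "main"]
    main <- if (length(mains)) mains[which.min(comid[mains])]
            else kids[which.min(comid[kids])]
    if (i == main) main_fraction
    else (1 - main_fraction) / (length(kids) - 1L)
  }
  acc <- numeric(length(x))
  for (i in ord_rows) {
    v <- x[i]
    for (p in ups[[i]]) v <- v + acc[p] * share(p, i)
    acc[i] <- v
  }
  stats::setNames(acc, as.character(comid))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
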