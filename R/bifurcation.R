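#' Code a tributary junction
#'
#' Renders the tributary-mainstem combination at the upstream end of a
#' reach. A reach with no (or one) upstream contributor is coded
#' `"<order>_0"`. With two contributors the two upstream orders follow the
#' period in ascending order (an order-1 and an order-2 stream joining above
#' an order-2 reach gives `"2.12"`). With three or four contributors, the
#' orders equal to the downstream order come first and the rest follow in
#' descending order (orders 5, 1, 1 above an order-5 reach give `"5.511"`).
#' When more than four reaches contribute, the largest four orders are
#' retained. Orders of 10 or more cannot be rendered as single digits, so
#' the rendered form joins tokens with hyphens (e.g. `"12.10-3"`).
#'
#' @param downstream_order Strahler order of the reach itself (>= 1)
#' @param upstream_orders integer vector of the contributing reaches'
#'   orders (possibly empty)
#' @return object of class `junction_code`: list with `downstream_order`,
#'   `upstream_orders` (the retained, arranged tokens) and `rendered`
#' @export
code_junction <- function(downstream_order, upstream_orders = integer(0)) {
  if (downstream_order < 1 || any(upstream_orders < 1))
    stop("value error: stream orders must be positive", call. = FALSE)
  ups <- as.integer(upstream_orders)
  if (length(ups) > 4L) ups <- sort(ups, decreasing = TRUE)[1:4]
  d <- as.integer(downstream_order)
  if (length(ups) <= 1L) {
    tokens <- integer(0)
    rendered <- paste0(d, "_0")
  } else if (length(ups) == 2L) {
    tokens <- sort(ups)
    rendered <- render_junction(d, tokens)
  } else {
    match_d <- ups[ups == d]
    rest <- sort(ups[ups != d], decreasing = TRUE)
    tokens <- c(match_d, rest)
    rendered <- render_junction(d, tokens)
  }
  structure(list(downstream_order = d, upstream_orders = tokens,
                 rendered = rendered),
            class = "junction_code")
}

render_junction <- function(d, tokens) {
  if (d <= 9L && all(tokens <= 9L))
    paste0(d, ".", paste0(tokens, collapse = ""))
  else
    paste0(d, ".", paste0(tokens, collapse = "-"))
}

#' @export
print.junction_code <- function(x, ...) {
  cat(x$rendered, "\n")
  invisible(x)
}

#' Format a junction code
#' @param x a `junction_code`
#' @param ... ignored
#' @return the rendered string
#' @export
format.junction_code <- function(x, ...) x$rendered

# walk from a flagged divergence channel up to the parent reach that split;
# returns the parent's row index or NA if the chain is malformed
divergence_origin <- function(net, row) {
  ups <- attr(net, "ups")
  downs <- attr(net, "downs")
  flag <- as.character(net$reaches$divergence_flag)
  cur <- row
  for (step in seq_len(nrow(net$reaches))) {
    u <- ups[[cur]]
    if (length(u) != 1L) return(NA_integer_)
    if (length(downs[[u]]) > 1L) return(u)
    if (!flag[u] %in% c("main", "secondary")) return(NA_integer_)
    cur <- u
  }
  NA_integer_
}

#' Detect non-sensical tributary junctions
#'
#' A junction is inconsistent when the downstream reach's stored order does
#' not match the Strahler combination of its upstream orders (maximum, plus
#' one if two or more share the maximum) and none of the upstream reaches
#' carries a divergence flag. Such junctions arise where a hydrography
#' product failed to designate a channel divergence; the affected reaches
#' receive the generic divergence class D.
#'
#' @param net a `stream_network` with Strahler orders present
#' @return integer vector of flagged comids
#' @export
detect_nonsensical_junctions <- function(net) {
  ups <- attr(net, "ups")
  ord <- net$reaches$strahler_order
  flag <- as.character(net$reaches$divergence_flag)
  out <- integer(0)
  for (i in seq_len(nrow(net$reaches))) {
    u <- ups[[i]]
    if (length(u) < 2L) next
    if (any(flag[u] %in% c("main", "secondary"))) next
    o <- ord[u]
    m <- max(o)
    expected <- if (sum(o == m) >= 2L) m + 1L else m
    if (ord[i] != expected) out <- c(out, net$reaches$comid[i])
  }
  out
}

#' Assign divergence classes
#'
#' Each reach gets exactly one of: `D1` (main channel of a divergence, from
#' the divergence flag), `D2` (secondary channel), `DU` (reach immediately
#' below the rejoining of two or more channels descending from a single
#' divergence), `D` (reach at a detected non-sensical junction, see
#' [detect_nonsensical_junctions()]), or `none`.
#'
#' @param net a `stream_network` with orders and flags
#' @return named character vector, comid -> divergence class
#' @export
assign_divergence_classes <- function(net) {
  n <- nrow(net$reaches)
  flag <- as.character(net$reaches$divergence_flag)
  ups <- attr(net, "ups")
  res <- rep("none", n)
  res[flag == "main"] <- "D1"
  res[flag == "secondary"] <- "D2"
  # DU: >= 2 immediate upstream divergence channels sharing an origin
  for (i in which(res == "none")) {
    u <- ups[[i]]
    ch <- u[flag[u] %in% c("main", "secondary")]
    if (length(ch) < 2L) next
    orig <- vapply(ch, function(r) divergence_origin(net, r), integer(1))
    orig <- orig[!is.na(orig)]
    if (length(orig) >= 2L && anyDuplicated(orig)) res[i] <- "DU"
  }
  bad <- detect_nonsensical_junctions(net)
  take <- match(bad, net$reaches$comid)
  res[take[res[take] == "none"]] <- "D"
  stats::setNames(res, as.character(net$reaches$comid))
}

#' Assign bifurcation classes to every reach
#'
#' Codes the tributary junction at the upstream end of each reach (see
#' [code_junction()]); reaches at detected non-sensical junctions carry the
#' generic divergence class `"D"` as their bifurcation code instead.
#' Upstream and downstream reach counts are emitted as companion columns.
#'
#' @param net a `stream_network` with orders
#' @return data.frame of class `class_assignment` with columns `COMID`,
#'   `bif_class`, `div_class`, `upstream_count`, `downstream_count`,
#'   `eco_unit_id`, `flagged`
#' @export
assign_bifurcation_classes <- function(net) {
  ups <- attr(net, "ups")
  downs <- attr(net, "downs")
  ord <- net$reaches$strahler_order
  if (anyNA(ord))
    stop("value error: Strahler orders missing; run compute_strahler_order",
         call. = FALSE)
  div <- assign_divergence_classes(net)
  bad <- detect_nonsensical_junctions(net)
  n <- nrow(net$reaches)
  bif <- character(n)
  for (i in seq_len(n)) {
    bif[i] <- code_junction(ord[i], ord[ups[[i]]])$rendered
  }
  flagged <- net$reaches$comid %in% bad
  bif[flagged] <- "D"
  out <- data.frame(
    COMID = net$reaches$comid,
    bif_class = bif,
    div_class = unname(div[as.character(net$reaches$comid)]),
    upstream_count = vapply(ups, length, integer(1)),
    downstream_count = vapply(downs, length, integer(1)),
    eco_unit_id = net$reaches$eco_unit_id,
    flagged = flagged
  )
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Correct split reaches via ecological units
#'
#' Reaches split at artificial boundaries (quadrangle edges and similar)
#' share an ecological unit id. Within each unit, every member receives the
#' bifurcation and divergence class of the topologically upstream-most
#' member. The operation is idempotent. A unit whose members do not form a
#' connected directed path is skipped with a warning.
#'
#' @param net a `stream_network` with `eco_unit_id` populated on split
#'   reaches
#' @param classes result of [assign_bifurcation_classes()]
#' @return the corrected `class_assignment`
#' @export
correct_split_reaches <- function(net, classes) {
  eco <- net$reaches$eco_unit_id
  units <- unique(eco[!is.na(eco)])
  downs <- attr(net, "downs")
  comid <- net$reaches$comid
  for (u in units) {
    rows <- which(eco == u)
    if (length(rows) < 2L) next
    # connected directed path: each member's downstream neighbour within the
    # unit is unique, and exactly one member has none (the tail)
    nxt <- lapply(rows, function(i) intersect(downs[[i]], rows))
    if (any(lengths(nxt) > 1L) || sum(lengths(nxt) == 0L) != 1L) {
      warning("eco unit ", u, " is not a connected directed path; skipped")
      next
    }
    heads <- rows[!rows %in% unlist(nxt)]
    if (length(heads) != 1L) {
      warning("eco unit ", u, " is not a connected directed path; skipped")
      next
    }
    hrow <- match(comid[heads], classes$COMID)
    urows <- match(comid[rows], classes$COMID)
    classes$bif_class[urows] <- classes$bif_class[hrow]
    classes$div_class[urows] <- classes$div_class[hrow]
  }
  classes
}
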