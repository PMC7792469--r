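#' Coronary vessel graphs
#'
#' A `vessel_graph` is the package's central container: a directed graph of
#' vessel segments rooted at one or more ostia (origins of the coronary
#' arteries at the aortic root).  Edges are oriented from the ostium outward,
#' in the direction of flow.  Each segment carries the geometric and
#' mechanical attributes needed by the 1D haemodynamic model: length (mm),
#' reference (healthy) diameter, effective diameter after any stenosis,
#' and the elastic wall characteristic speed c0 (m/s).
#'
#' @param nodes data.frame with columns `id`, `kind` (one of `"ostium"`,
#'   `"junction"`, `"terminal"`, `"internal"`), `x`, `y`, `z` (mm).
#' @param segments data.frame with columns `id`, `from`, `to`, `length_mm`,
#'   `reference_diameter_mm`, `effective_diameter_mm`, `wall_speed_m_s`,
#'   `label` (one of `"aorta"`, `"artery"`, `"vein"`), `ffr_site` (logical).
#'   An optional `vessel` column names the anatomical vessel (LAD, LCX, ...)
#'   the segment belongs to; it is used to group FFR sites per vessel.
#' @param ostia character vector of root node ids.
#' @return An object of class `vessel_graph`.
#' @examples
#' g <- single_segment_graph(diameter_mm = 3, length_mm = 10)
#' validate_graph(g)$pass
#' @export
vessel_graph <- function(nodes, segments, ostia) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need_n <- c("id", "kind", "x", "y", "z")
  need_s <- c("id", "from", "to", "length_mm", "reference_diameter_mm",
              "effective_diameter_mm", "wall_speed_m_s", "label", "ffr_site")
  miss <- setdiff(need_n, names(nodes))
  if (length(miss)) stop("nodes missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_s, names(segments))
  if (length(miss)) stop("segments missing column(s): ", paste(miss, collapse = ", "))
  if (!"vessel" %in% names(segments)) segments$vessel <- NA_character_
  nodes$id <- as.character(nodes$id)
  for (cc in c("id", "from", "to", "label")) segments[[cc]] <- as.character(segments[[cc]])
  segments$ffr_site <- as.logical(segments$ffr_site)
  structure(list(nodes = nodes, segments = segments,
                 ostia = as.character(ostia)),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d segments, %d ostium(s)\n",
              nrow(x$nodes), nrow(x$segments), length(x$ostia)))
  cat(sprintf("  total length %.1f mm; labels: %s\n",
              sum(x$segments$length_mm),
              paste(sprintf("%s=%d", names(table(x$segments$label)),
                            as.integer(table(x$segments$label))),
                    collapse = " ")))
  ns <- sum(x$segments$ffr_site)
  if (ns) cat(sprintf("  %d FFR site(s): %s\n", ns,
                      paste(x$segments$id[x$segments$ffr_site], collapse = ", ")))
  invisible(x)
}

#' Minimal one-segment graph (ostium -> terminal)
#'
#' Convenience constructor used throughout examples and tests.
#'
#' @param diameter_mm,length_mm segment geometry.
#' @param c0 wall characteristic speed, m/s.
#' @param label segment label.
#' @return A `vessel_graph` with one segment `"s1"` from node `"n_root"` to
#'   `"n_tip"` along the x axis.
#' @export
single_segment_graph <- function(diameter_mm = 3, length_mm = 10, c0 = 10,
                                 label = "artery") {
  vessel_graph(
    nodes = data.frame(id = c("n_root", "n_tip"),
                       kind = c("ostium", "terminal"),
                       x = c(0, length_mm), y = 0, z = 0,
                       stringsAsFactors = FALSE),
    segments = data.frame(id = "s1", from = "n_root", to = "n_tip",
                          length_mm = length_mm,
                          reference_diameter_mm = diameter_mm,
                          effective_diameter_mm = diameter_mm,
                          wall_speed_m_s = c0, label = label,
                          ffr_site = FALSE, stringsAsFactors = FALSE),
    ostia = "n_root")
}

#' Validate a vessel graph
#'
#' Checks the structural invariants the downstream model relies on: unique
#' ids, existing endpoints, positive dimensions, effective diameter not
#' exceeding the reference diameter, acyclicity, and - per connected
#' component of non-vein segments - a single ostium root from which every
#' node is reachable along edge orientation.  Vein-labelled segments are
#' exempt from the tree requirements (they are expected to be pruned by
#' [prune_nonarterial()] before modelling).
#'
#' @param graph a `vessel_graph`.
#' @return list with `pass` (logical) and `violations` (character vector).
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  v <- character()
  nd <- graph$nodes; sg <- graph$segments
  if (anyDuplicated(nd$id)) v <- c(v, "duplicate node id")
  if (anyDuplicated(sg$id)) v <- c(v, "duplicate segment id")
  if (!all(sg$from %in% nd$id) || !all(sg$to %in% nd$id))
    v <- c(v, "segment endpoint missing from node set")
  if (any(!is.finite(sg$length_mm)) || any(sg$length_mm <= 0))
    v <- c(v, "nonpositive length")
  if (any(sg$reference_diameter_mm <= 0) || any(sg$effective_diameter_mm <= 0))
    v <- c(v, "nonpositive diameter")
  if (any(sg$effective_diameter_mm > sg$reference_diameter_mm + 1e-9))
    v <- c(v, "effective diameter exceeds reference")
  if (any(sg$wall_speed_m_s <= 0)) v <- c(v, "nonpositive wall speed")
  if (!all(graph$ostia %in% nd$id)) v <- c(v, "ostium node missing")
  ost <- intersect(graph$ostia, nd$id)
  if (any(sg$to %in% ost)) v <- c(v, "ostium has incoming segment")
  term <- nd$id[nd$kind == "terminal"]
  if (any(sg$from %in% term)) v <- c(v, "terminal has outgoing segment")
  # tree structure on the non-vein subgraph
  art <- sg[sg$label != "vein", , drop = FALSE]
  if (nrow(art) && !length(setdiff(c(art$from, art$to), nd$id))) {
    comp <- .undirected_components(nd$id, art$from, art$to)
    used <- unique(c(art$from, art$to))
    for (cid in unique(comp[used])) {
      members <- names(comp)[comp == cid & names(comp) %in% used]
      e <- art[art$from %in% members | art$to %in% members, , drop = FALSE]
      roots <- intersect(ost, members)
      if (length(roots) > 1) v <- c(v, "multiple roots in one component")
      if (length(roots) == 0) v <- c(v, "component without ostium")
      if (nrow(e) != length(members) - 1 ||
          anyDuplicated(e$to) ||
          length(intersect(e$to, roots)))
        v <- c(v, "cycle")
      else if (length(roots) == 1 &&
               !setequal(.reachable(roots, e$from, e$to), members))
        v <- c(v, "node unreachable from ostium")
    }
  }
  v <- unique(v)
  list(pass = length(v) == 0L, violations = v)
}

.undirected_components <- function(ids, from, to) {
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    a <- pmin(comp[from], comp[to]); b <- pmax(comp[from], comp[to])
    changed <- FALSE
    for (i in seq_along(from)) {
      ca <- comp[from[i]]; cb <- comp[to[i]]
      if (ca != cb) {
        comp[comp == max(ca, cb)] <- min(ca, cb)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

.reachable <- function(roots, from, to) {
  seen <- roots
  frontier <- roots
  while (length(frontier)) {
    nxt <- setdiff(to[from %in% frontier], seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Stenosis specification
#'
#' @param segment_id id of the host segment.
#' @param diameter_reduction fraction in (0,1): percent-diameter stenosis
#'   divided by 100 (e.g. 0.6 for a 60\% stenosis).
#' @param extent_fraction fraction of the host segment's length occupied by
#'   the narrowed section, in (0,1].
#' @return list of class `stenosis_spec`.
#' @export
stenosis_spec <- function(segment_id, diameter_reduction, extent_fraction = 0.3) {
  if (!is.finite(diameter_reduction) || diameter_reduction <= 0 ||
      diameter_reduction >= 1)
    stop("diameter_reduction must lie in (0, 1)")
  if (!is.finite(extent_fraction) || extent_fraction <= 0 || extent_fraction > 1)
    stop("extent_fraction must lie in (0, 1]")
  structure(list(segment_id = as.character(segment_id),
                 diameter_reduction = diameter_reduction,
                 extent_fraction = extent_fraction),
            class = "stenosis_spec")
}

#' Apply a stenosis to a graph segment
#'
#' The host segment is split into up to three sub-edges (proximal, stenotic,
#' distal) so that the narrowed section is an individual graph edge with its
#' own modified diameter; the stenotic edge keeps the host segment's id, is
#' marked as an FFR measurement site, and gets
#' `effective_diameter = reference_diameter * (1 - diameter_reduction)`.
#' Total length is conserved.
#'
#' @param graph a `vessel_graph`.
#' @param spec a [stenosis_spec()].
#' @return the modified `vessel_graph`.
#' @examples
#' g <- apply_stenosis(single_segment_graph(), stenosis_spec("s1", 0.5))
#' g$segments[g$segments$ffr_site, "effective_diameter_mm"]  # 1.5
#' @export
apply_stenosis <- function(graph, spec) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(spec, "stenosis_spec"))
  sg <- graph$segments
  i <- match(spec$segment_id, sg$id)
  if (is.na(i)) stop("unknown segment id: ", spec$segment_id)
  host <- sg[i, ]
  d_eff <- host$reference_diameter_mm * (1 - spec$diameter_reduction)
  if (spec$extent_fraction >= 1) {
    sg$effective_diameter_mm[i] <- d_eff
    sg$ffr_site[i] <- TRUE
    graph$segments <- sg
    return(graph)
  }
  nfrom <- graph$nodes[match(host$from, graph$nodes$id), ]
  nto <- graph$nodes[match(host$to, graph$nodes$id), ]
  Ls <- host$length_mm * spec$extent_fraction
  Lp <- (host$length_mm - Ls) / 2
  t1 <- Lp / host$length_mm
  t2 <- (Lp + Ls) / host$length_mm
  lerp <- function(t) c(nfrom$x + t * (nto$x - nfrom$x),
                        nfrom$y + t * (nto$y - nfrom$y),
                        nfrom$z + t * (nto$z - nfrom$z))
  p1 <- lerp(t1); p2 <- lerp(t2)
  id1 <- paste0(host$id, "_sa"); id2 <- paste0(host$id, "_sb")
  graph$nodes <- rbind(graph$nodes,
                       data.frame(id = c(id1, id2), kind = "internal",
                                  x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
                                  z = c(p1[3], p2[3]), stringsAsFactors = FALSE))
  mk <- function(id, from, to, len, eff, site) {
    out <- host
    out$id <- id; out$from <- from; out$to <- to
    out$length_mm <- len; out$effective_diameter_mm <- eff
    out$ffr_site <- site
    out
  }
  parts <- rbind(mk(paste0(host$id, ".p"), host$from, id1, Lp,
                    host$effective_diameter_mm, FALSE),
                 mk(host$id, id1, id2, Ls, d_eff, TRUE),
                 mk(paste0(host$id, ".d"), id2, host$to, Lp,
                    host$effective_diameter_mm, FALSE))
  graph$segments <- rbind(sg[-i, ], parts)
  rownames(graph$segments) <- NULL
  graph
}

#' Remove vein-labelled segments
#'
#' Contrast agent entering veins contaminates the segmentation; the
#' corresponding graph edges must be deleted before FFR computation.  This
#' automates the deletion by label: all `"vein"` segments are removed, along
#' with any nodes and non-vein fragments left unreachable from every ostium.
#'
#' @param graph a `vessel_graph`.
#' @return the pruned `vessel_graph`.  Errors if pruning would disconnect an
#'   FFR site from every ostium.
#' @export
prune_nonarterial <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  on_vein <- graph$segments$id[graph$segments$ffr_site &
                                 graph$segments$label == "vein"]
  if (length(on_vein))
    stop("FFR site(s) marked on vein segment(s): ",
         paste(on_vein, collapse = ", "))
  sg <- graph$segments[graph$segments$label != "vein", , drop = FALSE]
  keep_nodes <- .reachable(graph$ostia, sg$from, sg$to)
  lost <- sg$id[sg$ffr_site & !(sg$to %in% keep_nodes)]
  if (length(lost))
    stop("pruning veins disconnects FFR site(s) from every ostium: ",
         paste(lost, collapse = ", "))
  sg <- sg[sg$from %in% keep_nodes & sg$to %in% keep_nodes, , drop = FALSE]
  nd <- graph$nodes[graph$nodes$id %in% unique(c(sg$from, sg$to, graph$ostia)), ,
                    drop = FALSE]
  rownames(sg) <- rownames(nd) <- NULL
  vessel_graph(nd, sg, graph$ostia)
}

# --- JSON I/O --------------------------------------------------------------

#' Read / write vessel graphs as JSON (schema v1)
#'
#' The on-disk schema is
#' `{schema_version, nodes:[{id,kind,position_mm}], segments:[...], ostia:[...]}`
#' with lengths/diameters in mm and wall speed in m/s.  `write_graph` followed
#' by `read_graph` is the identity on all fields.
#'
#' @param path file path.
#' @param graph a `vessel_graph`.
#' @return `read_graph` returns a `vessel_graph`; `write_graph` returns
#'   `path` invisibly.
#' @export
read_graph <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(j$schema_version) || j$schema_version != 1)
    stop("unsupported graph schema version: ",
         if (is.null(j$schema_version)) "<missing>" else j$schema_version)
  need_s <- c("id", "from", "to", "length_mm", "reference_diameter_mm",
              "effective_diameter_mm", "wall_speed_m_s", "label", "ffr_site")
  miss <- setdiff(need_s, names(j$segments))
  if (length(miss)) stop("graph file missing segment field(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(j$nodes$id) || is.null(j$nodes$kind) || is.null(j$nodes$position_mm))
    stop("graph file missing node fields")
  pos <- do.call(rbind, lapply(seq_len(nrow(j$nodes)), function(i)
    as.numeric(j$nodes$position_mm[[i]])))
  nodes <- data.frame(id = j$nodes$id, kind = j$nodes$kind,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) stop("duplicate node id in graph file")
  if (anyDuplicated(j$segments$id)) stop("duplicate segment id in graph file")
  g <- vessel_graph(nodes, j$segments, j$ostia)
  ok <- validate_graph(g)
  if (!ok$pass) stop("graph file violates invariants: ",
                     paste(ok$violations, collapse = "; "))
  g
}

#' @rdname read_graph
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "vessel_graph"))
  nd <- graph$nodes
  nodes <- lapply(seq_len(nrow(nd)), function(i)
    list(id = nd$id[i], kind = nd$kind[i],
         position_mm = c(nd$x[i], nd$y[i], nd$z[i])))
  obj <- list(schema_version = 1, nodes = nodes,
              segments = graph$segments, ostia = graph$ostia)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
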