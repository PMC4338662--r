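#' Vessel segments
#'
#' A vessel segment is either an unbranched region of a large blood
#' vessel, or one of the three serial components of an organ
#' microcirculation (an aggregate of arterioles, of capillaries, or of
#' venules). Flow direction is explicit: `upstream` and `downstream` name
#' junction nodes, and venous segments point toward the heart.
#'
#' @param segment_id Identifier string.
#' @param kind One of `"artery"`, `"vein"`, `"arteriole_aggregate"`,
#'   `"capillary_aggregate"`, `"venule_aggregate"`.
#' @param anatomy_term [ontology_term()] or id string; every segment
#'   carries exactly one anatomy annotation.
#' @param length_m Segment length in metres (> 0).
#' @param radius_m Reference radius in metres (> 0).
#' @param upstream,downstream Junction node ids.
#' @return A `vessel_segment` object.
#' @export
vessel_segment <- function(segment_id,
                           kind = c("artery", "vein", "arteriole_aggregate",
                                    "capillary_aggregate", "venule_aggregate"),
                           anatomy_term, length_m, radius_m,
                           upstream, downstream) {
  kind <- match.arg(kind)
  if (!is.character(segment_id) || length(segment_id) != 1L ||
      !nzchar(segment_id))
    stop("segment_id must be a non-empty string", call. = FALSE)
  structure(list(segment_id = segment_id, kind = kind,
                 anatomy_term = term_id(anatomy_term),
                 length_m = as.numeric(length_m),
                 radius_m = as.numeric(radius_m),
                 upstream = as.character(upstream),
                 downstream = as.character(downstream)),
            class = "vessel_segment")
}

#' Microcirculation components
#'
#' A serial connection between an aggregate of arterioles, an aggregate
#' of capillaries and an aggregate of venules, in this order, supplying
#' and draining one organ region.
#'
#' @param component_id Identifier.
#' @param region_term Anatomy term of the supplied/drained organ region.
#' @param arteriole_id,capillary_id,venule_id Member segment ids.
#' @param ptm_ref Optional id of the associated primary tissue motif.
#' @return A `microcirculation` object.
#' @export
microcirculation <- function(component_id, region_term, arteriole_id,
                             capillary_id, venule_id, ptm_ref = NULL) {
  structure(list(component_id = component_id,
                 region_term = term_id(region_term),
                 arteriole_id = arteriole_id, capillary_id = capillary_id,
                 venule_id = venule_id, ptm_ref = ptm_ref),
            class = "microcirculation")
}

#' Vascular network knowledgebase
#'
#' A typed directed graph over vessel segments: segment-to-segment
#' connectivity is implied by shared junction nodes in the direction of
#' flow; `branches` records the order in which child vessels originate
#' along their parent (as a fraction of parent length in `[0, 1]`, ties
#' broken by declaration order); `relations` holds
#' `has_branch` / `supplies` / `drains` triples. `supplies`/`drains`
#' relations may name either a microcirculation component id or its
#' region term; they are normalised to the component.
#'
#' @param segments List of [vessel_segment()].
#' @param microcirculations List of [microcirculation()].
#' @param branches Data frame with columns `parent`, `child`,
#'   `origin_fraction`.
#' @param relations Data frame with columns `subject`, `predicate`
#'   (`has_branch`, `supplies`, `drains`), `object`.
#' @return A `vascular_network` object.
#' @export
vascular_network <- function(segments = list(), microcirculations = list(),
                             branches = NULL, relations = NULL) {
  if (is.null(branches))
    branches <- data.frame(parent = character(), child = character(),
                           origin_fraction = numeric())
  if (is.null(relations))
    relations <- data.frame(subject = character(), predicate = character(),
                            object = character())
  ids <- vapply(segments, function(s) s$segment_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate segment ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(segments) <- ids
  mids <- vapply(microcirculations, function(m) m$component_id, character(1))
  names(microcirculations) <- mids
  net <- structure(list(segments = segments,
                        microcirculations = microcirculations,
                        branches = branches, relations = relations),
                   class = "vascular_network")
  normalize_relations(net)
}

## supplies/drains triples given against a region term are rewritten to
## the microcirculation component carrying that region.
normalize_relations <- function(net) {
  if (nrow(net$relations) == 0 || length(net$microcirculations) == 0)
    return(net)
  region_of <- vapply(net$microcirculations, function(m) m$region_term,
                      character(1))
  comp_by_region <- stats::setNames(names(region_of), region_of)
  rel <- net$relations
  sup <- rel$predicate == "supplies" & rel$object %in% names(comp_by_region)
  rel$object[sup] <- unname(comp_by_region[rel$object[sup]])
  drn <- rel$predicate == "drains" & rel$subject %in% names(comp_by_region)
  rel$subject[drn] <- unname(comp_by_region[rel$subject[drn]])
  net$relations <- rel
  net
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf(paste0("vascular network: %d segments, %d microcirculations, ",
                     "%d branch records, %d relations\n"),
              length(x$segments), length(x$microcirculations),
              nrow(x$branches), nrow(x$relations)))
  invisible(x)
}

#' Directed segment-adjacency graph of a network
#'
#' Vertices are segments; an edge runs A -> B when A's downstream node is
#' B's upstream node (flow direction).
#'
#' @param net A [vascular_network()].
#' @return An igraph graph.
#' @export
as_igraph <- function(net) {
  ids <- names(net$segments)
  dn <- vapply(net$segments, function(s) s$downstream, character(1))
  up <- vapply(net$segments, function(s) s$upstream, character(1))
  ft <- do.call(rbind, lapply(ids, function(a) {
    b <- ids[up == dn[[a]]]
    if (length(b)) cbind(a, b) else NULL
  }))
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (!is.null(ft)) g <- igraph::add_edges(g, as.vector(t(ft)))
  g
}

#' Validate a vascular network
#'
#' Checks the knowledgebase invariants: positive geometry and one anatomy
#' term per segment; microcirculations wired serially
#' arteriole -> capillary -> venule with kinds matching positions; branch
#' lists free of duplicates and referring to known segments; the segment
#' graph connected (as the cardiovascular system is one connected series
#' of vessel segments); and every microcirculation's region present in at
#' least one `supplies` and one `drains` relation.
#'
#' @param net A [vascular_network()].
#' @return A `validation_report`: data frame with columns `rule`,
#'   `object`, `message`; zero rows iff the network is valid.
#' @export
validate_network <- function(net) {
  bad <- list()
  note <- function(rule, object, message)
    bad[[length(bad) + 1L]] <<- data.frame(rule = rule, object = object,
                                           message = message)
  ids <- names(net$segments)
  for (s in net$segments) {
    if (!isTRUE(s$length_m > 0))
      note("geometry", s$segment_id, "length must be > 0")
    if (!isTRUE(s$radius_m > 0))
      note("geometry", s$segment_id, "reference radius must be > 0")
    if (is.null(s$anatomy_term) || !nzchar(s$anatomy_term))
      note("annotation", s$segment_id, "missing anatomy term")
  }
  for (m in net$microcirculations) {
    mem <- c(m$arteriole_id, m$capillary_id, m$venule_id)
    if (!all(mem %in% ids)) {
      note("microcirculation", m$component_id,
           paste("unknown member segment(s):",
                 paste(setdiff(mem, ids), collapse = ", ")))
      next
    }
    kinds <- vapply(net$segments[mem], function(s) s$kind, character(1))
    want <- c("arteriole_aggregate", "capillary_aggregate", "venule_aggregate")
    if (!identical(unname(kinds), want))
      note("microcirculation", m$component_id,
           "member kinds must be arteriole, capillary, venule in this order")
    a <- net$segments[[m$arteriole_id]]; cp <- net$segments[[m$capillary_id]]
    v <- net$segments[[m$venule_id]]
    if (!identical(a$downstream, cp$upstream) ||
        !identical(cp$downstream, v$upstream))
      note("microcirculation", m$component_id,
           "members not serially connected arteriole -> capillary -> venule")
  }
  if (nrow(net$branches) > 0) {
    for (p in unique(net$branches$parent)) {
      ch <- net$branches$child[net$branches$parent == p]
      if (anyDuplicated(ch))
        note("branch_order", p, "duplicate children in branch list")
      if (!(p %in% ids)) note("branch_order", p, "unknown parent segment")
      if (!all(ch %in% ids))
        note("branch_order", p, paste("unknown child segment(s):",
                                      paste(setdiff(ch, ids), collapse = ", ")))
    }
  }
  if (length(net$segments) > 1) {
    g <- as_igraph(net)
    comp <- igraph::components(g, mode = "weak")
    if (comp$no > 1) {
      main <- which.max(comp$csize)
      for (iso in names(comp$membership)[comp$membership != main])
        note("connectivity", iso, "segment disconnected from the main network")
    }
  }
  rel <- net$relations
  for (m in net$microcirculations) {
    has_sup <- any(rel$predicate == "supplies" & rel$object == m$component_id)
    has_drn <- any(rel$predicate == "drains" & rel$subject == m$component_id)
    if (!has_sup)
      note("supplies", m$component_id, "region has no supplies relation")
    if (!has_drn)
      note("drains", m$component_id, "region has no drains relation")
  }
  rep <- if (length(bad)) do.call(rbind, bad)
         else data.frame(rule = character(), object = character(),
                         message = character())
  structure(rep, class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) cat("network valid: no violations\n")
  else {
    cat(sprintf("network INVALID: %d violation(s)\n", nrow(x)))
    print.data.frame(x)
  }
  invisible(x)
}

#' @rdname validate_network
#' @export
is_valid_network <- function(net) nrow(validate_network(net)) == 0

## segments annotated with a term; for region terms, entry is the
## microcirculation's arteriole aggregate (where blood enters the
## region's exchange bed) and exit its venule aggregate.
segments_for_term <- function(net, term, role = c("source", "target")) {
  role <- match.arg(role)
  term <- term_id(term)
  hits <- names(net$segments)[vapply(net$segments,
                                     function(s) identical(s$anatomy_term, term),
                                     logical(1))]
  for (m in net$microcirculations) {
    if (identical(m$region_term, term))
      hits <- c(hits, if (role == "source") m$venule_id else m$arteriole_id)
  }
  unique(hits)
}

#' Anatomical route finding
#'
#' Enumerates simple directed routes (in flow direction:
#' artery -> microcirculation -> vein) between two anatomical locations,
#' answering: via which compartments must a ligand released at the source
#' transit to reach the target? Terms may annotate vessel segments or
#' microcirculation regions; a route into a region ends at that region's
#' arteriole aggregate, and a route out of a region starts at its venule
#' aggregate. Routes are returned shortest first (segment count, ties by
#' lexicographic segment ids), at most `max_routes`.
#'
#' @param net A [vascular_network()].
#' @param source_term,target_term [ontology_term()]s or id strings.
#' @param max_routes Maximum number of routes returned.
#' @return List of `route` objects (empty when no path exists). A query
#'   from a term to itself yields one zero-transit route holding just the
#'   annotated segment.
#' @export
find_routes <- function(net, source_term, target_term, max_routes = 10L) {
  src_id <- term_id(source_term); tgt_id <- term_id(target_term)
  make_route <- function(segs)
    structure(list(segments = segs, source = src_id, target = tgt_id),
              class = "route")
  if (identical(src_id, tgt_id)) {
    hits <- segments_for_term(net, src_id, "target")
    if (!length(hits))
      stop("term not found in network: ", src_id, call. = FALSE)
    return(list(make_route(hits[1])))
  }
  from <- segments_for_term(net, src_id, "source")
  to <- segments_for_term(net, tgt_id, "target")
  if (!length(from)) stop("term not found in network: ", src_id, call. = FALSE)
  if (!length(to)) stop("term not found in network: ", tgt_id, call. = FALSE)
  g <- as_igraph(net)
  paths <- list()
  for (f in from) for (t in to) {
    if (identical(f, t)) { paths <- c(paths, list(f)); next }
    sp <- igraph::all_simple_paths(g, from = f, to = t, mode = "out")
    paths <- c(paths, lapply(sp, function(p) igraph::V(g)$name[as.integer(p)]))
  }
  paths <- Filter(function(p) route_ok(net, p), paths)
  if (!length(paths)) return(list())
  key <- vapply(paths, function(p) paste(p, collapse = "\r"), character(1))
  paths <- paths[!duplicated(key)]
  ord <- order(lengths(paths),
               vapply(paths, function(p) paste(p, collapse = "\r"), character(1)))
  paths <- paths[ord]
  lapply(paths[seq_len(min(max_routes, length(paths)))], make_route)
}

#' @export
print.route <- function(x, ...) {
  cat(sprintf("route %s -> %s (%d segments):\n  %s\n", x$source, x$target,
              length(x$segments), paste(x$segments, collapse = " -> ")))
  invisible(x)
}

## a candidate path is a legal route when consecutive segments share a
## junction, no segment repeats, and every microcirculation it traverses
## is visited arteriole -> capillary -> venule in order (truncation at the
## route's own endpoints allowed).
route_ok <- function(net, segs) {
  if (anyDuplicated(segs)) return(FALSE)
  if (length(segs) > 1) {
    for (i in seq_len(length(segs) - 1)) {
      a <- net$segments[[segs[i]]]; b <- net$segments[[segs[i + 1]]]
      if (!identical(a$downstream, b$upstream)) return(FALSE)
    }
  }
  for (m in net$microcirculations) {
    mem <- c(m$arteriole_id, m$capillary_id, m$venule_id)
    pos <- match(mem, segs)
    pres <- which(!is.na(pos))
    if (length(pres) == 0) next
    ## present members must appear in a->c->v order and contiguously
    if (is.unsorted(pos[pres], strictly = TRUE)) return(FALSE)
    if (length(pres) > 1 && any(diff(pos[pres]) != 1)) return(FALSE)
    ## no skipping the capillary between arteriole and venule
    if (all(c(1, 3) %in% pres) && !(2 %in% pres)) return(FALSE)
  }
  TRUE
}

#' Validate a single route against a network
#'
#' @param net A [vascular_network()].
#' @param route A `route` (or character vector of segment ids).
#' @return TRUE/FALSE.
#' @export
validate_route <- function(net, route) {
  segs <- if (inherits(route, "route")) route$segments else route
  all(segs %in% names(net$segments)) && route_ok(net, segs)
}

#' Molecular entities encountered along a route
#'
#' Given tissue-specific expression (anatomy term -> molecule ids) and an
#' interaction table (ligand -> interacting molecule ids), reports, for
#' each route segment in order, which target or off-target interactors of
#' the ligand are expressed there.
#'
#' @param route A `route`.
#' @param net The [vascular_network()] the route was found on.
#' @param expression_map Named list: anatomy term id -> character vector
#'   of molecule ids expressed there.
#' @param ligand Molecule id.
#' @param interactors Named list: molecule id -> character vector of its
#'   interactors.
#' @return List of `list(segment_id, encountered)` entries, route order,
#'   only segments with at least one encounter. Unknown ligand yields an
#'   empty list with a warning.
#' @export
entities_en_route <- function(route, net, expression_map, ligand, interactors) {
  if (!ligand %in% names(interactors)) {
    warning("ligand ", ligand, " absent from interactor table")
    return(list())
  }
  partners <- interactors[[ligand]]
  out <- list()
  segs <- if (inherits(route, "route")) route$segments else route
  for (sid in segs) {
    term <- net$segments[[sid]]$anatomy_term
    expressed <- expression_map[[term]]
    enc <- intersect(expressed, partners)
    if (length(enc))
      out[[length(out) + 1L]] <- list(segment_id = sid, encountered = enc)
  }
  out
}

#' Ordered branch sequence of a parent vessel
#'
#' Children sorted by the fraction of the parent's length at which they
#' originate (ties broken by declaration order); the ordinal position in
#' the returned vector is the origin order along the parent.
#'
#' @param net A [vascular_network()].
#' @param parent_segment_id Parent segment id.
#' @return Character vector of child segment ids (empty for a leaf).
#' @export
branch_sequence <- function(net, parent_segment_id) {
  if (!parent_segment_id %in% names(net$segments))
    stop("unknown parent segment: ", parent_segment_id, call. = FALSE)
  b <- net$branches[net$branches$parent == parent_segment_id, , drop = FALSE]
  if (nrow(b) == 0) return(character(0))
  b$child[order(b$origin_fraction)] # order() is stable: declaration ties kept
}
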