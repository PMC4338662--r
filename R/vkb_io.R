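#' Read and write vascular networks as JSON
#'
#' Schema: an object with arrays `segments`
#' (`id, kind, anatomy_term, length_m, radius_m, upstream, downstream`),
#' `microcirculations` (`id, region_term, arteriole, capillary, venule,
#' ptm_ref`), `branches` (`parent, child, origin_fraction`) and
#' `relations` (`subject, predicate, object`). Serialisation followed by
#' deserialisation is the identity on the in-memory network, including
#' branch declaration order.
#'
#' @param net A [vascular_network()].
#' @param path JSON file path.
#' @return `write_network` returns `path` invisibly; `read_network` the
#'   network. Malformed records raise a parse error naming the record.
#' @export
write_network <- function(net, path) {
  segs <- lapply(net$segments, function(s)
    list(id = s$segment_id, kind = s$kind, anatomy_term = s$anatomy_term,
         length_m = s$length_m, radius_m = s$radius_m,
         upstream = s$upstream, downstream = s$downstream))
  mics <- lapply(net$microcirculations, function(m)
    list(id = m$component_id, region_term = m$region_term,
         arteriole = m$arteriole_id, capillary = m$capillary_id,
         venule = m$venule_id,
         ptm_ref = if (is.null(m$ptm_ref)) NULL else m$ptm_ref))
  obj <- list(segments = unname(segs), microcirculations = unname(mics),
              branches = net$branches, relations = net$relations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- function(rec, field, where, i) {
    v <- rec[[field]]
    if (is.null(v) || (is.character(v) && !nzchar(v)))
      stop(sprintf("parse error in %s record %d: missing or empty '%s'",
                   where, i, field), call. = FALSE)
    v
  }
  segments <- lapply(seq_along(obj$segments), function(i) {
    r <- obj$segments[[i]]
    vessel_segment(need(r, "id", "segment", i), r$kind,
                   need(r, "anatomy_term", "segment", i),
                   r$length_m, r$radius_m,
                   need(r, "upstream", "segment", i),
                   need(r, "downstream", "segment", i))
  })
  mics <- lapply(seq_along(obj$microcirculations), function(i) {
    r <- obj$microcirculations[[i]]
    microcirculation(need(r, "id", "microcirculation", i),
                     need(r, "region_term", "microcirculation", i),
                     r$arteriole, r$capillary, r$venule, r$ptm_ref)
  })
  todf <- function(x, cols) {
    if (length(x) == 0) {
      df <- as.data.frame(stats::setNames(
        replicate(length(cols), character(0), simplify = FALSE), cols))
      if ("origin_fraction" %in% cols) df$origin_fraction <- numeric(0)
      return(df)
    }
    do.call(rbind, lapply(x, function(r) as.data.frame(r[cols])))
  }
  branches <- todf(obj$branches, c("parent", "child", "origin_fraction"))
  relations <- todf(obj$relations, c("subject", "predicate", "object"))
  vascular_network(segments, mics, branches, relations)
}

#' Export a network to GraphML
#'
#' Writes the directed segment-adjacency graph with kind and anatomy-term
#' vertex attributes, for use in external graph tools.
#'
#' @param net A [vascular_network()].
#' @param path Output GraphML path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::V(g)$kind <- vapply(net$segments[igraph::V(g)$name],
                              function(s) s$kind, character(1))
  igraph::V(g)$anatomy_term <- vapply(net$segments[igraph::V(g)$name],
                                      function(s) s$anatomy_term, character(1))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
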