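test_that("a well-formed network validates cleanly and violations are named", {
  net <- toy_kidney_network()
  rep <- validate_network(net)
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep), 0)
  expect_true(is_valid_network(net))

  ## microcirculation wired capillary -> arteriole -> venule: the only
  ## legal serial order is arteriole -> capillary -> venule
  bad <- net
  bad$microcirculations[["kidney_bed"]] <-
    microcirculation("kidney_bed", "FMA:kidney", "capillaries",
                     "arterioles", "venules")
  rep <- validate_network(bad)
  expect_true(any(rep$rule == "microcirculation" &
                    rep$object == "kidney_bed"))

  ## isolated segment is reported by id
  iso <- toy_kidney_network()
  iso$segments[["island"]] <- vessel_segment(
    "island", "artery", "FMA:island", 0.01, 1e-3, "zz1", "zz2")
  rep <- validate_network(iso)
  expect_true(any(rep$rule == "connectivity" & rep$object == "island"))

  ## non-positive geometry and missing supplies/drains
  bad2 <- toy_kidney_network()
  bad2$segments[["aorta"]]$length_m <- -1
  bad2$relations <- bad2$relations[0, ]
  rep <- validate_network(bad2)
  expect_true(any(rep$rule == "geometry" & rep$object == "aorta"))
  expect_true(any(rep$rule == "supplies"))
  expect_true(any(rep$rule == "drains"))
})

test_that("supplies/drains against a region term normalise to the component", {
  net <- toy_kidney_network()
  rel <- data.frame(subject = c("renal_art", "FMA:kidney"),
                    predicate = c("supplies", "drains"),
                    object = c("FMA:kidney", "renal_vein"))
  net2 <- vascular_network(unname(net$segments),
                           unname(net$microcirculations),
                           net$branches, rel)
  expect_true(is_valid_network(net2))
  expect_true(all(net2$relations$object[net2$relations$predicate ==
                                          "supplies"] == "kidney_bed"))
})

test_that("route finding matches the exhaustive DFS oracle", {
  ## unique arterial route heart -> kidney region (ends at the arteriole
  ## aggregate, where blood enters the exchange bed)
  net <- toy_kidney_network()
  r <- find_routes(net, "FMA:heart", "FMA:kidney")
  expect_length(r, 1)
  expect_equal(r[[1]]$segments,
               c("heart", "aorta", "renal_art", "arterioles"))
  oracle <- dfs_paths(net, "heart", "arterioles")
  expect_equal(lapply(r, `[[`, "segments"), oracle)

  ## two parallel supplying arteries: 2 routes, shorter first
  net2 <- toy_kidney_network(parallel_artery = TRUE)
  r2 <- find_routes(net2, "FMA:heart", "FMA:kidney")
  expect_length(r2, 2)
  expect_true(length(r2[[1]]$segments) <= length(r2[[2]]$segments))
  oracle2 <- dfs_paths(net2, "heart", "arterioles")
  expect_setequal(vapply(r2, function(x) paste(x$segments, collapse = ">"),
                         character(1)),
                  vapply(oracle2, paste, character(1), collapse = ">"))

  ## source == target: single zero-transit route
  r3 <- find_routes(net, "FMA:aorta", "FMA:aorta")
  expect_length(r3, 1)
  expect_equal(r3[[1]]$segments, "aorta")

  ## unknown term errors; unreachable target yields an empty list
  expect_error(find_routes(net, "FMA:nope", "FMA:kidney"), "not found")
  expect_equal(find_routes(net, "FMA:vena-cava", "FMA:heart"), list())
})

test_that("route enumeration matches DFS on generated trees (oracle sweep)", {
  for (depth in 2:3) {
    tree <- make_vascular_tree(depth, seed = depth)
    net <- tree$network
    expect_lte(length(net$segments), 30)
    routes <- find_routes(net, "FMA:artery-1", "FMA:vein-1",
                          max_routes = 1000L)
    oracle <- dfs_paths(net, "art_1", "vein_1")
    expect_setequal(
      vapply(routes, function(x) paste(x$segments, collapse = ">"),
             character(1)),
      vapply(oracle, paste, character(1), collapse = ">"))
    expect_true(all(vapply(routes, validate_route, logical(1), net = net)))
    ## shortest-first ordering
    expect_true(!is.unsorted(lengths(lapply(routes, `[[`, "segments"))))
  }
})

test_that("every returned route traverses microcirculations in order", {
  tree <- make_vascular_tree(3, seed = 11)
  routes <- find_routes(tree$network, "FMA:artery-1", "FMA:vein-1",
                        max_routes = 100L)
  expect_gt(length(routes), 0)
  for (r in routes) {
    kinds <- vapply(tree$network$segments[r$segments], function(s) s$kind,
                    character(1))
    mc <- kinds[kinds %in% c("arteriole_aggregate", "capillary_aggregate",
                             "venule_aggregate")]
    expect_equal(unname(mc), c("arteriole_aggregate", "capillary_aggregate",
                               "venule_aggregate"))
  }
})

test_that("entities en route reports interactors in route order", {
  net <- toy_kidney_network()
  route <- find_routes(net, "FMA:heart", "FMA:kidney")[[1]]
  emap <- list("FMA:heart" = c("R_off"),
               "FMA:renal-artery" = c("R_tgt", "X"))
  ints <- list(ligandA = c("R_tgt", "R_off"))
  enc <- entities_en_route(route, net, emap, "ligandA", ints)
  expect_length(enc, 2)
  expect_equal(enc[[1]]$segment_id, "heart")
  expect_equal(enc[[1]]$encountered, "R_off")
  expect_equal(enc[[2]]$segment_id, "renal_art")
  expect_equal(enc[[2]]$encountered, "R_tgt")

  ## empty expression map: nothing encountered
  expect_length(entities_en_route(route, net, list(), "ligandA", ints), 0)
  ## unknown ligand: empty with warning
  expect_warning(out <- entities_en_route(route, net, emap, "nope", ints),
                 "absent")
  expect_length(out, 0)
})

test_that("branch sequences sort by origin fraction with stable ties", {
  net <- toy_kidney_network()
  net$branches <- data.frame(
    parent = rep("aorta", 3),
    child = c("c3", "c1", "c2"),
    origin_fraction = c(0.7, 0.2, 0.5))
  expect_equal(branch_sequence(net, "aorta"), c("c1", "c2", "c3"))
  expect_equal(branch_sequence(net, "heart"), character(0))
  expect_error(branch_sequence(net, "nope"), "unknown parent")
  ## declaration order breaks ties
  net$branches <- data.frame(parent = "aorta", child = c("b", "a"),
                             origin_fraction = c(0.5, 0.5))
  expect_equal(branch_sequence(net, "aorta"), c("b", "a"))
})

test_that("network JSON round-trip is the identity, preserving branch order", {
  net <- toy_kidney_network(parallel_artery = TRUE)
  net$branches <- data.frame(parent = "aorta", child = c("z", "a"),
                             origin_fraction = c(0.5, 0.5))
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f)
  net2 <- read_network(f)
  expect_equal(net2, net)
  expect_equal(branch_sequence(net2, "aorta"), c("z", "a"))

  ## malformed record: parse error naming it
  obj <- jsonlite::read_json(f, simplifyVector = FALSE)
  obj$segments[[2]]$id <- ""
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_network(f2), "segment record 2")
})

test_that("GraphML export is readable by igraph with annotations", {
  net <- toy_kidney_network()
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(sort(igraph::V(g)$name), sort(names(net$segments)))
  expect_true("anatomy_term" %in% igraph::vertex_attr_names(g))
})
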