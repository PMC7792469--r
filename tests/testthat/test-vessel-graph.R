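test_that("validate_graph accepts a minimal tree and reports violations", {
  g <- single_segment_graph(diameter_mm = 3, length_mm = 10)
  expect_true(validate_graph(g)$pass)

  # directed cycle among artery segments
  gc <- g
  gc$segments <- rbind(gc$segments, within(gc$segments[1, ], {
    id <- "s2"; from <- "n_tip"; to <- "n_root"
  }))
  gc$nodes$kind[gc$nodes$kind == "terminal"] <- "junction"
  v <- validate_graph(gc)
  expect_false(v$pass)
  expect_true(any(grepl("cycle|incoming", v$violations)))

  gl <- g
  gl$segments$length_mm <- 0
  v <- validate_graph(gl)
  expect_false(v$pass)
  expect_true("nonpositive length" %in% v$violations)

  gd <- g
  gd$nodes <- rbind(gd$nodes, gd$nodes[1, ])
  expect_false(validate_graph(gd)$pass)
})

test_that("apply_stenosis narrows, splits and conserves length", {
  g <- single_segment_graph(diameter_mm = 3, length_mm = 10)
  s <- apply_stenosis(g, stenosis_spec("s1", 0.5, 0.3))
  sten <- s$segments[s$segments$ffr_site, ]
  expect_equal(sten$effective_diameter_mm, 1.5)
  expect_equal(nrow(s$segments), 3)
  expect_equal(sum(s$segments$length_mm), 10, tolerance = 1e-12)

  # 80% stenosis: effective diameter is 20% of reference
  s8 <- apply_stenosis(g, stenosis_spec("s1", 0.8, 0.5))
  expect_equal(s8$segments$effective_diameter_mm[s8$segments$ffr_site],
               0.2 * 3)

  # degenerate extent: whole segment narrowed, no split
  sf <- apply_stenosis(g, stenosis_spec("s1", 0.4, 1.0))
  expect_equal(nrow(sf$segments), 1)
  expect_equal(sf$segments$effective_diameter_mm, 1.8)
  expect_true(sf$segments$ffr_site)

  expect_error(apply_stenosis(g, stenosis_spec("nope", 0.5)), "unknown segment")
  expect_error(stenosis_spec("s1", 1.2), "diameter_reduction")
  expect_error(stenosis_spec("s1", 0), "diameter_reduction")
})

test_that("stenosis editing properties hold on random trees", {
  for (sd in 1:5) {
    g <- make_coronary_tree(seed = sd)
    total <- sum(g$segments$length_mm)
    pick <- g$segments$id[1 + sd %% nrow(g$segments)]
    red <- 0.3 + 0.05 * sd
    s <- apply_stenosis(g, stenosis_spec(pick, red, 0.25))
    expect_equal(sum(s$segments$length_mm), total, tolerance = 1e-9)
    expect_true(all(s$segments$effective_diameter_mm <=
                      s$segments$reference_diameter_mm + 1e-12))
    expect_true(validate_graph(s)$pass)
    # exactly the stenotic edge is narrowed
    narrowed <- s$segments$effective_diameter_mm <
      s$segments$reference_diameter_mm - 1e-12
    expect_identical(narrowed, s$segments$ffr_site)
  }
})

test_that("prune_nonarterial removes veins and protects FFR sites", {
  g <- graph_with_vein()
  p <- prune_nonarterial(g)
  expect_false(any(p$segments$label == "vein"))
  expect_true(validate_graph(p)$pass)
  expect_equal(nrow(p$segments), 3)

  # all-artery graph unchanged
  ga <- single_segment_graph()
  expect_equal(prune_nonarterial(ga)$segments, ga$segments)

  # vein is the only path from the ostium to a marked site -> error
  gv <- graph_with_vein()
  gv$segments$label[gv$segments$id == "trunk"] <- "vein"
  gv$segments$ffr_site[gv$segments$id == "b2"] <- TRUE
  expect_error(prune_nonarterial(gv), "b2")
  # a site marked on a vein edge itself is also rejected
  gw <- graph_with_vein()
  gw$segments$ffr_site[gw$segments$id == "vein1"] <- TRUE
  expect_error(prune_nonarterial(gw), "vein1")
})

test_that("graph JSON roundtrip is the identity and bad files are rejected", {
  g <- apply_stenosis(make_coronary_tree(seed = 2), stenosis_spec("s_LAD", 0.6))
  tf <- withr::local_tempfile(fileext = ".json")
  write_graph(g, tf)
  g2 <- read_graph(tf)
  for (cc in names(g$segments))
    expect_equal(g2$segments[[cc]], g$segments[[cc]], tolerance = 1e-12)
  expect_equal(g2$ostia, g$ostia)
  expect_equal(g2$nodes$x, g$nodes$x, tolerance = 1e-12)

  # missing required field
  j <- jsonlite::fromJSON(tf, simplifyVector = TRUE)
  j$segments$reference_diameter_mm <- NULL
  tf2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j, tf2, auto_unbox = TRUE, digits = NA)
  expect_error(read_graph(tf2), "reference_diameter_mm")

  # duplicate node id
  j <- jsonlite::fromJSON(tf, simplifyVector = FALSE)
  j$nodes[[length(j$nodes) + 1]] <- j$nodes[[1]]
  tf3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j, tf3, auto_unbox = TRUE, digits = NA)
  expect_error(read_graph(tf3), "duplicate")

  # unknown schema version
  j <- jsonlite::fromJSON(tf, simplifyVector = TRUE)
  j$schema_version <- 99
  tf4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j, tf4, auto_unbox = TRUE, digits = NA)
  expect_error(read_graph(tf4), "schema")
})
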