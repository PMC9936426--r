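# interactome construction, validation, synonyms, file round trips

test_that("parsing minimal edge files, with sign aliases", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,sign,weight",
               "A,B,activates,1",
               "B,C,-1,1"), path)
  net <- parse_network(path, "edge_csv")
  expect_s3_class(net, "interactome")
  expect_equal(n_nodes(net), 3)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("activates", "inhibits"))
})

test_that("empty edge file with a one-node node file gives N = 1", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("source,target,sign,weight", path)
  nodes_path <- paste0(sub("\\.csv$", "", path), ".nodes.csv")
  writeLines(c("node,category,h,gamma", "solo,other,10,1"), nodes_path)
  net <- parse_network(path, "edge_csv")
  expect_equal(n_nodes(net), 1)
  expect_equal(nrow(net$edges), 0)
  expect_equal(net$nodes$id, "solo")
})

test_that("malformed and contradictory inputs are rejected with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,sign,weight", "A,B,activates,1", "oops"), path)
  expect_error(parse_network(path), class = "cnet_parse_error")
  expect_error(parse_network(path), "line 3")

  writeLines(c("source,target,sign,weight", "A,B,sometimes,1"), path)
  expect_error(parse_network(path), class = "cnet_parse_error")

  contradictory <- toy_edges("A", "B", "activates", "A", "B", "inhibits")
  expect_error(interactome(edges = contradictory),
               class = "cnet_validation_error")
  net <- interactome(edges = contradictory, allow_contradictory = TRUE)
  expect_equal(nrow(net$edges), 2)

  expect_error(
    interactome(edges = toy_edges("A", "B", "activates"),
                switch_rules = list(switch_rule("Z", 0.5))),
    class = "cnet_validation_error")
  expect_error(
    interactome(edges = toy_edges("A", "B", "activates"),
                switch_rules = list(
                  switch_rule("A", 0.5, list(flip_sign("B", "A"))))),
    class = "cnet_validation_error")
})

test_that("round trip parse(serialize(net)) is the identity, both dialects", {
  for (seed in 1:5) {
    net <- make_random_network(12, 30, inhibitor_fraction = 0.4, seed = seed)
    for (fmt in c("edge_csv", "sif")) {
      path <- withr::local_tempfile(
        fileext = if (fmt == "sif") ".sif" else ".csv")
      serialize_network(net, path, fmt)
      back <- parse_network(path, fmt)
      expect_identical(edge_signature(back), edge_signature(net))
      expect_identical(sort(back$nodes$id), sort(net$nodes$id))
    }
  }
})

test_that("switch rules survive a round trip and SIF refuses weights", {
  net <- make_motif("rgd_switch_motif")
  path <- withr::local_tempfile(fileext = ".csv")
  serialize_network(net, path, "edge_csv")
  back <- parse_network(path, "edge_csv")
  expect_length(back$switch_rules, 2)
  expect_identical(
    lapply(back$switch_rules, unclass),
    lapply(net$switch_rules, unclass))

  heavy <- interactome(edges = data.frame(
    source = "A", target = "B", sign = "activates", weight = 2))
  expect_error(
    serialize_network(heavy, withr::local_tempfile(fileext = ".sif"), "sif"),
    class = "cnet_io_error")
})

test_that("synonym canonicalization is case-insensitive and fails loudly", {
  expect_equal(canonical_node_id(c("HIF2", "hif2a", "NF-kB", "ADAMT4")),
               c("HIF2a", "HIF2a", "NFkB", "ADAMTS4"))
  expect_equal(canonical_node_id("totally_new_node"), "totally_new_node")
  net <- load_reduced_network()
  expect_equal(resolve_nodes(net, c("nf-kb", "Adamt5")),
               c("NFkB", "ADAMTS5"))
  expect_error(resolve_nodes(net, "no_such_protein"),
               class = "cnet_lookup_error")
  # duplicate ids after canonicalization are rejected
  expect_error(interactome(nodes = c("HIF2", "HIF2a")),
               class = "cnet_validation_error")
})

test_that("partition_inputs splits incoming edges exactly by sign", {
  net <- interactome(edges = toy_edges("A", "T", "activates",
                                       "B", "T", "inhibits"))
  p <- partition_inputs(net, "T")
  expect_equal(p$activators$source, "A")
  expect_equal(p$inhibitors$source, "B")
  p0 <- partition_inputs(net, "A")
  expect_equal(nrow(p0$activators) + nrow(p0$inhibitors), 0)
  expect_error(partition_inputs(net, "Z"), class = "cnet_lookup_error")

  # property: partition sizes sum to in-degree, every edge in exactly one
  rnet <- make_random_network(15, 50, 0.5, seed = 11)
  for (id in rnet$nodes$id) {
    p <- partition_inputs(rnet, id)
    indeg <- sum(rnet$edges$target == id)
    expect_equal(nrow(p$activators) + nrow(p$inhibitors), indeg)
  }
})

test_that("the reduced network asset loads with its RGD switch rules", {
  net <- load_reduced_network()
  expect_equal(n_nodes(net), 52)
  expect_equal(nrow(net$edges), 85)
  expect_length(net$switch_rules, 2)
  expect_true(all(vapply(net$switch_rules, function(r) r$watch, "") == "RGD"))
  expect_true(all(vapply(net$switch_rules, function(r) r$threshold, 1) == 0.5))
  # integrins are actin activators in the base (unswitched) topology
  p <- partition_inputs(net, "actin")
  expect_true(all(c("a5b1", "aVb3") %in% p$activators$source))
})

test_that("the curated asset is reported unavailable, pointing at reduced", {
  expect_error(load_curated_network(), class = "cnet_curated_unavailable")
  expect_error(load_curated_network(), "load_reduced_network")
})
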