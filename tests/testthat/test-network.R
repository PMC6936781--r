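test_that("correlations match hand values and guard their preconditions", {
  x <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "g"))
  expect_equal(unname(correlate(x, matrix(c(2, 4, 6), 3, 1))[1, 1]), 1)
  expect_equal(unname(correlate(x, matrix(c(6, 4, 2), 3, 1))[1, 1]), -1)
  expect_equal(unname(correlate(x, matrix(c(1, 3, 2), 3, 1))[1, 1]), 0.5)
  expect_error(correlate(x[1:2, , drop = FALSE],
                         matrix(1:2, 2, 1)), "3 samples")
  # constant column: NA, not silent zero
  r <- correlate(x, matrix(1, 3, 1))
  expect_true(is.na(r[1, 1]))
})

test_that("thresholding is strict and nested across cutoffs", {
  net <- hand_network(0.7)
  expect_equal(nrow(net), 4)           # 0.71, -0.75 in row 1; 0.95, -0.85 in row 2
  expect_false("v2" %in% net$flavor[net$genus == "g1"])  # 0.69 excluded
  # boundary: |r| exactly at the cutoff is excluded
  r <- matrix(c(0.7, 0.8), 1, 2, dimnames = list("g", c("f1", "f2")))
  nb <- threshold_network(r, 0.7)
  expect_equal(nb$flavor, "f2")
  expect_error(threshold_network(r, 1.2), "cutoff")
  # nestedness of the 0.8 network inside the 0.7 network
  for (seed in 1:10) {
    set.seed(seed)
    rm <- matrix(runif(30, -1, 1), 5, 6,
                 dimnames = list(paste0("g", 1:5), paste0("f", 1:6)))
    e7 <- threshold_network(rm, 0.7)
    e8 <- threshold_network(rm, 0.8)
    key <- function(e) paste(e$genus, e$flavor)
    expect_true(all(key(e8) %in% key(e7)))
  }
})

test_that("partner summary counts by flavor class and forms the class lists", {
  net <- hand_network(0.7)
  ps <- partner_summary(net, tiny_annotation())
  # g1: edges to v1 (VF) and a1 (AA); g2: a1 (AA) and v2 (VF)
  expect_equal(ps$total, c(2, 2))
  expect_equal(ps$aa_partners, c(1, 1))
  expect_equal(ps$vf_partners, c(1, 1))
  expect_setequal(attr(ps, "both_genera"),
                  intersect(attr(ps, "aa_genera"), attr(ps, "vf_genera")))
  # empty network: all counts zero, genera preserved
  r0 <- matrix(0.1, 2, 3, dimnames = list(c("g1", "g2"),
                                          c("v1", "v2", "a1")))
  ps0 <- partner_summary(threshold_network(r0, 0.7), tiny_annotation())
  expect_equal(ps0$total, c(0, 0))
  # the both-list identity holds on random networks
  for (seed in 1:10) {
    set.seed(seed)
    rm <- matrix(runif(10, -1, 1), 2, 5,
                 dimnames = list(c("g1", "g2"), tiny_annotation()$component_id))
    ps <- partner_summary(threshold_network(rm, 0.5), tiny_annotation())
    expect_setequal(attr(ps, "both_genera"),
                    intersect(attr(ps, "aa_genera"), attr(ps, "vf_genera")))
  }
  # unannotated flavor is an error
  bad <- hand_network(0.7)
  attr(bad, "flavors") <- c(attr(bad, "flavors"), "ghost")
  bad2 <- rbind(as.data.frame(bad),
                data.frame(genus = "g1", flavor = "ghost", r = 0.9,
                           sign = "positive"))
  attributes(bad2) <- c(attributes(bad2),
                        attributes(bad)[c("threshold", "genera", "flavors")])
  class(bad2) <- class(bad)
  expect_error(partner_summary(bad2, tiny_annotation()), "ghost")
})

test_that("the three-criterion screen is inclusive at its boundaries", {
  genera <- c("all_pass", "low_vip", "vf_only", "boundary")
  summ <- data.frame(genus = genera,
                     total = c(17, 20, 16, 16),
                     aa_partners = c(10, 10, 0, 1),
                     vf_partners = c(7, 10, 16, 15))
  attr(summ, "aa_genera") <- genera[summ$aa_partners >= 1]
  attr(summ, "vf_genera") <- genera[summ$vf_partners >= 1]
  attr(summ, "both_genera") <- genera[summ$aa_partners >= 1 &
                                        summ$vf_partners >= 1]
  class(summ) <- c("partner_summary", "data.frame")
  vip <- c(all_pass = 1.2, low_vip = 0.9, vf_only = 1.5, boundary = 1.0)
  sc <- screen_core(summ, vip)
  expect_setequal(attr(sc, "core_set"), c("all_pass", "boundary"))
  expect_false(sc$core[sc$genus == "low_vip"])    # fails ii
  expect_false(sc$core[sc$genus == "vf_only"])    # fails i
  # VIP = 1.00 and 16 partners are inclusive ("at least")
  expect_true(sc$core[sc$genus == "boundary"])
  expect_error(screen_core(summ, vip[-1]), "missing from VIP")
})

test_that("networks export and re-import losslessly, and emit valid GraphML", {
  net <- hand_network(0.7)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, p1, format = "edge_tsv")
  expect_equal(length(readLines(p1)), nrow(net) + 1)
  back <- read_network(p1, threshold = 0.7,
                       genera = attr(net, "genera"),
                       flavors = attr(net, "flavors"))
  expect_equal(as.data.frame(back), as.data.frame(net))
  expect_equal(attr(back, "threshold"), attr(net, "threshold"))
  skip_if_not_installed("xml2")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, p2, format = "graphml", ann = tiny_annotation())
  doc <- xml2::read_xml(p2)  # well-formed XML with graphml root
  expect_equal(xml2::xml_name(doc), "graphml")
  g <- igraph::read_graph(p2, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net))
  expect_setequal(igraph::vertex_attr(g, "side"),
                  rep(c("genus", "flavor"), c(2, 3)))
})
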