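# PPI/EPPI/CPPI assembly, ranking curves, putative selection, and the
# end-to-end screen.

toy_interactome <- interactome(rbind(
  c("A", "B"), c("B", "C"), c("D", "E"), c("F", "G")
))

test_that("PPI keeps all seeds and only seed-internal edges", {
  ppi <- assemble_ppi(c("A", "B", "C", "D", "H"), toy_interactome)
  expect_setequal(igraph::V(ppi)$name, c("A", "B", "C", "D", "H"))
  expect_equal(igraph::ecount(ppi), 2)
  expect_equal(igraph::degree(ppi)[["D"]], 0)
  expect_equal(igraph::degree(ppi)[["H"]], 0)
  # seeds disjoint from the interactome: all isolated
  ppi2 <- assemble_ppi(c("X", "Y"), toy_interactome)
  expect_equal(igraph::ecount(ppi2), 0)
  # seeds covering the interactome reproduce it
  ppi3 <- assemble_ppi(igraph::V(toy_interactome)$name, toy_interactome)
  expect_equal(igraph::ecount(ppi3), igraph::ecount(toy_interactome))
  expect_error(assemble_ppi(character(), toy_interactome), "empty")
})

test_that("EPPI is the one-hop closure of known targets, induced", {
  path4 <- interactome(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  eppi <- expand_eppi("B", path4)
  expect_setequal(igraph::V(eppi)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(eppi), 2)
  eppi2 <- expand_eppi(c("B", "ZZ"), path4)
  expect_true("ZZ" %in% igraph::V(eppi2)$name)
  expect_equal(igraph::degree(eppi2)[["ZZ"]], 0)
  eppi3 <- expand_eppi(igraph::V(path4)$name, path4)
  expect_equal(igraph::ecount(eppi3), igraph::ecount(path4))
  expect_error(expand_eppi(character(), path4), "empty")
})

test_that("CPPI is the interactome induced on the PPI/EPPI intersection", {
  full <- interactome(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  ppi <- assemble_ppi(c("A", "B", "C"), full)
  eppi <- assemble_ppi(c("B", "C", "D"), full)  # any graphs with node sets
  cppi <- build_cppi(ppi, eppi, full)
  expect_setequal(igraph::V(cppi)$name, c("B", "C"))
  expect_equal(igraph::ecount(cppi), 1)
  expect_error(build_cppi(assemble_ppi("A", full), assemble_ppi("D", full),
                          full),
               "disjoint")
  same <- build_cppi(ppi, ppi, full)
  expect_setequal(igraph::V(same)$name, igraph::V(ppi)$name)
})

test_that("predictive-rate curves count known targets cumulatively", {
  tab <- data.frame(node = c("T1", "X", "T2", "Y"),
                    degree = 1, clustering = 0,
                    betweenness = c(4, 3, 2, 1),
                    bridging = 0, closeness = 0)
  cur <- predictive_rate(tab, c("T1", "T2"), "betweenness")
  expect_equal(cur$hits, c(1, 1, 2, 2))
  expect_identical(cur$node, c("T1", "X", "T2", "Y"))
  expect_equal(predictive_rate(tab, "ZZ", "betweenness")$hits, rep(0, 4))
  expect_equal(predictive_rate(tab, tab$node, "betweenness")$hits, 1:4)
  expect_error(predictive_rate(tab, "T1", "pagerank"))
})

test_that("ties break by symbol so rankings are reproducible", {
  tab <- data.frame(node = c("B", "A", "C"), degree = 1, clustering = 0,
                    betweenness = c(1, 1, 1), bridging = 0, closeness = 0)
  cur <- predictive_rate(tab, character(0), "betweenness")
  expect_identical(cur$node, c("A", "B", "C"))
})

test_that("putative selection is the top fraction minus known targets", {
  tab <- data.frame(node = sprintf("N%02d", 1:10), degree = 1,
                    clustering = 0, betweenness = 10:1, bridging = 0,
                    closeness = 0)
  tab$node[3] <- "T1"
  put <- select_putative(tab, "T1", top_fraction = 0.30)
  expect_setequal(put$symbols, c("N01", "N02"))
  all_min_known <- select_putative(tab, "T1", top_fraction = 1.0)
  expect_setequal(all_min_known$symbols, setdiff(tab$node, "T1"))
  expect_error(select_putative(tab, "T1", top_fraction = 0))
})

test_that("the full screen equals its stage-by-stage composition", {
  cfg <- synth_config(rng_seed = 17)
  net <- make_interactome(cfg)
  seeds <- make_seed_genes(cfg, net)
  known <- net$roles$known
  res <- run_screen(seeds, known, net$graph)

  ppi <- assemble_ppi(seeds, net$graph)
  eppi <- expand_eppi(known, net$graph)
  cppi <- build_cppi(ppi, eppi, net$graph)
  tab <- centrality_table(cppi)
  manual <- select_putative(tab, known, 0.30, "betweenness")

  expect_setequal(igraph::V(res$cppi)$name,
                  intersect(igraph::V(res$ppi)$name,
                            igraph::V(res$eppi)$name))
  expect_identical(res$putative$symbols, manual$symbols)
  expect_equal(res$centralities, tab)

  # curve invariants: nondecreasing, terminal value = |known in CPPI|
  for (m in unique(res$curves$measure)) {
    cur <- res$curves[res$curves$measure == m, ]
    expect_true(all(diff(cur$hits) >= 0))
    expect_equal(cur$hits[nrow(cur)],
                 length(intersect(known, tab$node)))
    expect_true(all(cur$hits <= pmin(cur$rank,
                                     length(intersect(known, tab$node)))))
  }
  expect_lte(length(res$putative$symbols),
             ceiling(0.30 * igraph::vcount(res$cppi)))
  expect_length(intersect(res$putative$symbols, known), 0)
})

test_that("screen serialization is byte-identical across reruns", {
  cfg <- synth_config(rng_seed = 5, n_proteins = 150, n_seed_genes = 60,
                      n_known = 8, n_planted_putative = 8)
  net <- make_interactome(cfg)
  seeds <- make_seed_genes(cfg, net)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res1 <- run_screen(seeds, net$roles$known, net$graph)
  res2 <- run_screen(seeds, net$roles$known, net$graph)
  write_screen_result(res1, d1, known = net$roles$known)
  write_screen_result(res2, d2, known = net$roles$known)
  files <- list.files(d1)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})
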