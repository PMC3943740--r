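# Rule-of-five filtering, the dual-cutoff docking rule, and bipartite
# network construction.

mini_cutoffs <- function(targets, cutoffs) {
  data.frame(target = targets, structure_id = paste0("PDB", seq_along(targets)),
             positive_drug = "drug", cutoff_kcal = cutoffs,
             n_effective = NA_real_, role = NA_character_,
             dockable = !is.na(cutoffs), stringsAsFactors = FALSE)
}

mini_catalog <- function(ids, herbs = "H1") {
  data.frame(compound_id = ids, herbs = herbs, mw = 300, logp = 2,
             hbd = 1, hba = 3, stringsAsFactors = FALSE)
}

test_that("rule-of-five boundaries are inclusive and conjunctive", {
  expect_true(lipinski_pass(500, 5, 5, 10))
  expect_false(lipinski_pass(600, 2, 2, 4))   # weight violation
  expect_false(lipinski_pass(300, 6, 1, 3))   # logP violation
  expect_false(lipinski_pass(300, 2, 6, 3))
  expect_false(lipinski_pass(300, 2, 2, 11))
})

test_that("compounds with missing properties are excluded with a warning", {
  cat <- mini_catalog(c("c1", "c2"))
  cat$logp[2] <- NA
  expect_warning(kept <- lipinski_filter(cat), "missing")
  expect_identical(kept$compound_id, "c1")
})

test_that("effective docking needs a score below both cutoff and floor, strictly", {
  expect_true(effective_docking(-9.0, -8.4))    # below CA2-style cutoff
  expect_false(effective_docking(-5.0, -5))     # boundary: both legs strict
  expect_false(effective_docking(-6.0, -7.0))   # fails the cutoff leg
  expect_true(effective_docking(-5.2, -4.8))    # below both legs
  expect_false(effective_docking(-4.9, -4.8))   # passes cutoff, fails floor
  expect_error(effective_docking(-9, NA_real_), "non-dockable")
})

test_that("bipartite construction applies the rule per score entry", {
  catalog <- mini_catalog(c("c1", "c2", "c3"))
  scores <- data.frame(compound_id = c("c1", "c2", "c3"),
                       target = c("t1", "t1", "t2"),
                       score = c(-9, -4, -6))
  cutoffs <- mini_cutoffs(c("t1", "t2"), c(-8, -5.5))
  net <- build_bipartite(catalog, scores, cutoffs)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$compound, net$edges$target),
                  c("c1 T1", "c3 T2"))
  expect_true(all(net$edges$provenance == "docking"))
  # zero-degree nodes are omitted
  expect_false("c2" %in% net$compounds$compound_id)
  # empty score table gives an empty network
  empty <- build_bipartite(catalog, scores[0, ], cutoffs)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$compounds), 0)
})

test_that("unknown compounds or non-dockable targets are rejected by name", {
  catalog <- mini_catalog("c1")
  cutoffs <- mini_cutoffs(c("t1", "t2"), c(-8, NA))
  expect_error(
    build_bipartite(catalog,
                    data.frame(compound_id = "ghost", target = "t1",
                               score = -9),
                    cutoffs),
    "ghost")
  expect_error(
    build_bipartite(catalog,
                    data.frame(compound_id = "c1", target = "t2",
                               score = -9),
                    cutoffs),
    "T2")
})

test_that("literature edges append with provenance and docking wins ties", {
  catalog <- mini_catalog(c("c1", "c2"))
  scores <- data.frame(compound_id = "c1", target = "t1", score = -9)
  cutoffs <- mini_cutoffs(c("t1", "t2"), c(-8, NA))  # t2 not dockable
  lit <- data.frame(compound_id = c("c1", "c2"), target = c("t1", "t2"))
  net <- build_bipartite(catalog, scores, cutoffs, literature = lit)
  expect_equal(nrow(net$edges), 2)
  e1 <- net$edges[net$edges$compound == "c1", ]
  expect_identical(e1$provenance, "docking")
  e2 <- net$edges[net$edges$compound == "c2", ]
  expect_identical(e2$provenance, "literature")  # non-dockable target allowed
})

test_that("the edge set equals an independent filter over the raw table", {
  cfg <- synth_config(rng_seed = 11)
  fix <- make_docking_fixture(cfg, sprintf("T%02d", 1:20))
  net <- build_bipartite(fix$catalog, fix$scores, fix$cutoffs)
  lim <- pmin(fix$cutoffs$cutoff_kcal[match(fix$scores$target,
                                            fix$cutoffs$target)], -5)
  manual <- fix$scores[fix$scores$score < lim, c("compound_id", "target")]
  expect_setequal(paste(net$edges$compound, net$edges$target),
                  paste(manual$compound_id, manual$target))
  # two-mode invariant: compound degrees and target degrees both sum to |E|
  expect_equal(sum(table(net$edges$compound)), nrow(net$edges))
  expect_equal(sum(table(net$edges$target)), nrow(net$edges))
})

test_that("score-table row order does not change the network", {
  cfg <- synth_config(rng_seed = 4, compounds_per_herb = 10)
  fix <- make_docking_fixture(cfg, sprintf("T%02d", 1:8))
  net1 <- build_bipartite(fix$catalog, fix$scores, fix$cutoffs)
  set.seed(99)
  shuf <- fix$scores[sample(nrow(fix$scores)), ]
  net2 <- build_bipartite(fix$catalog, shuf, fix$cutoffs)
  expect_identical(net1$edges, net2$edges)
  expect_identical(net1$compounds, net2$compounds)
})

test_that("subnetwork restriction is idempotent and monotone", {
  cfg <- synth_config(rng_seed = 8, compounds_per_herb = 10)
  fix <- make_docking_fixture(cfg, sprintf("T%02d", 1:10))
  net <- build_bipartite(fix$catalog, fix$scores, fix$cutoffs)
  ids <- net$compounds$compound_id
  one <- subnetwork(net, ids[1])
  expect_equal(nrow(one$compounds), 1)
  expect_equal(nrow(one$edges), nrow(one$targets))
  expect_identical(subnetwork(net, ids)$edges, net$edges)      # identity
  half <- subnetwork(net, ids[1:5])
  expect_identical(subnetwork(half, ids[1:5])$edges, half$edges)  # idempotent
  quarter <- subnetwork(net, ids[1:2])
  expect_true(all(paste(quarter$edges$compound, quarter$edges$target) %in%
                  paste(half$edges$compound, half$edges$target)))
  expect_equal(nrow(subnetwork(net, character())$edges), 0)
})
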