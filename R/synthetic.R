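# Seeded generators for synthetic pipeline fixtures: a scale-free
# interactome with planted known/putative targets, a seed-gene list that
# guarantees the planted targets survive the PPI/EPPI intersection, and a
# docking fixture (catalog, scores, cutoffs) with known active pairs.

#' Synthetic-data generator configuration
#'
#' Defaults describe the study conditions the package's property tests
#' run under: a 400-protein preferential-attachment interactome with two
#' edges per new node, 12 known targets on the strongest hubs, 15 planted
#' putative targets among their neighbors, 120 seed genes, and a
#' five-herb catalog of 30 compounds per herb with a small two-herb
#' overlap mirroring the ~4% multi-herb fraction seen in herbal formula
#' catalogs.
#'
#' @param rng_seed integer seed; every generator derives its stream from
#'   this.
#' @param n_proteins number of interactome proteins.
#' @param attachment_m preferential-attachment edges per new node.
#' @param n_known number of known targets (assigned to top-degree hubs).
#' @param n_planted_putative number of planted putative targets
#'   (high-betweenness neighbors of the known targets).
#' @param n_seed_genes number of disease seed genes (always includes the
#'   planted targets).
#' @param n_herbs,compounds_per_herb catalog shape.
#' @param overlap_fraction fraction of compounds assigned to a second
#'   herb, in `[0, 1)`.
#' @param inactive_score_mean,inactive_score_sd Normal parameters
#'   (kcal/mol) for inactive docking scores; draws are clamped above
#'   -4.5 kcal/mol so no inactive pair can pass the -5 floor.
#' @param active_shift negative shift (kcal/mol) applied below
#'   `min(cutoff, -5)` for designated active pairs.
#' @param cutoff_range length-2 numeric, uniform range for per-target
#'   positive-drug cutoffs (kcal/mol).
#' @param lipinski_violation_rate fraction of compounds given one
#'   rule-of-five violation, in `[0, 1)`.
#' @param active_rate probability that a rule-of-five-passing compound is
#'   an active for any given target.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(rng_seed = 1L,
                         n_proteins = 400L,
                         attachment_m = 2L,
                         n_known = 12L,
                         n_planted_putative = 15L,
                         n_seed_genes = 120L,
                         n_herbs = 5L,
                         compounds_per_herb = 30L,
                         overlap_fraction = 0.04,
                         inactive_score_mean = -3.0,
                         inactive_score_sd = 0.6,
                         active_shift = -1.0,
                         cutoff_range = c(-10, -6),
                         lipinski_violation_rate = 0.1,
                         active_rate = 0.1) {
  cfg <- list(rng_seed = as.integer(rng_seed),
              n_proteins = as.integer(n_proteins),
              attachment_m = as.integer(attachment_m),
              n_known = as.integer(n_known),
              n_planted_putative = as.integer(n_planted_putative),
              n_seed_genes = as.integer(n_seed_genes),
              n_herbs = as.integer(n_herbs),
              compounds_per_herb = as.integer(compounds_per_herb),
              overlap_fraction = overlap_fraction,
              inactive_score_mean = inactive_score_mean,
              inactive_score_sd = inactive_score_sd,
              active_shift = active_shift,
              cutoff_range = sort(as.numeric(cutoff_range)),
              lipinski_violation_rate = lipinski_violation_rate,
              active_rate = active_rate)
  if (cfg$attachment_m < 1L) stop("attachment_m must be >= 1")
  if (cfg$n_known < 1L) stop("n_known must be >= 1")
  if (cfg$n_known + cfg$n_planted_putative > cfg$n_proteins) {
    stop("n_known + n_planted_putative exceeds n_proteins")
  }
  if (cfg$inactive_score_sd <= 0) stop("inactive_score_sd must be > 0")
  if (cfg$active_shift >= 0) stop("active_shift must be negative")
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)")
  }
  if (cfg$lipinski_violation_rate < 0 || cfg$lipinski_violation_rate >= 1) {
    stop("lipinski_violation_rate must lie in [0, 1)")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a scale-free interactome with planted target roles
#'
#' Grows an undirected preferential-attachment graph, assigns the known
#' targets to the highest-degree hubs (drug targets are observed to
#' concentrate on interactome hubs and to interact with one another), and
#' plants putative targets on the known targets' neighbors that occupy
#' the most connective positions *within the known-target neighborhood
#' subgraph* — the bridging positions between the known targets'
#' satellite proteins that the screen is designed to recover.
#'
#' @param cfg a [synth_config].
#' @return list with `graph` (interactome), and `roles` (list with
#'   character vectors `known` and `planted`).
#' @export
make_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$rng_seed)
  g <- igraph::sample_pa(cfg$n_proteins, power = 1, m = cfg$attachment_m,
                         directed = FALSE)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(cfg$n_proteins))
  deg <- igraph::degree(g)
  ord <- order(-deg, igraph::V(g)$name)
  known <- igraph::V(g)$name[ord][seq_len(cfg$n_known)]
  hood <- igraph::ego(g, order = 1, nodes = known)
  module <- unique(unlist(lapply(hood, function(v) v$name)))
  cand <- setdiff(module, known)
  if (length(cand) < cfg$n_planted_putative) {
    stop("known-target neighborhood too small (", length(cand),
         ") to plant ", cfg$n_planted_putative, " putative targets")
  }
  # bridging position is judged inside the known-target neighborhood:
  # that subgraph is all the PPI/EPPI intersection can ever retain, and
  # neighborhood connectivity survives seed subsampling where raw
  # betweenness rank does not
  sub <- igraph::induced_subgraph(g, module)
  mdeg <- igraph::degree(sub)[cand]
  planted <- cand[order(-mdeg, cand)][seq_len(cfg$n_planted_putative)]
  list(graph = g,
       roles = list(known = known, planted = planted, module = module))
}

#' Sample seed genes around the planted targets
#'
#' The seed list always contains every planted putative target (so the
#' plants survive the PPI side of the PPI/EPPI intersection). Background
#' seeds emulate a differentially-expressed disease gene set overlapping
#' the known-target neighborhood: three quarters are drawn from that
#' neighborhood and the rest uniformly from the remaining proteins. The
#' known targets themselves are not eligible — they stand for approved
#' drug targets supplied to the screen as a separate labelled input, not
#' for expression-derived seed genes.
#'
#' @param cfg a [synth_config].
#' @param net result of [make_interactome()].
#' @return a [protein_set] labelled `"seed"`.
#' @export
make_seed_genes <- function(cfg, net) {
  stopifnot(inherits(cfg, "synth_config"))
  planted <- net$roles$planted
  if (cfg$n_seed_genes < length(planted)) {
    stop("n_seed_genes (", cfg$n_seed_genes, ") smaller than the number ",
         "of planted targets (", length(planted), ")")
  }
  set.seed(cfg$rng_seed + 1L)
  n_bg <- cfg$n_seed_genes - length(planted)
  pool_module <- setdiff(net$roles$module, c(planted, net$roles$known))
  pool_rest <- setdiff(igraph::V(net$graph)$name,
                       c(net$roles$module, planted, net$roles$known))
  n_mod <- min(round(0.75 * n_bg), length(pool_module))
  background <- c(sample(pool_module, n_mod),
                  sample(pool_rest, min(n_bg - n_mod, length(pool_rest))))
  protein_set(c(planted, background), label = "seed")
}

#' Generate a docking fixture with known active pairs
#'
#' Builds a herb-structured compound catalog (an `overlap_fraction` of
#' compounds belongs to two herbs; a `lipinski_violation_rate` fraction
#' violates exactly one rule-of-five condition via an inflated molecular
#' weight), per-target positive-drug cutoffs drawn uniformly from
#' `cutoff_range`, and a score table covering every rule-of-five-passing
#' compound against every target. Inactive scores are
#' Normal(`inactive_score_mean`, `inactive_score_sd`) clamped above
#' -4.5 kcal/mol; each designated active pair scores strictly below
#' `min(cutoff, -5)` by at least `|active_shift|`, so the effective-docking
#' rule recovers the truth set exactly.
#'
#' @param cfg a [synth_config].
#' @param targets target symbols ([protein_set] or character).
#' @return list with `catalog`, `scores`, `cutoffs` (a `cutoff_table`)
#'   and `truth` (`data.frame` of active `compound_id`/`target` pairs).
#' @export
make_docking_fixture <- function(cfg, targets) {
  stopifnot(inherits(cfg, "synth_config"))
  tg <- .sym(targets)
  if (length(tg) == 0L) stop("target set is empty")
  set.seed(cfg$rng_seed + 2L)
  n_comp <- cfg$n_herbs * cfg$compounds_per_herb
  ids <- sprintf("CMP%03d", seq_len(n_comp))
  herb_ids <- sprintf("HERB%d", seq_len(cfg$n_herbs))
  primary <- rep(herb_ids, each = cfg$compounds_per_herb)
  herbs <- primary
  n_overlap <- round(cfg$overlap_fraction * n_comp)
  if (n_overlap > 0) {
    multi <- sample(seq_len(n_comp), n_overlap)
    for (i in multi) {
      second <- sample(setdiff(herb_ids, primary[i]), 1)
      herbs[i] <- paste(sort(c(primary[i], second)), collapse = ";")
    }
  }
  catalog <- data.frame(
    compound_id = ids,
    herbs = herbs,
    mw = round(runif(n_comp, 200, 480), 1),
    logp = round(runif(n_comp, 0, 4.5), 2),
    hbd = sample(0:4, n_comp, replace = TRUE),
    hba = sample(0:8, n_comp, replace = TRUE),
    stringsAsFactors = FALSE
  )
  n_viol <- round(cfg$lipinski_violation_rate * n_comp)
  if (n_viol > 0) {
    viol <- sample(seq_len(n_comp), n_viol)
    catalog$mw[viol] <- round(runif(n_viol, 520, 750), 1)  # one-rule violation
  }
  cutoffs <- data.frame(
    target = tg,
    structure_id = sprintf("SYN%03d", seq_along(tg)),
    positive_drug = "synthetic_positive",
    cutoff_kcal = round(runif(length(tg), cfg$cutoff_range[1],
                              cfg$cutoff_range[2]), 1),
    n_effective = NA_real_,
    role = NA_character_,
    dockable = TRUE,
    stringsAsFactors = FALSE
  )
  class(cutoffs) <- c("cutoff_table", "data.frame")
  passing <- lipinski_filter(catalog)$compound_id
  grid <- expand.grid(compound_id = passing, target = tg,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$compound_id, grid$target), , drop = FALSE]
  n_pairs <- nrow(grid)
  active <- runif(n_pairs) < cfg$active_rate
  score <- pmax(rnorm(n_pairs, cfg$inactive_score_mean,
                      cfg$inactive_score_sd), -4.5)
  lim <- pmin(cutoffs$cutoff_kcal[match(grid$target, cutoffs$target)], -5)
  score[active] <- lim[active] + cfg$active_shift + runif(sum(active), -0.3, 0)
  scores <- data.frame(compound_id = grid$compound_id, target = grid$target,
                       score = round(score, 2), stringsAsFactors = FALSE)
  truth <- grid[active, , drop = FALSE]
  rownames(truth) <- NULL
  rownames(scores) <- NULL
  list(catalog = catalog, scores = scores, cutoffs = cutoffs, truth = truth)
}

#' Build a synthetic graph with a prescribed component profile
#'
#' Constructs an interactome whose connected-component structure is given
#' exactly: one cluster per entry of `cluster_nodes`/`cluster_edges`
#' (each cluster is a ring of its nodes plus random chords up to the
#' requested edge count, so connectivity and the edge total are
#' guaranteed) plus `n_isolated` isolated nodes. Useful for reproducing a
#' network summary when only the published component arithmetic — not the
#' underlying edge list — is available.
#'
#' @param cluster_nodes integer vector of cluster sizes (each >= 2).
#' @param cluster_edges integer vector of per-cluster edge counts; entry
#'   `i` must lie in `[cluster_nodes[i] - 1, choose(cluster_nodes[i], 2)]`.
#'   For a size-2 cluster the count is 1.
#' @param n_isolated number of isolated nodes to add.
#' @param rng_seed seed for the chord placement.
#' @return an interactome (`igraph`).
#' @export
make_component_fixture <- function(cluster_nodes, cluster_edges,
                                   n_isolated = 0L, rng_seed = 1L) {
  stopifnot(length(cluster_nodes) == length(cluster_edges))
  set.seed(as.integer(rng_seed))
  edges <- NULL
  for (i in seq_along(cluster_nodes)) {
    n <- as.integer(cluster_nodes[i])
    e <- as.integer(cluster_edges[i])
    if (n < 2L) stop("cluster sizes must be >= 2")
    ring_e <- if (n == 2L) 1L else n
    if (e < n - 1L || e > choose(n, 2)) {
      stop("cluster ", i, ": ", e, " edges infeasible for ", n, " nodes")
    }
    if (e < ring_e) {
      # a tree: path through the cluster
      em <- cbind(seq_len(n - 1L), 2:n)
    } else {
      em <- if (n == 2L) cbind(1L, 2L) else cbind(seq_len(n), c(2:n, 1L))
      need <- e - ring_e
      if (need > 0L) {
        all_pairs <- t(utils::combn(n, 2))
        ring_key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
        pool <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in%
                              ring_key), , drop = FALSE]
        pick <- pool[sample(nrow(pool), need), , drop = FALSE]
        em <- rbind(em, pick)
      }
    }
    nm <- sprintf("C%02dN%04d", i, seq_len(n))
    edges <- rbind(edges, cbind(nm[em[, 1]], nm[em[, 2]]))
  }
  iso <- if (n_isolated > 0L) sprintf("ISO%04d", seq_len(n_isolated)) else character()
  interactome(edges, nodes = iso)
}

#' Planted-target recovery of the screen on one synthetic instance
#'
#' Generates an interactome and seed genes from `cfg`, runs the full
#' screen with the planted known targets, and reports the fraction of
#' planted putative targets recovered in the top-fraction selection.
#'
#' @param cfg a [synth_config].
#' @param top_fraction,measure forwarded to [run_screen()].
#' @return list with `recall` (fraction of planted targets recovered),
#'   `n_cppi` (core-network size) and the underlying `screen_result`.
#' @export
recover_planted <- function(cfg, top_fraction = 0.30,
                            measure = "betweenness") {
  net <- make_interactome(cfg)
  seeds <- make_seed_genes(cfg, net)
  res <- run_screen(seeds, net$roles$known, net$graph,
                    top_fraction = top_fraction, measure = measure)
  planted <- net$roles$planted
  list(
    recall = length(intersect(planted, res$putative$symbols)) / length(planted),
    n_cppi = igraph::vcount(res$cppi),
    screen = res
  )
}

#' Write a complete synthetic fixture to a directory
#'
#' Emits every input file the other modules read: `interactome.tsv`,
#' `seed_genes.txt`, `known_targets.txt`, `planted_targets.txt`,
#' `catalog.csv`, `scores.csv`, `cutoffs.csv` and `truth.csv`.
#'
#' @param cfg a [synth_config].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- make_interactome(cfg)
  seeds <- make_seed_genes(cfg, net)
  fix <- make_docking_fixture(cfg, c(net$roles$known, net$roles$planted))
  write_interactome(net$graph, file.path(dir, "interactome.tsv"), "tsv")
  write_symbol_list(seeds, file.path(dir, "seed_genes.txt"))
  write_symbol_list(net$roles$known, file.path(dir, "known_targets.txt"))
  write_symbol_list(net$roles$planted, file.path(dir, "planted_targets.txt"))
  utils::write.csv(fix$catalog, file.path(dir, "catalog.csv"),
                   row.names = FALSE)
  utils::write.csv(fix$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  cut_out <- data.frame(target = fix$cutoffs$target,
                        pdb_id = fix$cutoffs$structure_id,
                        positive_drug = fix$cutoffs$positive_drug,
                        cutoff = fix$cutoffs$cutoff_kcal,
                        n_effective = fix$cutoffs$n_effective,
                        role = fix$cutoffs$role,
                        stringsAsFactors = FALSE)
  utils::write.csv(cut_out, file.path(dir, "cutoffs.csv"), row.names = FALSE)
  utils::write.csv(fix$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
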