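# Lipinski filtering, the dual-cutoff effective-docking rule, and
# bipartite compound-target network construction.

#' Lipinski rule-of-five test
#'
#' A compound passes when all four conditions hold: molecular weight
#' <= 500 Da, logP <= 5, H-bond donors <= 5, H-bond acceptors <= 10
#' (boundaries inclusive; no one-violation relaxation). Missing
#' properties yield `NA`; [lipinski_filter()] treats those as failures.
#'
#' @param mw molecular weight (Da).
#' @param logp octanol-water partition coefficient.
#' @param hbd number of hydrogen-bond donors.
#' @param hba number of hydrogen-bond acceptors.
#' @param limits named numeric vector overriding the four thresholds
#'   (`mw`, `logp`, `hbd`, `hba`).
#' @return logical vector (`NA` where a property is missing).
#' @export
lipinski_pass <- function(mw, logp, hbd, hba,
                          limits = c(mw = 500, logp = 5, hbd = 5, hba = 10)) {
  mw <= limits[["mw"]] & logp <= limits[["logp"]] &
    hbd <= limits[["hbd"]] & hba <= limits[["hba"]]
}

#' Filter a compound catalog by the rule of five
#'
#' Compounds with any missing property are excluded with a warning
#' (fail-closed), matching how a docking campaign would treat compounds
#' of unknown drug-likeness.
#'
#' @param catalog `data.frame` with columns `compound_id`, `herbs`
#'   (semicolon-separated herb ids), `mw`, `logp`, `hbd`, `hba`.
#' @inheritParams lipinski_pass
#' @return the passing subset of `catalog`.
#' @export
lipinski_filter <- function(catalog,
                            limits = c(mw = 500, logp = 5, hbd = 5, hba = 10)) {
  need <- c("compound_id", "mw", "logp", "hbd", "hba")
  miss <- setdiff(need, names(catalog))
  if (length(miss)) stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  ok <- lipinski_pass(catalog$mw, catalog$logp, catalog$hbd, catalog$hba,
                      limits = limits)
  if (anyNA(ok)) {
    warning(sum(is.na(ok)), " compound(s) with missing properties excluded: ",
            paste(utils::head(catalog$compound_id[is.na(ok)], 5), collapse = ", "))
    ok[is.na(ok)] <- FALSE
  }
  catalog[ok, , drop = FALSE]
}

#' Effective-docking rule (dual cutoff)
#'
#' A docking score calls an interaction when it is strictly below both
#' the target's positive-drug cutoff and the global floor of -5.0
#' kcal/mol (more negative = stronger binding). Both inequalities are
#' strict, so a score exactly at -5.0 against a -5 cutoff is not
#' effective.
#'
#' @param score docking score(s), kcal/mol.
#' @param cutoff_kcal per-target positive-drug cutoff(s), kcal/mol; `NA`
#'   (a non-dockable target) is an error — callers must pre-filter.
#' @param floor_kcal global score floor, default -5.0 kcal/mol.
#' @return logical vector.
#' @export
effective_docking <- function(score, cutoff_kcal, floor_kcal = -5.0) {
  if (anyNA(cutoff_kcal)) {
    stop("effective_docking called with a non-dockable target ",
         "(missing cutoff); pre-filter to dockable targets")
  }
  score < cutoff_kcal & score < floor_kcal
}

#' Build a bipartite compound-target network
#'
#' One docking edge per score entry that satisfies [effective_docking()];
#' optional literature-curated pairs are appended with provenance
#' `"literature"` (when a pair is supported both ways, the docking edge
#' wins). Compounds and targets with no edges are omitted from the
#' network (they remain countable from the catalog/cutoff inputs).
#'
#' @param catalog compound catalog (`compound_id`, `herbs`, `mw`, `logp`,
#'   `hbd`, `hba`).
#' @param scores `data.frame` with columns `compound_id`, `target`,
#'   `score` (kcal/mol), at most one row per pair.
#' @param cutoffs a `cutoff_table` from [read_cutoff_table()] or a
#'   `data.frame` with `target`, `cutoff_kcal`, `dockable` (and
#'   optionally `role`).
#' @param literature optional `data.frame` with columns `compound_id`,
#'   `target` of literature-confirmed interactions; these may reference
#'   non-dockable targets.
#' @param floor_kcal global score floor, default -5.0 kcal/mol.
#' @return an object of class `bipartite_net`: list with `edges`
#'   (`compound`, `target`, `provenance`, `score`), `compounds`
#'   (`compound_id`, `herbs`) and `targets` (`target`, `role`).
#' @export
build_bipartite <- function(catalog, scores, cutoffs, literature = NULL,
                            floor_kcal = -5.0) {
  stopifnot(all(c("compound_id", "target", "score") %in% names(scores)))
  scores$target <- norm_symbols(scores$target)
  cutoffs$target <- norm_symbols(cutoffs$target)
  key <- paste(scores$compound_id, scores$target)
  if (anyDuplicated(key)) {
    stop("duplicate (compound, target) score entries: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  bad_c <- setdiff(scores$compound_id, catalog$compound_id)
  if (length(bad_c)) {
    stop("score table references uncataloged compound(s): ",
         paste(utils::head(bad_c, 10), collapse = ", "))
  }
  dockable <- cutoffs$target[cutoffs$dockable]
  bad_t <- setdiff(scores$target, dockable)
  if (length(bad_t)) {
    stop("score table references unknown or non-dockable target(s): ",
         paste(utils::head(bad_t, 10), collapse = ", "))
  }
  cut <- cutoffs$cutoff_kcal[match(scores$target, cutoffs$target)]
  eff <- effective_docking(scores$score, cut, floor_kcal)
  edges <- data.frame(compound = scores$compound_id[eff],
                      target = scores$target[eff],
                      provenance = if (any(eff)) "docking" else character(),
                      score = scores$score[eff],
                      stringsAsFactors = FALSE)
  if (!is.null(literature) && nrow(literature)) {
    stopifnot(all(c("compound_id", "target") %in% names(literature)))
    lit <- data.frame(compound = literature$compound_id,
                      target = norm_symbols(literature$target),
                      provenance = "literature", score = NA_real_,
                      stringsAsFactors = FALSE)
    bad_lc <- setdiff(lit$compound, catalog$compound_id)
    if (length(bad_lc)) {
      stop("literature edges reference uncataloged compound(s): ",
           paste(utils::head(bad_lc, 10), collapse = ", "))
    }
    bad_lt <- setdiff(lit$target, cutoffs$target)
    if (length(bad_lt)) {
      stop("literature edges reference unknown target(s): ",
           paste(utils::head(bad_lt, 10), collapse = ", "))
    }
    have <- paste(edges$compound, edges$target)
    lit <- lit[!duplicated(paste(lit$compound, lit$target)), , drop = FALSE]
    lit <- lit[!(paste(lit$compound, lit$target) %in% have), , drop = FALSE]
    edges <- rbind(edges, lit)
  }
  edges <- edges[order(edges$compound, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  .bipartite_from_edges(edges, catalog, cutoffs)
}

.bipartite_from_edges <- function(edges, catalog, cutoffs = NULL) {
  comp_ids <- sort(unique(edges$compound))
  compounds <- data.frame(
    compound_id = comp_ids,
    herbs = if ("herbs" %in% names(catalog)) {
      as.character(catalog$herbs[match(comp_ids, catalog$compound_id)])
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  tgt_ids <- sort(unique(edges$target))
  role <- rep(NA_character_, length(tgt_ids))
  if (!is.null(cutoffs) && "role" %in% names(cutoffs)) {
    role <- as.character(cutoffs$role[match(tgt_ids, cutoffs$target)])
  }
  targets <- data.frame(target = tgt_ids, role = role,
                        stringsAsFactors = FALSE)
  structure(list(edges = edges, compounds = compounds, targets = targets),
            class = "bipartite_net")
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat("<bipartite_net: ", nrow(x$compounds), " compounds, ",
      nrow(x$targets), " targets, ", nrow(x$edges), " edges>\n", sep = "")
  invisible(x)
}

#' Restrict a bipartite network to a compound subset
#'
#' Keeps the given compounds, their incident edges, and the targets those
#' edges touch. Used to derive main-component and representative-compound
#' views of a full network.
#'
#' @param net a `bipartite_net`.
#' @param compound_ids character vector of compound ids to retain.
#' @return a `bipartite_net`.
#' @export
subnetwork <- function(net, compound_ids) {
  stopifnot(inherits(net, "bipartite_net"))
  keep <- net$edges$compound %in% compound_ids
  edges <- net$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  catalog <- data.frame(compound_id = net$compounds$compound_id,
                        herbs = net$compounds$herbs,
                        stringsAsFactors = FALSE)
  out <- .bipartite_from_edges(edges, catalog)
  out$targets$role <- net$targets$role[match(out$targets$target,
                                             net$targets$target)]
  out
}

#' Convert a bipartite network to an igraph two-mode graph
#'
#' @param net a `bipartite_net`.
#' @return an undirected `igraph` with logical vertex attribute `type`
#'   (`TRUE` for targets), vertex attributes `herbs`/`role`, and edge
#'   attribute `provenance`.
#' @export
bipartite_igraph <- function(net) {
  stopifnot(inherits(net, "bipartite_net"))
  g <- igraph::make_empty_graph(0, directed = FALSE) +
    igraph::vertices(c(net$compounds$compound_id, net$targets$target))
  g <- igraph::set_vertex_attr(g, "type",
    value = c(rep(FALSE, nrow(net$compounds)), rep(TRUE, nrow(net$targets))))
  g <- igraph::set_vertex_attr(g, "herbs",
    value = c(net$compounds$herbs, rep(NA_character_, nrow(net$targets))))
  g <- igraph::set_vertex_attr(g, "role",
    value = c(rep(NA_character_, nrow(net$compounds)), net$targets$role))
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$compound, net$edges$target))
    g <- igraph::set_edge_attr(g, "provenance", value = net$edges$provenance)
  }
  g
}

#' Write a bipartite network to a directory
#'
#' Emits `edges.csv`, `compounds.csv`, `targets.csv`, plus SIF and
#' GraphML renderings (GraphML carries provenance/herb/role attributes).
#'
#' @param net a `bipartite_net`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bipartite <- function(net, dir) {
  stopifnot(inherits(net, "bipartite_net"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(net$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(net$compounds, file.path(dir, "compounds.csv"),
                   row.names = FALSE)
  utils::write.csv(net$targets, file.path(dir, "targets.csv"),
                   row.names = FALSE)
  writeLines(paste(net$edges$compound, net$edges$provenance, net$edges$target),
             file.path(dir, "network.sif"))
  igraph::write_graph(bipartite_igraph(net),
                      file.path(dir, "network.graphml"), format = "graphml")
  invisible(dir)
}

#' Read a compound catalog CSV
#' @param path CSV with columns `compound_id`, `herbs`
#'   (semicolon-separated), `mw`, `logp`, `hbd`, `hba`.
#' @return `data.frame`.
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "herbs", "mw", "logp", "hbd", "hba")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read a docking score table CSV
#' @param path CSV with columns `compound_id`, `target`, `score`.
#' @return `data.frame` with normalized target symbols.
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "target", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("score table lacks column(s): ", paste(miss, collapse = ", "))
  df$target <- norm_symbols(df$target)
  if (any(!is.finite(df$score))) stop("non-finite docking score(s) in ", path)
  df
}
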