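# Reading and writing interactomes, symbol lists and cutoff tables.
#
# An interactome is represented as an undirected simple igraph object whose
# vertex names are uppercase protein symbols. All constructors enforce:
# no self-loops, no duplicate edges, every edge endpoint a named vertex.

#' Build an interactome from an edge table
#'
#' @param edges two-column character matrix/data.frame of endpoint symbols,
#'   or `NULL` for an edgeless graph.
#' @param nodes additional node symbols to include as isolated vertices.
#' @return an undirected simple `igraph` graph with uppercase vertex names.
#' @export
interactome <- function(edges = NULL, nodes = character()) {
  nodes <- norm_symbols(nodes)
  nodes <- nodes[nzchar(nodes)]
  if (is.null(edges) || NROW(edges) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE) +
             igraph::vertices(unique(nodes)))
  }
  em <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(em) <- "character"
  em[] <- norm_symbols(em)
  nodes <- c(as.vector(t(em)), nodes)  # self-loop endpoints stay as nodes
  self <- em[, 1] == em[, 2]
  if (any(self)) {
    message(sum(self), " self-loop(s) dropped")
    em <- em[!self, , drop = FALSE]
  }
  key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) collapsed")
    em <- em[!dup, , drop = FALSE]
  }
  all_nodes <- unique(nodes)
  g <- igraph::make_empty_graph(0, directed = FALSE) +
    igraph::vertices(all_nodes)
  g <- igraph::add_edges(g, t(em))
  igraph::simplify(g)
}

# sanity check used by consumers of user-supplied graphs
.check_interactome <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) stop("interactome must be undirected")
  if (is.null(igraph::V(g)$name) && igraph::vcount(g) > 0) {
    stop("interactome vertices must be named")
  }
  if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
    stop("interactome must be a simple graph (no loops or multi-edges)")
  }
  invisible(g)
}

#' Read an undirected edge list (TSV or SIF)
#'
#' TSV lines are `A<TAB>B` (extra columns ignored). SIF lines are
#' `A <relation> B [B2 ...]`, fanning out to one edge per listed target;
#' a single-token SIF line declares an isolated node. Symbols are
#' uppercased; self-loops and duplicate edges are dropped with a logged
#' count.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"sif"`.
#' @return an interactome (`igraph`).
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(idx) == 0L) stop("empty edge-list file: ", path)
  edges <- vector("list", length(idx))
  iso <- character()
  for (j in seq_along(idx)) {
    i <- idx[j]
    fields <- if (dialect == "tsv") {
      strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    } else {
      strsplit(trimws(lines[i]), "\\s+")[[1]]
    }
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (dialect == "tsv") {
      if (length(fields) < 2L) {
        stop("malformed TSV edge on line ", i, ": ", lines[i])
      }
      edges[[j]] <- cbind(fields[1], fields[2])
    } else {
      if (length(fields) == 1L) {
        iso <- c(iso, fields[1])
      } else if (length(fields) == 2L) {
        stop("malformed SIF line ", i,
             " (expected 'source relation target ...'): ", lines[i])
      } else {
        edges[[j]] <- cbind(fields[1], fields[-(1:2)])
      }
    }
  }
  interactome(do.call(rbind, edges), nodes = iso)
}

#' Write an interactome to disk
#'
#' `tsv` writes a two-column edge list (isolated nodes are not
#' representable and are omitted); `sif` writes `A pp B` lines plus bare
#' single-symbol lines for isolated nodes; `graphml` delegates to igraph
#' and preserves vertex/edge attributes. Edge rows are written in sorted
#' order so output is byte-reproducible.
#'
#' @param g interactome.
#' @param path output file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(g, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  .check_interactome(g)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  lines <- if (format == "tsv") {
    if (nrow(el)) paste(el[, 1], el[, 2], sep = "\t") else character()
  } else {
    iso <- sort(igraph::V(g)$name[igraph::degree(g) == 0])
    c(if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(), iso)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-symbol-per-line protein list
#'
#' `#` starts a comment (whole-line or trailing); blank lines are skipped;
#' symbols are uppercased and deduplicated.
#'
#' @param path file path.
#' @param label role label for the resulting set.
#' @return a [protein_set].
#' @export
read_symbol_list <- function(path, label = "set") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("no symbols found in ", path)
  }
  protein_set(lines, label = label)
}

#' Write a protein set as a plain symbol list
#' @param x a [protein_set] or character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_symbol_list <- function(x, path) {
  writeLines(sort(.sym(x)), path)
  invisible(path)
}

#' Read a per-target docking cutoff table
#'
#' CSV with a header; recognized columns are `target`, `pdb_id`,
#' `positive_drug`, `cutoff`, `n_effective` and optionally `role`
#' (known/putative). The `cutoff` field may be blank or carry the
#' sentinels `"NO ligand"` / `"No PDB data"`; such rows (and rows whose
#' `pdb_id` is blank or `"No PDB data"`) are marked non-dockable. A
#' non-blank, non-sentinel cutoff that fails to parse as a number is an
#' error naming the row.
#'
#' @param path CSV file path.
#' @return a `data.frame` of class `cutoff_table` with columns `target`,
#'   `structure_id`, `positive_drug`, `cutoff_kcal`, `n_effective`,
#'   `role`, `dockable`.
#' @export
read_cutoff_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, quote = "\"",
                        check.names = FALSE, colClasses = "character")
  names(df) <- tolower(trimws(names(df)))
  if (!"target" %in% names(df)) stop("cutoff table needs a 'target' column")
  n <- nrow(df)
  get_col <- function(nm) {
    if (nm %in% names(df)) trimws(df[[nm]]) else rep("", n)
  }
  is_sentinel <- function(x) grepl("^no\\s+(ligand|pdb)", x, ignore.case = TRUE)

  raw_cut <- get_col("cutoff")
  cutoff_kcal <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- raw_cut[i]
    if (!nzchar(v) || is_sentinel(v)) next
    # tolerate the unicode minus sign used in typeset tables
    num <- suppressWarnings(as.numeric(gsub("−", "-", v)))
    if (is.na(num)) {
      stop("non-numeric cutoff value in row ", i, ": '", v, "'")
    }
    if (!is.finite(num)) stop("non-finite cutoff value in row ", i)
    cutoff_kcal[i] <- num
  }
  structure_id <- get_col("pdb_id")
  structure_id[!nzchar(structure_id) | is_sentinel(structure_id)] <- NA
  n_eff <- suppressWarnings(as.numeric(get_col("n_effective")))
  out <- data.frame(
    target = norm_symbols(df$target),
    structure_id = structure_id,
    positive_drug = get_col("positive_drug"),
    cutoff_kcal = cutoff_kcal,
    n_effective = n_eff,
    role = get_col("role"),
    dockable = !is.na(structure_id) & !is.na(cutoff_kcal),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cutoff_table", "data.frame")
  out
}
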