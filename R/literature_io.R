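# Input/output for the three tabular inputs: the compound graph, the
# per-metabolite mention corpus (n_i) and the metabolite-descriptor
# co-occurrence counts (y_i). Identifiers are opaque, case-sensitive
# strings; no normalization is attempted.

#' Read a compound graph
#'
#' Reads an undirected compound graph, the network over which literature is
#' propagated. Two formats are supported: a tab-separated edge list with a
#' header row (`source`, `target`; `#` lines are comments) and GraphML.
#' Self-loops and duplicate edges are dropped with a warning reporting how
#' many were removed; a metabolite cannot be its own neighbor.
#'
#' @param path Path to the graph file.
#' @param format `"edgelist"` (TSV) or `"graphml"`.
#' @return An undirected, simple [igraph::igraph] object with named
#'   vertices.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("source\ttarget", "a\tb", "b\tc"), f)
#' g <- read_compound_graph(f)
#' igraph::vcount(g)
read_compound_graph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("graph file not found: ", path)
  if (format == "edgelist") {
    df <- read.delim(path, header = TRUE, comment.char = "#",
                     colClasses = "character", sep = "\t",
                     encoding = "UTF-8", quote = "")
    if (!all(c("source", "target") %in% names(df))) {
      stop("edge list must have header columns 'source' and 'target'")
    }
    bad <- which(is.na(df$source) | is.na(df$target) |
                   df$source == "" | df$target == "")
    if (length(bad)) {
      stop("malformed edge list line(s): ", paste(bad + 1L, collapse = ", "))
    }
    g <- igraph::graph_from_data_frame(df[, c("source", "target")],
                                       directed = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name)) {
      stop("GraphML file must carry vertex names")
    }
  }
  validate_compound_graph(g)
}

#' Write a compound graph
#'
#' @param graph An igraph object with named vertices.
#' @param path Output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_compound_graph <- function(graph, path,
                                 format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(graph, names = TRUE)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     stringsAsFactors = FALSE)
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("source\ttarget", con)
    if (nrow(df)) {
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  } else {
    igraph::write_graph(graph, path, format = "graphml")
  }
  invisible(path)
}

# enforce the simple-undirected invariants; warns with removal counts
validate_compound_graph <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  if (n_loops || n_multi) {
    warning(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_multi))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  if (anyDuplicated(igraph::V(g)$name)) stop("duplicate node identifiers")
  g
}

#' Build a mention corpus
#'
#' Bundles per-metabolite total article counts `n_i` with the global
#' bookkeeping: `N` (total mentions over the network) and `M` (number of
#' metabolites). Metabolites absent from `counts` get `n_i = 0`: the
#' dominant real-world case is a network metabolite with no annotated
#' articles at all.
#'
#' @param counts Named non-negative integer vector of article counts; names
#'   must be nodes of `graph`.
#' @param graph The associated compound graph.
#' @return A `mention_corpus`: list with `n` (named vector over all graph
#'   nodes), `N` and `M`.
#' @export
mention_corpus <- function(counts, graph) {
  nodes <- igraph::V(graph)$name
  counts <- counts[!is.na(counts)]
  if (length(counts) && is.null(names(counts))) {
    stop("counts must be named by metabolite id")
  }
  unknown <- setdiff(names(counts), nodes)
  if (length(unknown)) {
    stop("unknown node id(s) in corpus: ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) {
    stop("negative article count for: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  if (anyDuplicated(names(counts))) {
    stop("duplicate metabolite id(s) in corpus: ",
         paste(unique(names(counts)[duplicated(names(counts))]),
               collapse = ", "))
  }
  n <- setNames(numeric(length(nodes)), nodes)
  n[names(counts)] <- as.numeric(counts)
  structure(list(n = n, N = sum(n), M = length(nodes)),
            class = "mention_corpus")
}

#' Read a mention corpus from TSV
#'
#' The file must be tab-separated with a header row holding columns
#' `metabolite` and `n_articles`; `#` lines are comments. Graph nodes
#' missing from the file get `n_i = 0`.
#'
#' @param path Path to the corpus TSV.
#' @param graph The associated compound graph.
#' @return A [mention_corpus()].
#' @export
read_corpus <- function(path, graph) {
  df <- read.delim(path, header = TRUE, comment.char = "#", sep = "\t",
                   colClasses = c("character", "numeric"),
                   encoding = "UTF-8", quote = "")
  if (!all(c("metabolite", "n_articles") %in% names(df))) {
    stop("corpus TSV must have columns 'metabolite' and 'n_articles'")
  }
  mention_corpus(setNames(df$n_articles, df$metabolite), graph)
}

#' @export
print.mention_corpus <- function(x, ...) {
  cat(sprintf("mention corpus: %d metabolites, N = %s total mentions (%.1f%% without literature)\n",
              x$M, format(x$N, big.mark = ","),
              100 * mean(x$n == 0)))
  invisible(x)
}

#' Write a mention corpus to TSV
#' @param corpus A [mention_corpus()].
#' @param path Output path.
#' @param keep_zero Write rows for metabolites with `n_i = 0` (default
#'   `FALSE`: absence means zero).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, keep_zero = FALSE) {
  n <- corpus$n
  if (!keep_zero) n <- n[n > 0]
  df <- data.frame(metabolite = names(n), n_articles = unname(n))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a co-occurrence table
#'
#' Per (metabolite, descriptor) co-mention counts `y_i`, with per-descriptor
#' totals `m` and background rates `P = m / N`. `P` is the probability that
#' a random mention in the network's literature also involves the
#' descriptor; a descriptor is only scoreable when `0 < P < 1`.
#'
#' @param pairs Data frame with columns `metabolite`, `descriptor`,
#'   `n_comentions`.
#' @param corpus The associated [mention_corpus()]; enforces
#'   `y_i <= n_i`.
#' @return A `cooccurrence_table`: list with `pairs` (data frame of
#'   positive counts), per-descriptor totals `m`, and `N`.
#' @export
cooccurrence_table <- function(pairs, corpus) {
  stopifnot(is.data.frame(pairs))
  need <- c("metabolite", "descriptor", "n_comentions")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns ", paste(need, collapse = ", "))
  }
  pairs$metabolite <- as.character(pairs$metabolite)
  pairs$descriptor <- as.character(pairs$descriptor)
  pairs$n_comentions <- as.numeric(pairs$n_comentions)
  if (any(pairs$n_comentions < 0)) {
    stop("negative co-mention count")
  }
  key <- paste(pairs$metabolite, pairs$descriptor, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (metabolite, descriptor) pair(s): ",
         paste(unique(sub("\r", " / ", key[duplicated(key)])),
               collapse = ", "))
  }
  unknown <- setdiff(pairs$metabolite, names(corpus$n))
  if (length(unknown)) {
    stop("unknown metabolite id(s) in co-occurrence table: ",
         paste(unknown, collapse = ", "))
  }
  over <- pairs$n_comentions > corpus$n[pairs$metabolite]
  if (any(over)) {
    stop("co-mentions exceed article count (y > n) for pair(s): ",
         paste(paste(pairs$metabolite[over], pairs$descriptor[over]),
               collapse = ", "))
  }
  pairs <- pairs[pairs$n_comentions > 0, , drop = FALSE]
  pairs <- pairs[order(pairs$descriptor, pairs$metabolite), , drop = FALSE]
  rownames(pairs) <- NULL
  m <- tapply(pairs$n_comentions, pairs$descriptor, sum)
  m <- setNames(as.numeric(m), names(m))
  structure(list(pairs = pairs, m = m, N = corpus$N),
            class = "cooccurrence_table")
}

#' Read a co-occurrence table from TSV
#'
#' Columns `metabolite`, `descriptor`, `n_comentions`; `#` lines are
#' comments. Absent pairs mean `y_i = 0`.
#'
#' @param path Path to the co-occurrence TSV.
#' @param corpus The associated [mention_corpus()].
#' @return A [cooccurrence_table()].
#' @export
read_cooccurrence <- function(path, corpus) {
  df <- read.delim(path, header = TRUE, comment.char = "#", sep = "\t",
                   colClasses = c("character", "character", "numeric"),
                   encoding = "UTF-8", quote = "")
  if (!all(c("metabolite", "descriptor", "n_comentions") %in% names(df))) {
    stop("co-occurrence TSV must have columns ",
         "'metabolite', 'descriptor', 'n_comentions'")
  }
  cooccurrence_table(df, corpus)
}

#' Write a co-occurrence table to TSV
#' @param cooc A [cooccurrence_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cooccurrence <- function(cooc, path) {
  write.table(cooc$pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat(sprintf("co-occurrence table: %d positive pairs, %d descriptors, N = %s\n",
              nrow(x$pairs), length(x$m), format(x$N, big.mark = ",")))
  invisible(x)
}

#' Background rate of a descriptor
#'
#' `P = m / N`: the probability that a random metabolite mention co-occurs
#' with the descriptor.
#'
#' @param cooc A [cooccurrence_table()].
#' @param descriptor Descriptor id.
#' @return The background rate, a probability.
#' @export
descriptor_rate <- function(cooc, descriptor) {
  m <- if (descriptor %in% names(cooc$m)) cooc$m[[descriptor]] else 0
  if (cooc$N <= 0) stop("corpus has no literature: P undefined (N = 0)")
  m / cooc$N
}

#' Co-mention count for one pair
#' @param cooc A [cooccurrence_table()].
#' @param metabolite,descriptor Identifiers.
#' @return `y_i` for the pair (0 when absent).
#' @export
comentions <- function(cooc, metabolite, descriptor) {
  hit <- cooc$pairs$metabolite == metabolite &
    cooc$pairs$descriptor == descriptor
  if (any(hit)) cooc$pairs$n_comentions[which(hit)[1]] else 0
}

# named vector of y_i over metabolites for a descriptor (positive only)
descriptor_comentions <- function(cooc, descriptor) {
  sel <- cooc$pairs$descriptor == descriptor
  setNames(cooc$pairs$n_comentions[sel], cooc$pairs$metabolite[sel])
}
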