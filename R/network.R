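#' Directed gene network
#'
#' A gene regulatory network is represented as a tibble of directed edges
#' with columns `regulator` and `target`, plus a `nodes` attribute carrying
#' the full gene set (so isolated genes are retained). Self-loops are not
#' allowed.
#'
#' @param edges Data frame with columns `regulator` and `target` (may have
#'   zero rows).
#' @param nodes Character vector of gene identifiers; defaults to the genes
#'   appearing in `edges`.
#' @return A tibble of class `gene_network`.
#' @export
gene_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) edges <- tibble::tibble(regulator = character(), target = character())
  edges <- tibble::as_tibble(edges)[, c("regulator", "target")]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  edges <- dplyr::distinct(edges)
  if (any(edges$regulator == edges$target))
    stop("self-loops are not allowed in a gene network", call. = FALSE)
  if (is.null(nodes)) nodes <- unique(c(edges$regulator, edges$target))
  nodes <- as.character(nodes)
  extra <- setdiff(unique(c(edges$regulator, edges$target)), nodes)
  if (length(extra) > 0)
    stop("edges reference undeclared node(s): ", paste(extra, collapse = ", "), call. = FALSE)
  structure(edges, nodes = nodes,
            class = c("gene_network", class(tibble::tibble())))
}

#' @rdname gene_network
#' @param x A `gene_network`.
#' @export
network_nodes <- function(x) {
  nodes <- attr(x, "nodes")
  if (is.null(nodes)) nodes <- unique(c(x$regulator, x$target))
  nodes
}

#' @keywords internal
edge_keys <- function(x) paste(x$regulator, x$target, sep = "\r")

#' @keywords internal
as_igraph_network <- function(x) {
  igraph::graph_from_data_frame(as.data.frame(x[, c("regulator", "target")]),
                                directed = TRUE,
                                vertices = data.frame(name = network_nodes(x)))
}

#' Read a directed network from SIF or two-column edge-list text
#'
#' Accepts tab-separated lines that are either SIF-style
#' (`regulator<TAB>relation<TAB>target`) or plain two-column
#' (`regulator<TAB>target`). In `strict` mode a self-loop line is an error;
#' in lenient mode (default) it is dropped with a warning.
#'
#' @param path Path to the network file.
#' @param strict If `TRUE`, self-loop lines are an error instead of a warning.
#' @return A [gene_network].
#' @export
read_network <- function(path, strict = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(gene_network())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(!n_fields %in% c(2L, 3L))
  if (length(bad) > 0)
    stop(sprintf("malformed network line %d: '%s' (expected 2 or 3 tab-separated fields)",
                 bad[1], lines[bad[1]]), call. = FALSE)
  reg <- vapply(parts, `[[`, character(1), 1L)
  tgt <- vapply(parts, function(p) p[[length(p)]], character(1))
  selfs <- reg == tgt
  if (any(selfs)) {
    if (strict)
      stop(sprintf("self-loop at line %d: '%s'", which(selfs)[1], lines[which(selfs)[1]]),
           call. = FALSE)
    warning(sum(selfs), " self-loop line(s) dropped", call. = FALSE)
  }
  gene_network(tibble::tibble(regulator = reg[!selfs], target = tgt[!selfs]),
               nodes = unique(c(reg, tgt)))
}

#' Write a directed network as SIF or two-column edge list
#'
#' @param network A [gene_network].
#' @param path Output path.
#' @param format `"sif"` (relation column, defaulting to `"regulates"`) or
#'   `"edgelist"` (two columns).
#' @param relation Relation label used in SIF output.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "edgelist"),
                          relation = "regulates") {
  format <- match.arg(format)
  lines <- if (format == "sif") {
    sprintf("%s\t%s\t%s", network$regulator, relation, network$target)
  } else {
    sprintf("%s\t%s", network$regulator, network$target)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d directed edges\n",
              length(network_nodes(x)), nrow(x)))
  NextMethod()
}
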