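#' Two-slice dynamic Bayesian network structure
#'
#' Holds the pair of graphs a stationary first-order DBN is built from: the
#' initial network (parents of each gene in the first time slice) and the
#' transition network (parents of each gene at slice t+1, each tagged
#' `"prev"` for a slice-t parent or `"same"` for a slice-(t+1) parent). One
#' transition table represents every t -> t+1 step (stationarity).
#'
#' @param genes Character vector of gene identifiers.
#' @param b0 Data frame of initial-network edges, columns `parent`, `child`.
#' @param trans Data frame of transition edges, columns `parent`, `lag`
#'   (`"prev"` or `"same"`) and `child`. A gene may be its own `"prev"`
#'   parent (persistence) but never its own `"same"` parent.
#' @param metadata Optional named list of provenance (method, options, seed).
#' @return An object of class `dbn_structure`.
#' @export
dbn_structure <- function(genes, b0 = NULL, trans = NULL, metadata = list()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers", call. = FALSE)
  if (is.null(b0) || nrow(as.data.frame(b0)) == 0L)
    b0 <- tibble::tibble(parent = character(), child = character())
  if (is.null(trans) || nrow(as.data.frame(trans)) == 0L)
    trans <- tibble::tibble(parent = character(), lag = character(), child = character())
  b0 <- tibble::as_tibble(b0)[, c("parent", "child")]
  trans <- tibble::as_tibble(trans)[, c("parent", "lag", "child")]
  ref <- unique(c(b0$parent, b0$child, trans$parent, trans$child))
  if (!all(ref %in% genes))
    stop("edges reference unknown gene(s): ",
         paste(setdiff(ref, genes), collapse = ", "), call. = FALSE)
  if (!all(trans$lag %in% c("prev", "same")))
    stop("transition lag must be 'prev' or 'same'", call. = FALSE)
  if (any(b0$parent == b0$child))
    stop("self-loop in initial network", call. = FALSE)
  same <- trans[trans$lag == "same", ]
  if (any(same$parent == same$child))
    stop("a gene cannot be its own same-slice parent", call. = FALSE)
  if (!edges_are_dag(b0$parent, b0$child, genes))
    stop("initial network is cyclic", call. = FALSE)
  if (!edges_are_dag(same$parent, same$child, genes))
    stop("same-slice transition subgraph is cyclic", call. = FALSE)
  structure(list(genes = genes, b0 = b0, trans = trans, metadata = metadata),
            class = "dbn_structure")
}

#' @keywords internal
edges_are_dag <- function(parent, child, nodes) {
  if (length(parent) == 0L) return(TRUE)
  g <- igraph::graph_from_data_frame(data.frame(from = parent, to = child),
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  igraph::is_dag(g)
}

#' @export
print.dbn_structure <- function(x, ...) {
  cat(sprintf("<dbn_structure> %d genes | B0: %d edge(s) | transition: %d edge(s)\n",
              length(x$genes), nrow(x$b0), nrow(x$trans)))
  if (!is.null(x$metadata$method))
    cat("  method:", x$metadata$method, "\n")
  invisible(x)
}

#' Tidy a DBN structure into one edge table
#'
#' @param x A [dbn_structure].
#' @param ... Unused.
#' @return Tibble with columns `component` (`"b0"` or `"transition"`),
#'   `parent`, `lag` (`NA` for b0 edges) and `child`.
#' @exportS3Method generics::tidy
tidy.dbn_structure <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$b0, component = "b0", lag = NA_character_),
    dplyr::mutate(x$trans, component = "transition")
  )[, c("component", "parent", "lag", "child")] |> tibble::as_tibble()
}

#' @exportS3Method generics::glance
glance.dbn_structure <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes),
                 n_b0_edges = nrow(x$b0),
                 n_trans_edges = nrow(x$trans),
                 n_prev = sum(x$trans$lag == "prev"),
                 n_same = sum(x$trans$lag == "same"),
                 method = x$metadata$method %||% NA_character_)
}

#' Serialize / parse a DBN structure as two-section text
#'
#' The format has a `[B0]` section of `parent<TAB>child` lines and a
#' `[TRANS]` section of `parent<TAB>tag<TAB>child` lines with tag `PREV` or
#' `SAME`.
#'
#' @param x A [dbn_structure].
#' @param path File path.
#' @return `path` invisibly (write) or a [dbn_structure] (read).
#' @export
write_structure <- function(x, path) {
  lines <- c(sprintf("#genes\t%s", paste(x$genes, collapse = "\t")),
             "[B0]",
             sprintf("%s\t%s", x$b0$parent, x$b0$child),
             "[TRANS]",
             sprintf("%s\t%s\t%s", x$trans$parent, toupper(x$trans$lag), x$trans$child))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  gene_line <- grep("^#genes\t", lines, value = TRUE)
  genes <- if (length(gene_line) == 1L) strsplit(gene_line, "\t")[[1]][-1] else character()
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  sec <- cumsum(body %in% c("[B0]", "[TRANS]"))
  b0_lines <- body[sec == 1 & body != "[B0]"]
  tr_lines <- body[sec == 2 & body != "[TRANS]"]
  parse2 <- function(l) do.call(rbind, strsplit(l, "\t", fixed = TRUE))
  b0 <- if (length(b0_lines)) {
    m <- parse2(b0_lines); tibble::tibble(parent = m[, 1], child = m[, 2])
  } else NULL
  trans <- if (length(tr_lines)) {
    m <- parse2(tr_lines)
    tibble::tibble(parent = m[, 1], lag = tolower(m[, 2]), child = m[, 3])
  } else NULL
  if (length(genes) == 0L)
    genes <- unique(c(b0$parent, b0$child, trans$parent, trans$child))
  dbn_structure(genes, b0 = b0, trans = trans)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
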