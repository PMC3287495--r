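#' Read a time-series expression table
#'
#' Reads a tab-separated expression table whose first column (`gene`) holds
#' gene identifiers and whose remaining columns are named `t<time>_r<rep>`,
#' one column per (time point, replicate) pair. Values are continuous
#' expression measurements; the table must be complete (no missing cells).
#'
#' @param path Path to a tab-separated text file.
#' @return A tibble in long form with columns `gene` (character), `time`
#'   (0-based integer), `replicate` (1-based integer) and `value` (double),
#'   ordered by gene (file order), time, replicate.
#' @export
read_expression <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L)
    stop("expression table needs a gene column plus at least one t<i>_r<j> column", call. = FALSE)
  names(raw)[1] <- "gene"
  value_cols <- names(raw)[-1]
  bad <- value_cols[!grepl("^t[0-9]+_r[0-9]+$", value_cols)]
  if (length(bad) > 0)
    stop("unparsable column header(s): ", paste(bad, collapse = ", "),
         " (expected t<time>_r<replicate>)", call. = FALSE)
  if (anyDuplicated(raw$gene))
    stop("duplicate gene identifier(s): ",
         paste(unique(raw$gene[duplicated(raw$gene)]), collapse = ", "), call. = FALSE)

  long <- raw |>
    tidyr::pivot_longer(-"gene", names_to = "cell", values_to = "value_chr") |>
    tidyr::extract("cell", into = c("time", "replicate"), regex = "^t([0-9]+)_r([0-9]+)$",
                   convert = TRUE)
  value <- suppressWarnings(as.numeric(long$value_chr))
  bad_cell <- is.na(value) | !is.finite(value)
  if (any(bad_cell)) {
    first <- which(bad_cell)[1]
    stop(sprintf("missing or non-numeric value for gene '%s' at t%d_r%d: '%s'",
                 long$gene[first], long$time[first], long$replicate[first],
                 long$value_chr[first]), call. = FALSE)
  }
  out <- long |>
    dplyr::mutate(value = value, .keep = "unused") |>
    dplyr::mutate(gene = factor(.data$gene, levels = raw$gene)) |>
    dplyr::arrange(.data$gene, .data$time, .data$replicate) |>
    dplyr::mutate(gene = as.character(.data$gene))
  validate_expression(out)
}

#' Write a time-series expression table
#'
#' Inverse of [read_expression()]: writes the long tibble back to the wide
#' tab-separated layout with `t<time>_r<rep>` headers. Round-trips values at
#' full double precision.
#'
#' @param data Long expression tibble (`gene`, `time`, `replicate`, `value`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path) {
  data <- validate_expression(data)
  wide <- data |>
    dplyr::mutate(gene = factor(.data$gene, levels = unique(data$gene)),
                  cell = sprintf("t%d_r%d", .data$time, .data$replicate)) |>
    dplyr::select("gene", "cell", "value") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "value") |>
    dplyr::mutate(gene = as.character(.data$gene))
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @keywords internal
validate_expression <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("gene", "time", "replicate", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("expression data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(data$value)))
    stop("expression data contains missing or non-finite values; complete data required",
         call. = FALSE)
  # every (gene, time, replicate) combination exactly once
  counts <- dplyr::count(data, .data$gene, .data$time, .data$replicate)
  if (any(counts$n != 1L))
    stop("duplicated (gene, time, replicate) cells in expression data", call. = FALSE)
  n_cells <- dplyr::n_distinct(data$time) * dplyr::n_distinct(data$replicate)
  per_gene <- dplyr::count(data, .data$gene)
  if (any(per_gene$n != n_cells))
    stop("expression data is ragged: every gene needs every (time, replicate) cell",
         call. = FALSE)
  tibble::as_tibble(data)
}

#' @keywords internal
expression_genes <- function(data) unique(data$gene)
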