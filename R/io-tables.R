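# Reading and writing activity tables, region metadata, correlation
# matrices and network exports. Tab-delimited text is the canonical table
# dialect; comma-separated files are accepted on read. Region rows are keyed
# by abbreviation (not position) so files survive reordering, and tables are
# re-sorted into metadata matrix_index order on read so exported matrices
# share a common axis ordering.

#' Construct an activity table
#'
#' An activity table holds the regional activity densities (immediate early
#' gene positive nuclei per 10,000 square micrometres) for every subject of
#' one experimental group, as a regions x subjects matrix.
#'
#' @param values Numeric matrix, regions in rows and subjects in columns.
#'   Row names are region abbreviations, column names subject ids (generated
#'   when absent). All cells must be present and non-negative.
#' @param group_label Single string naming the experimental group.
#' @return An object of class `activity_table`: a list with elements
#'   `group_label`, `regions`, `subjects` and `values`.
#' @export
#' @examples
#' m <- matrix(c(5, 7, 6, 8, 9, 10), nrow = 3,
#'             dimnames = list(c("CA1", "CA3", "DG"), c("s1", "s2")))
#' activity_table(m, "wt_1d")
activity_table <- function(values, group_label = "group") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (regions x subjects)")
  if (anyNA(values))
    stop("activity table has missing cells")
  if (any(values < 0))
    stop("activity table has negative values; densities must be >= 0")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("R%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate region abbreviation: ",
         rownames(values)[duplicated(rownames(values))][1L])
  structure(
    list(group_label = as.character(group_label)[1L],
         regions = rownames(values),
         subjects = colnames(values),
         values = values),
    class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("Activity table '%s': %d regions x %d subjects\n",
              x$group_label, length(x$regions), length(x$subjects)))
  invisible(x)
}

# Sniff the field separator: tab canonical, comma accepted.
.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a region metadata table
#'
#' The metadata table mirrors the structure of a brain-region listing: one
#' row per region with columns `abbreviation`, `index` (the 1-based position
#' of the region on correlation-matrix axes) and `subdivision` (major brain
#' subdivision, e.g. neocortex, hippocampus, thalamus, hypothalamus,
#' cerebral nuclei, midbrain).
#'
#' @param path Path to a tab- or comma-delimited text file with a header.
#' @return A `region_metadata` data frame with columns `abbreviation`,
#'   `matrix_index` and `subdivision`, sorted by `matrix_index`.
#' @export
read_region_metadata <- function(path) {
  df <- read.delim(path, sep = .sniff_sep(path), stringsAsFactors = FALSE,
                   strip.white = TRUE)
  names(df) <- tolower(names(df))
  need <- c("abbreviation", "index", "subdivision")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  region_metadata(df$abbreviation, df$index, df$subdivision)
}

#' Construct region metadata in code
#'
#' @param abbreviation Character vector of unique region abbreviations.
#' @param matrix_index Integer vector; must be a permutation of
#'   `1:length(abbreviation)`.
#' @param subdivision Character vector of major brain subdivisions.
#' @return A `region_metadata` data frame sorted by `matrix_index`.
#' @export
region_metadata <- function(abbreviation, matrix_index, subdivision) {
  abbreviation <- as.character(abbreviation)
  matrix_index <- as.integer(matrix_index)
  if (anyDuplicated(abbreviation))
    stop("duplicate region abbreviation in metadata: ",
         abbreviation[duplicated(abbreviation)][1L])
  if (!setequal(matrix_index, seq_along(abbreviation)))
    stop("matrix_index must be a permutation of 1..",
         length(abbreviation), " (duplicate or non-contiguous indices)")
  df <- data.frame(abbreviation = abbreviation,
                   matrix_index = matrix_index,
                   subdivision = as.character(subdivision),
                   stringsAsFactors = FALSE)
  df <- df[order(df$matrix_index), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("region_metadata", "data.frame")
  df
}

#' Read an activity table from delimited text
#'
#' Expects a header row of subject ids and a first column of region
#' abbreviations. When metadata is supplied the table is validated against
#' it (unknown or missing regions are errors) and rows are reordered into
#' `matrix_index` order.
#'
#' @param path Path to a tab- or comma-delimited file.
#' @param metadata Optional [region_metadata()] table.
#' @param group_label Group label for the resulting table; defaults to the
#'   file name without extension.
#' @return An [activity_table()].
#' @export
read_activity_table <- function(path, metadata = NULL, group_label = NULL) {
  sep <- .sniff_sep(path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character",
                   strip.white = TRUE)
  if (ncol(df) < 2L)
    stop("activity table needs a region column plus >= 1 subject column")
  regions <- df[[1L]]
  if (anyDuplicated(regions))
    stop("duplicate region row: ", regions[duplicated(regions)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals))
  bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("missing or non-numeric cell at region '%s', subject '%s'",
                 regions[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative value at region '%s', subject '%s'",
                 regions[neg[1L, 1L]], colnames(vals)[neg[1L, 2L]]))
  dimnames(num) <- list(regions, colnames(vals))
  if (!is.null(metadata)) {
    unknown <- setdiff(regions, metadata$abbreviation)
    if (length(unknown) > 0L)
      stop("region not in metadata: ", unknown[1L])
    absent <- setdiff(metadata$abbreviation, regions)
    if (length(absent) > 0L)
      stop("region in metadata but missing from table: ", absent[1L])
    num <- num[metadata$abbreviation, , drop = FALSE]
  }
  if (is.null(group_label))
    group_label <- sub("\\.[^.]*$", "", basename(path))
  activity_table(num, group_label)
}

#' Write an activity table as tab-delimited text
#'
#' @param table An [activity_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(table, path) {
  stopifnot(inherits(table, "activity_table"))
  df <- data.frame(region = table$regions, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a correlation matrix as tab-delimited text
#'
#' Axes follow the region order of the matrix (metadata matrix_index order
#' when the source table was read against metadata).
#'
#' @param corr A [pairwise_correlations()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(corr, path) {
  stopifnot(inherits(corr, "correlation_matrix"))
  df <- data.frame(region = rownames(corr$r), corr$r,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a functional network to GraphML or a whitespace edge list
#'
#' Node attributes include the major brain subdivision (when metadata is
#' given) and degree; edge weights carry the correlation coefficient. The
#' edge-list format stores isolated nodes in `#node` header lines so a
#' round trip recovers the full node set.
#'
#' @param net A [build_network()] result (or [functional_network()]).
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @param metadata Optional [region_metadata()] used to attach subdivisions.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist"),
                           metadata = NULL) {
  stopifnot(inherits(net, "functional_network"))
  format <- match.arg(format)
  g <- net$graph
  igraph::V(g)$degree <- igraph::degree(g)
  if (!is.null(metadata)) {
    idx <- match(igraph::V(g)$name, metadata$abbreviation)
    igraph::V(g)$subdivision <- metadata$subdivision[idx]
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    w <- igraph::E(g)$weight %||% rep(NA_real_, nrow(el))
    if (length(w) == 0L) w <- numeric(0)
    lines <- c(
      sprintf("#node %s", igraph::V(g)$name),
      if (nrow(el) > 0L)
        sprintf("%s %s %.6f", el[, 1L], el[, 2L], w))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return A [functional_network()] object (threshold metadata is not stored
#'   in the export formats and comes back as `NA`).
#' @export
import_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
  } else {
    lines <- readLines(path)
    nodes <- sub("^#node ", "", grep("^#node ", lines, value = TRUE))
    edges <- grep("^#", lines, value = TRUE, invert = TRUE)
    edges <- edges[nzchar(edges)]
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    if (length(edges) > 0L) {
      parts <- do.call(rbind, strsplit(edges, "[[:space:]]+"))
      g <- igraph::add_edges(g, rbind(match(parts[, 1L], nodes),
                                      match(parts[, 2L], nodes)))
      igraph::E(g)$weight <- as.numeric(parts[, 3L])
    }
  }
  functional_network(g)
}

#' Path to the packaged synthetic region metadata fixture
#'
#' An 84-region metadata table whose abbreviations and subdivision labels
#' follow the naming conventions of mouse brain atlas regions discussed in
#' the fear-memory mapping literature. It is a synthetic stand-in
#' constructed for examples and tests, not a published region list.
#'
#' @return File path of the packaged TSV.
#' @export
fosnet_example_metadata <- function() {
  system.file("extdata", "region_metadata_synthetic.tsv",
              package = "fosnet", mustWork = TRUE)
}
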