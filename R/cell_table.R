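#' Construct a cell table
#'
#' A \code{cell_table} is a data.frame with one row per segmented cell:
#' micrometer coordinates, case/region identifiers, a region class
#' (\code{edge} or \code{core}), a population label, and any number of
#' numeric marker columns. \code{(case_id, region_id)} partitions the cells
#' into regions; all spatial statistics operate region by region.
#'
#' @param df data.frame holding at least the columns \code{cell_id},
#'   \code{x}, \code{y}, \code{case_id}, \code{region_id},
#'   \code{region_class}, \code{population}.
#' @param markers character vector naming the marker columns. Default: all
#'   numeric columns other than \code{x}/\code{y}.
#' @param populations declared population set; defaults to the labels present.
#' @return the validated data.frame with class \code{cell_table} and
#'   attributes \code{markers} and \code{populations}.
#' @export
cell_table <- function(df, markers = NULL, populations = NULL) {
  req <- c("cell_id", "x", "y", "case_id", "region_id",
           "region_class", "population")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)])[1:3], collapse = ", "))
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("cell coordinates must be finite")
  if (!all(df$region_class %in% c("edge", "core")))
    stop("region_class must be 'edge' or 'core'")
  if (is.null(markers)) {
    num <- vapply(df, is.numeric, logical(1))
    markers <- setdiff(names(df)[num], c("x", "y"))
  }
  bad <- markers[!vapply(df[markers], is.numeric, logical(1))]
  if (length(bad)) stop("non-numeric marker column(s): ",
                        paste(bad, collapse = ", "))
  populations <- populations %||% sort(unique(as.character(df$population)))
  if (!all(df$population %in% populations))
    stop("population labels outside the declared set")
  df$population <- as.character(df$population)
  structure(df, class = c("cell_table", "data.frame"),
            markers = markers, populations = populations)
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("cell_table: %d cells, %d regions, %d populations, %d markers\n",
              nrow(x), nrow(unique(x[c("case_id", "region_id")])),
              length(attr(x, "populations")), length(attr(x, "markers"))))
  invisible(x)
}

#' Marker column names of a cell table
#' @param x a \code{cell_table}.
#' @return character vector of marker column names.
#' @export
marker_names <- function(x) attr(x, "markers")

#' Declared population labels of a cell table
#' @param x a \code{cell_table}.
#' @return character vector of population labels.
#' @export
population_levels <- function(x) attr(x, "populations")

# region view in canonical (cell_id) order, so downstream permutation
# streams are invariant to input row order
region_view <- function(cells, region_id) {
  sel <- cells$region_id == region_id
  if (!any(sel)) stop("region not found: ", region_id)
  v <- cells[sel, , drop = FALSE]
  v <- v[order(v$cell_id), , drop = FALSE]
  rownames(v) <- NULL
  attr(v, "markers") <- attr(cells, "markers")
  attr(v, "populations") <- attr(cells, "populations")
  class(v) <- class(cells)
  v
}

#' Region identifiers of a cell table
#' @param x a \code{cell_table}.
#' @return data.frame of \code{case_id}, \code{region_id},
#'   \code{region_class}, and cell counts.
#' @export
region_summary <- function(x) {
  agg <- aggregate(list(n_cells = x$cell_id),
                   x[c("case_id", "region_id", "region_class")], length)
  agg[order(agg$case_id, agg$region_id), , drop = FALSE]
}

default_schema <- function() {
  list(cell_id = "cell_id", x = "x", y = "y", case_id = "case_id",
       region_id = "region_id", region_class = "region_class",
       population = "population")
}

#' Read a segmented single-cell table
#'
#' Reads a CSV/TSV with one row per cell and maps its columns onto the
#' canonical \code{cell_table} schema. The mapping can be given directly or
#' loaded from the \code{schema:} block of a YAML config file. Columns not
#' named in the schema are carried along; numeric ones become markers unless
#' the schema lists \code{markers} explicitly.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension).
#' @param schema named list mapping canonical names (\code{cell_id}, \code{x},
#'   \code{y}, \code{case_id}, \code{region_id}, \code{region_class},
#'   \code{population}, optionally \code{markers}) to file column names.
#' @param config path to a YAML file with a \code{schema} block, used when
#'   \code{schema} is NULL.
#' @return a \code{cell_table}.
#' @export
read_cell_table <- function(path, schema = NULL, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(schema) && !is.null(config)) {
    schema <- yaml::read_yaml(config)$schema
    # YAML 1.1 reads a bare key `y` as boolean TRUE; map it back
    names(schema)[names(schema) == "TRUE"] <- "y"
    names(schema)[names(schema) == "FALSE"] <- "n"
  }
  schema <- utils::modifyList(default_schema(), as.list(schema %||% list()))
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  mk <- schema$markers
  schema$markers <- NULL
  for (canon in names(schema)) {
    file_col <- schema[[canon]]
    if (!file_col %in% names(df))
      stop("schema error: mapped column '", file_col, "' (for '", canon,
           "') not present in ", path)
    names(df)[names(df) == file_col] <- canon
  }
  if (!is.null(mk)) {
    for (m in mk) {
      if (!m %in% names(df))
        stop("schema error: marker column '", m, "' not present")
      v <- suppressWarnings(as.numeric(df[[m]]))
      if (anyNA(v) && !anyNA(df[[m]]))
        stop("parse error: non-numeric marker value in column '", m,
             "', row ", which(is.na(v))[1])
      df[[m]] <- v
    }
  }
  cell_table(df, markers = mk)
}

#' Write a cell table
#'
#' Emits the same CSV/TSV dialect \code{\link{read_cell_table}} consumes
#' (canonical column names, so it round-trips with the default schema).
#'
#' @param x a \code{cell_table}.
#' @param path output file; \code{.tsv} extension selects tab delimiting.
#' @return \code{path}, invisibly.
#' @export
write_cell_table <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Percentile-normalize marker intensities
#'
#' Divides each marker by its own upper percentile (default the 99th)
#' computed over all cells, then clips to \code{[0, 1]}; intensities above
#' the percentile therefore map to 1. A marker whose percentile value is 0
#' maps to all zeros.
#'
#' @param cells a \code{cell_table} with raw (non-negative) intensities.
#' @param percentile percentile in \code{(0, 100]}; default 99.
#' @return the cell table with markers rescaled into \code{[0, 1]}.
#' @export
normalize_markers <- function(cells, percentile = 99) {
  stopifnot(inherits(cells, "cell_table"))
  if (nrow(cells) == 0L) stop("empty cell table")
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]")
  for (m in marker_names(cells)) {
    v <- cells[[m]]
    if (any(v < 0, na.rm = TRUE))
      stop("negative intensity in marker '", m, "'")
    q <- unname(quantile(v, percentile / 100, na.rm = TRUE, names = FALSE))
    cells[[m]] <- if (q == 0) rep(0, length(v)) else pmin(v / q, 1)
  }
  cells
}
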