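#' Write a connectivity matrix as CSV
#'
#' The CSV has one header row of node ids and one row per node (node id in
#' the first column), so a 90-node matrix becomes 91 lines.
#'
#' @param matrix numeric matrix with node ids as dimnames (or `node_ids`).
#' @param path output CSV path.
#' @param node_ids optional node ids; defaults to existing dimnames or 1..N.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, node_ids = NULL) {
  m <- as.matrix(matrix)
  if (is.null(node_ids)) {
    node_ids <- rownames(m)
    if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(m)))
  }
  dimnames(m) <- list(node_ids, node_ids)
  utils::write.table(m, file = path, sep = ",", col.names = NA,
                     row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path CSV path.
#' @return Numeric matrix with node-id dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  as.matrix(df)
}

#' Export a matrix as JSON (node-id list plus dense grid)
#'
#' @param matrix numeric matrix.
#' @param path output JSON path.
#' @param node_ids node ids; defaults as in [write_matrix()].
#' @return `path`, invisibly.
#' @export
write_matrix_json <- function(matrix, path, node_ids = NULL) {
  m <- as.matrix(matrix)
  if (is.null(node_ids)) {
    node_ids <- rownames(m)
    if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(m)))
  }
  obj <- list(nodes = node_ids, data = unname(m))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_matrix_json
#' @export
read_matrix_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.matrix(obj$data)
  dimnames(m) <- list(obj$nodes, obj$nodes)
  m
}

#' Write / read a metrics (or any rectangular) table as CSV
#'
#' @param rows data frame.
#' @param path CSV path.
#' @return `path` (write) or data frame (read).
#' @export
write_metrics_table <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a stimulation-point table
#'
#' Columns: `subject`, `x`, `y`, `z` (world mm), `polarity` (`POS`/`NEG`).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "x", "y", "z", "polarity")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("points table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(df$polarity %in% c("POS", "NEG"))) {
    stop("polarity must be 'POS' or 'NEG'")
  }
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("point coordinates must be finite")
  }
  df
}

#' @rdname read_points_csv
#' @param points data frame with the point-table columns.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a cohort table
#'
#' Columns: `subject`, `group` (`NA_group`/`GIA`), `tumor_size` (cm^3),
#' `aphasia_level` (ordinal 0-5), and `;`-separated `pos_regions` /
#' `neg_regions` id lists.
#'
#' @param path CSV path.
#' @return Data frame with list-columns `pos_regions`, `neg_regions`.
#' @export
read_cohort_csv <- function(path) {
  # na.strings = "" so the "NA" (no-aphasia) group label survives the read
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = c(subject = "character",
                                       group = "character"))
  df$pos_regions <- parse_id_sets(df$pos_regions)
  df$neg_regions <- parse_id_sets(df$neg_regions)
  df
}

#' @rdname read_cohort_csv
#' @param cohort cohort data frame (list-columns allowed).
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  out$pos_regions <- format_id_sets(cohort$pos_regions)
  out$neg_regions <- format_id_sets(cohort$neg_regions)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_id_sets <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1L]])
  })
}

format_id_sets <- function(x) {
  vapply(x, function(ids) paste(ids, collapse = ";"), "")
}
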