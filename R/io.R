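#' Read a delimited feature table
#'
#' Reads a TSV/CSV abundance table with a header row and a leading id
#' column. The default orientation is samples-by-features; pass
#' `orientation = "features-by-samples"` to transpose on read. Every data
#' cell must be numeric: the first offending cell is reported by row and
#' column label. Duplicate sample or feature ids are an error.
#'
#' @param path file path.
#' @param orientation `"samples-by-features"` (default) or
#'   `"features-by-samples"`.
#' @param delimiter field delimiter (default tab).
#' @return a [feature_matrix()].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples-by-features",
                                               "features-by-samples"),
                               delimiter = "\t") {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus at least one data column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate ids in first column of ", path)
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                   ids[bad[1L]], names(vals)[j], path))
    if (anyNA(v))
      stop(sprintf("missing value at row '%s', column '%s' in %s",
                   ids[which(is.na(v))[1L]], names(vals)[j], path))
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "features-by-samples") m <- t(m)
  if (anyDuplicated(colnames(m))) stop("duplicate feature ids in ", path)
  feature_matrix(m)
}

#' Write a feature table or association matrix as TSV
#'
#' Full-precision round trip: values are written with 17 significant
#' digits so `read_feature_table()` recovers them exactly.
#'
#' @param x matrix-like with dimnames.
#' @param path output path.
#' @param id_header label for the leading id column.
#' @export
write_feature_table <- function(x, path, id_header = "id") {
  m <- as.matrix(unclass(x))
  df <- data.frame(rownames(m), format(m, digits = 17, trim = TRUE,
                                       scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_header, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join a sample metadata table onto a feature matrix
#'
#' Aligns metadata rows to the feature matrix by sample id and drops
#' samples with missing outcome or covariate values, logging the count
#' (mirrors cohort filtering where subjects with missing clinical
#' variables are omitted before analysis).
#'
#' @param X a [feature_matrix()].
#' @param meta data.frame with a sample id column.
#' @param id_col name of the sample id column in `meta`.
#' @param columns metadata columns that must be non-missing.
#' @return list with filtered `X` and aligned `meta`, plus `n_dropped`.
#' @export
join_metadata <- function(X, meta, id_col = 1L, columns = NULL) {
  X <- as_feature_matrix(X)
  ids <- as.character(meta[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in metadata")
  common <- intersect(rownames(X), ids)
  meta <- meta[match(common, ids), , drop = FALSE]
  if (is.null(columns)) columns <- setdiff(names(meta), names(meta)[id_col])
  complete <- stats::complete.cases(meta[columns])
  n_dropped <- (nrow(X) - length(common)) + sum(!complete)
  keep <- common[complete]
  if (length(keep) < 2L) stop("fewer than 2 samples remain after filtering")
  if (n_dropped > 0)
    message(sprintf("dropped %d sample(s) with missing metadata", n_dropped))
  list(X = X[keep, , drop = FALSE] |> feature_matrix(),
       meta = meta[complete, , drop = FALSE], n_dropped = n_dropped)
}

#' Read a feature-to-group map
#'
#' Two-column delimited text (feature_id, group). Duplicate feature rows
#' are an error. Features present in `feature_ids` but absent from the
#' map are an error in strict mode, or become singleton groups with
#' `allow_ungrouped = TRUE`.
#'
#' @param path file path.
#' @param feature_ids optional universe of feature ids to check coverage
#'   against.
#' @param allow_ungrouped put unmapped features into singleton groups
#'   instead of erroring.
#' @param delimiter field delimiter.
#' @return a [group_partition()].
#' @export
read_group_map <- function(path, feature_ids = NULL, allow_ungrouped = FALSE,
                           delimiter = "\t") {
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("group map needs two columns: feature_id, group")
  fid <- as.character(df[[1L]])
  if (anyDuplicated(fid))
    stop("duplicate feature rows in group map: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  groups <- stats::setNames(as.character(df[[2L]]), fid)
  if (!is.null(feature_ids)) {
    missing <- setdiff(feature_ids, fid)
    if (length(missing)) {
      if (!allow_ungrouped)
        stop("features absent from group map: ",
             paste(utils::head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) ", ...")
      groups <- c(groups,
                  stats::setNames(paste0("singleton_", missing), missing))
    }
    groups <- groups[feature_ids]
  }
  group_partition(groups)
}

# Serialize a pipeline result (meff + threshold) to a plain list for JSON.
result_as_list <- function(res, alpha) {
  th_b <- adjusted_pwer(alpha, res$meff$value, "bonferroni")
  th_s <- adjusted_pwer(alpha, res$meff$value, "sidak")
  out <- list(estimator = res$meff$estimator,
              corr_method = res$meff$corr_method,
              meff = res$meff$value,
              meff_rounded = round(res$meff$value),
              alpha = alpha,
              pwer_bonferroni = th_b$pwer,
              pwer_sidak = th_s$pwer)
  if (!is.null(res$meff$per_group))
    out$per_group <- as.list(res$meff$per_group)
  out
}
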