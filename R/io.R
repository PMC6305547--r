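## On-disk dialect: tab-delimited text, full float precision, ROI labels
## in the header row (and first column for square networks).  Lossless,
## diffable and language-neutral.

fmt_num <- function(x) sprintf("%.17g", x)

split_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("'%s' is empty", path)
  delim <- if (grepl("\t", lines[[1L]])) "\t" else ","
  cells <- strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stopf("format error in '%s': ragged rows (widths %s)",
          path, paste(unique(widths), collapse = ", "))
  cells
}

## TRUE for cells that are neither parseable numbers nor spelled-out
## non-finite values: such cells mark a header row.
label_like <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  is.na(v) & !(toupper(trimws(x)) %in%
                 c("NAN", "-NAN", "NA", "INF", "-INF", "+INF"))
}

#' Read a time-series matrix
#'
#' Reads a tab- or comma-delimited numeric V x P matrix, with an
#' optional single header row of ROI labels (labels `ROI_001`, ... are
#' generated when absent).  Ragged rows raise a format error; any
#' non-finite cell raises a value error naming its row and column.
#'
#' @param path file path.
#' @return numeric matrix with ROI column names.
#' @export
read_timeseries <- function(path) {
  cells <- split_table(path)
  has_header <- any(label_like(cells[[1L]]))
  labels <- if (has_header) cells[[1L]] else NULL
  body <- if (has_header) cells[-1L] else cells
  if (length(body) == 0L) stopf("'%s' has a header but no data rows", path)
  X <- suppressWarnings(
    matrix(as.numeric(unlist(body)), nrow = length(body),
           byrow = TRUE))
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stopf("value error in '%s': non-finite entry at data row %d, column %d",
          path, bad[1L], bad[2L])
  }
  colnames(X) <- if (!is.null(labels)) labels else
    default_roi_labels(ncol(X))
  check_timeseries(X, what = sprintf("'%s'", path))
}

#' @describeIn read_timeseries write a time-series matrix in the same
#'   dialect (tab-delimited, header row of ROI labels, full precision).
#' @param X numeric V x P matrix.
#' @export
write_timeseries <- function(X, path) {
  X <- check_timeseries(X)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(X), collapse = "\t"), con)
  writeLines(apply(X, 1L, function(r) paste(fmt_num(r), collapse = "\t")),
             con)
  invisible(path)
}

#' Read a connectivity matrix
#'
#' Reads the square tab-delimited network dialect: a header row of ROI
#' labels, and each data row starting with its ROI label.  The matrix
#' must be square and symmetric within `1e-10`.
#'
#' @param path file path.
#' @return symmetric numeric matrix with ROI dimnames.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stopf("'%s' is not a labelled square matrix", path)
  delim <- if (grepl("\t", lines[[1L]])) "\t" else ","
  cells <- strsplit(lines, delim, fixed = TRUE)
  labels <- cells[[1L]]
  # tolerate an empty corner cell in the header
  if (length(labels) == length(cells[[2L]]) && !nzchar(labels[[1L]]))
    labels <- labels[-1L]
  p <- length(labels)
  body <- cells[-1L]
  if (length(body) != p || any(lengths(body) != p + 1L))
    stopf("'%s' is not square: %d labels, %d data rows",
          path, p, length(body))
  W <- suppressWarnings(matrix(as.numeric(unlist(
    lapply(body, `[`, -1L))), nrow = p, byrow = TRUE))
  if (!all(is.finite(W)))
    stopf("value error in '%s': non-finite network entry", path)
  dimnames(W) <- list(vapply(body, `[[`, "", 1L), labels)
  check_network(W, what = sprintf("'%s'", path))
}

#' @describeIn read_network write a connectivity matrix (square,
#'   symmetric within `1e-10`) in the same dialect.
#' @param W symmetric numeric matrix.
#' @export
write_network <- function(W, path) {
  W <- check_network(W)
  labs <- colnames(W)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labs, collapse = "\t"), con)
  writeLines(vapply(seq_len(nrow(W)), function(i)
    paste(c(labs[i], fmt_num(W[i, ])), collapse = "\t"), ""), con)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Three tab-delimited columns with header: `subject_id`, `path`,
#' `label`.  Subject ids must be unique; relative paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest file path.
#' @param check_paths verify that every time-series file exists.
#' @return data frame with columns `subject_id`, `path`, `label`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stopf("manifest '%s' does not exist", path)
  m <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, comment.char = "")
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(m)))
    stopf("manifest '%s' must have columns %s", path,
          paste(need, collapse = ", "))
  if (anyDuplicated(m$subject_id))
    stopf("manifest '%s' has duplicate subject ids", path)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  if (check_paths) {
    missing <- m$path[!file.exists(m$path)]
    if (length(missing))
      stopf("manifest '%s': missing files: %s", path,
            paste(missing, collapse = ", "))
  }
  m
}

#' @describeIn read_manifest write a manifest data frame.
#' @param manifest data frame with `subject_id`, `path`, `label`.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest[, c("subject_id", "path", "label")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Lines of `key = value`; blank lines and `#` comments ignored.
#' Values that parse as numbers become numeric.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lines[lengths(kv) == 0L]
  if (length(bad)) stopf("config '%s': unparseable line '%s'", path, bad[1L])
  out <- lapply(kv, function(m) {
    v <- trimws(m[[3L]])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, function(m) trimws(m[[2L]]), "")
  out
}

#' Write a per-fold evaluation table
#'
#' Tab-delimited table with one row per outer fold plus an `all`
#' aggregate row: columns `method`, `N`, `s`, `param`, `fold`, `TP`,
#' `TN`, `FP`, `FN`, `ACC`, `SEN`, `SPE`.
#'
#' @param res an `eval_result` from [nested_loocv()].
#' @param method,N,s,grid run descriptors; `grid` maps the per-fold
#'   parameter index back to its value (a list or vector).
#' @param path output file; use `""` for stdout.
#' @param append append to an existing table without rewriting the
#'   header.
#' @return the table, invisibly.
#' @export
write_eval_table <- function(res, method, N, s, grid, path,
                             append = FALSE) {
  param_str <- vapply(as.list(grid), function(g)
    paste(format(unlist(g), digits = 10), collapse = "/"), "")
  f <- res$folds
  per_fold <- data.frame(
    method = method, N = N, s = s,
    param = param_str[f$param_index],
    fold = seq_len(nrow(f)),
    TP = as.integer(f$prediction > 0 & f$label > 0),
    TN = as.integer(f$prediction < 0 & f$label < 0),
    FP = as.integer(f$prediction > 0 & f$label < 0),
    FN = as.integer(f$prediction < 0 & f$label > 0),
    ACC = as.numeric(f$prediction == f$label), SEN = NA, SPE = NA)
  total <- data.frame(method = method, N = N, s = s, param = "selected",
                      fold = "all", TP = res$TP, TN = res$TN,
                      FP = res$FP, FN = res$FN, ACC = res$ACC,
                      SEN = res$SEN, SPE = res$SPE)
  tab <- rbind(per_fold, total)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !append, append = append)
  invisible(tab)
}
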