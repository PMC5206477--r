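#' Read a GEO Series Matrix file
#'
#' Parses the tab-delimited Series Matrix export used by the Gene
#' Expression Omnibus: metadata lines prefixed with `!`, then a
#' probes-by-samples table delimited by `!series_matrix_table_begin` /
#' `!series_matrix_table_end` whose first column is the probe ID. The
#' table is transposed so that genes become columns. Literal `null`,
#' `NA` or empty cells become missing values.
#'
#' Series Matrix files do not carry a canonical dose field, so the
#' response must be supplied: either directly as a numeric vector
#' (`dose`), or as the name of a `!Sample_characteristics_ch1` key
#' (`dose_key`) whose per-sample values contain a number, e.g.
#' `"dose: 2.5"`.
#'
#' @param path path to an (uncompressed) Series Matrix TXT file.
#' @param dose optional numeric vector, one dose per sample, in file order.
#' @param dose_key optional characteristics key to extract the dose from.
#' @return An [expr_dataset()]; `meta` holds the `!Series_*` metadata
#'   fields encountered.
#' @export
read_series_matrix <- function(path, dose = NULL, dose_key = NULL) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin)
    stop("malformed series matrix: expected one table_begin/table_end pair",
         " (found begin at line ", paste(begin, collapse = ","),
         ", end at line ", paste(end, collapse = ","), ")")

  unquote <- function(x) gsub('^"|"$', "", x)
  split_tsv <- function(x) unquote(strsplit(x, "\t", fixed = TRUE)[[1]])

  header <- split_tsv(lines[begin + 1L])
  sample_ids <- header[-1L]
  n <- length(sample_ids)
  body <- lines[(begin + 2L):(end - 1L)]
  if (!length(body)) stop("series matrix table has no data rows")

  probe_ids <- character(length(body))
  M <- matrix(NA_real_, nrow = length(body), ncol = n)
  for (k in seq_along(body)) {
    cells <- split_tsv(body[k])
    if (length(cells) != n + 1L)
      stop("series matrix row at line ", begin + 1L + k, " has ",
           length(cells) - 1L, " values but the header names ", n,
           " samples")
    probe_ids[k] <- cells[1L]
    v <- cells[-1L]
    v[v %in% c("", "null", "NA", "NULL")] <- NA
    M[k, ] <- suppressWarnings(as.numeric(v))
  }

  meta <- list()
  meta_lines <- grep("^!", lines[seq_len(begin - 1L)], value = TRUE)
  for (ln in meta_lines) {
    parts <- split_tsv(ln)
    key <- sub("^!", "", parts[1L])
    if (length(parts) > 1L)
      meta[[key]] <- c(meta[[key]], list(parts[-1L]))
  }

  if (is.null(dose)) {
    if (is.null(dose_key))
      stop("no response: supply `dose` or `dose_key` to define the dose")
    char_fields <- meta[grepl("^Sample_characteristics", names(meta))]
    found <- NULL
    for (field in char_fields) for (row in field) {
      hit <- grepl(paste0("^\\s*", dose_key, "\\s*:"), row)
      if (all(hit)) {
        found <- suppressWarnings(
          as.numeric(sub(paste0("^\\s*", dose_key, "\\s*:\\s*"), "",
                         sub("\\s*([a-zA-Z%]+)\\s*$", "", row))))
        break
      }
    }
    if (is.null(found) || anyNA(found))
      stop("no response: dose_key '", dose_key,
           "' not found (or non-numeric) in sample characteristics")
    dose <- found
  }
  if (length(dose) != n)
    stop("dose vector has length ", length(dose), " but the file has ",
         n, " samples")

  X <- t(M)
  dimnames(X) <- list(sample_ids, probe_ids)
  expr_dataset(X, dose, sample_ids = sample_ids, gene_ids = probe_ids,
               meta = meta)
}

#' Read and write the package TSV dialect
#'
#' A plain UTF-8 tab-separated table with header
#' `sample_id<TAB>dose<TAB><gene>...`, one row per sample, `.` decimal
#' separator and `NA` for missing cells. Doubles are written with 17
#' significant digits, so a write/read round trip reproduces `X` and `y`
#' bit-exactly.
#'
#' @param ds an [expr_dataset()].
#' @param path file path.
#' @return `read_expr_tsv` returns an `expr_dataset`; `write_expr_tsv`
#'   returns `path` invisibly.
#' @export
write_expr_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "expr_dataset"))
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  }
  header <- paste(c("sample_id", "dose", ds$gene_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(ds$X)), function(i) {
    paste(c(ds$sample_ids[i], fmt(ds$y[i]), fmt(ds$X[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_expr_tsv
#' @export
read_expr_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (ncol(dt) < 3L || names(dt)[1L] != "sample_id" ||
      names(dt)[2L] != "dose")
    stop("not an exprdose TSV: expected header sample_id<TAB>dose<TAB>...")
  X <- as.matrix(dt[, -(1:2), drop = FALSE])
  expr_dataset(X, dt$dose, sample_ids = dt$sample_id,
               gene_ids = colnames(X))
}
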