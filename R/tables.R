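#' Write the shortest-path results table
#'
#' Emits a UTF-8, LF-terminated TSV with columns exactly
#' `source  target  size  path`: one row per direction-annotated path
#' listing, size being the hop count (total weight in weighted mode) and
#' the path rendered as node ids joined by `"|"`. Rows are sorted by
#' (source, target, path) under byte collation, so output is deterministic
#' for a given path set. An empty path set yields the header only.
#'
#' @param pathset an `spn_pathset`.
#' @param file output path (or connection).
#' @return `file`, invisibly.
#' @export
write_path_table <- function(pathset, file) {
  stopifnot(inherits(pathset, "spn_pathset"))
  header <- "source\ttarget\tsize\tpath"
  if (!length(pathset$paths)) {
    writeLines(header, file)
    return(invisible(file))
  }
  src <- vapply(pathset$paths, `[[`, character(1), "source")
  tgt <- vapply(pathset$paths, `[[`, character(1), "target")
  size <- if (pathset$weighted) {
    vapply(pathset$paths, `[[`, numeric(1), "weight")
  } else {
    vapply(pathset$paths, `[[`, integer(1), "hops")
  }
  pth <- vapply(pathset$paths, function(l) paste(l$nodes, collapse = "|"),
                character(1))
  o <- order_c(src, tgt, pth)
  rows <- paste(src[o], tgt[o],
                format(size[o], trim = TRUE, scientific = FALSE, digits = 15),
                pth[o], sep = "\t")
  tryCatch(writeLines(c(header, rows), file), error = function(e)
    spn_stop("io", sprintf("cannot write path table: %s", conditionMessage(e))))
  invisible(file)
}

#' Write the summary-statistics table
#'
#' One-row TSV with columns `average_path_length`, `unique_paths`,
#' `expected_paths`, `connected` (rendered `True`/`False`, `NA` when not
#' applicable).
#'
#' @param stats an `spn_stats` from [compute_stats()].
#' @param file output path (or connection).
#' @return `file`, invisibly.
#' @export
write_stats_table <- function(stats, file) {
  stopifnot(inherits(stats, "spn_stats"))
  fmt_num <- function(x) {
    if (is.na(x)) "NA" else format(x, trim = TRUE, scientific = FALSE, digits = 15)
  }
  row <- paste(fmt_num(stats$average_path_length),
               stats$unique_paths,
               fmt_num(stats$expected_paths),
               if (is.na(stats$connected)) "NA"
               else if (stats$connected) "True" else "False",
               sep = "\t")
  tryCatch(
    writeLines(c("average_path_length\tunique_paths\texpected_paths\tconnected",
                 row), file),
    error = function(e)
      spn_stop("io", sprintf("cannot write stats table: %s", conditionMessage(e))))
  invisible(file)
}

#' Write the path-length grouping table
#'
#' TSV rendering of [group_by_length()]: columns `size` and `count`, one
#' row per realized path size.
#'
#' @param lengths an `spn_lengthtable`.
#' @param file output path (or connection).
#' @return `file`, invisibly.
#' @export
write_length_table <- function(lengths, file) {
  stopifnot(inherits(lengths, "spn_lengthtable"))
  rows <- paste(format(lengths$size, trim = TRUE, scientific = FALSE, digits = 15),
                lengths$count, sep = "\t")
  tryCatch(writeLines(c("size\tcount", rows), file), error = function(e)
    spn_stop("io", sprintf("cannot write length table: %s", conditionMessage(e))))
  invisible(file)
}
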