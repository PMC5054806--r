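#' Read an edge-weight table
#'
#' Two dialects are supported:
#' * `tsv3` — three columns `source`, `target`, `weight`, tab- or
#'   space-delimited, with an optional header line (a first row whose
#'   fields are all non-numeric is treated as a header and skipped);
#' * `cytoscape_ea` — the Cytoscape edge-attribute format: a header line
#'   naming the attribute, then `source (label) target = value` lines. The
#'   header must match `attribute_name`, otherwise a mismatch error is
#'   raised.
#'
#' Weights are real-valued and may be negative. A non-numeric weight raises
#' a parse error naming the line. Duplicate entries for the same node pair
#' with differing values are collapsed to the minimum with a warning.
#'
#' @param file path to the weight file.
#' @param attribute_name name of the edge attribute holding the weights.
#' @param dialect `"tsv3"` or `"cytoscape_ea"`.
#' @return an object of class `spn_weightmap` with fields `attribute` and
#'   `entries` (data frame `from`, `to`, `weight`).
#' @export
read_weights <- function(file, attribute_name,
                         dialect = c("tsv3", "cytoscape_ea")) {
  dialect <- match.arg(dialect)
  lines <- tryCatch(readLines(file, warn = FALSE), error = function(e)
    spn_stop("io", sprintf("cannot read weight file: %s", conditionMessage(e))))
  from <- character()
  to <- character()
  w <- numeric()
  nonblank <- which(nzchar(trimws(lines)))

  if (dialect == "tsv3") {
    first <- TRUE
    for (i in nonblank) {
      tok <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
      if (length(tok) != 3L)
        spn_stop("parse", sprintf("weight file line %d: expected 3 columns, found %d",
                                  i, length(tok)))
      val <- suppressWarnings(as.numeric(tok[3L]))
      if (first && all(is.na(suppressWarnings(as.numeric(tok))))) {
        first <- FALSE  # header row: every field non-numeric
        next
      }
      first <- FALSE
      if (is.na(val))
        spn_stop("parse", sprintf("weight file line %d: non-numeric weight '%s'",
                                  i, tok[3L]))
      from <- c(from, tok[1L])
      to <- c(to, tok[2L])
      w <- c(w, val)
    }
  } else {
    if (!length(nonblank))
      spn_stop("parse", "edge-attribute file is empty (missing header line)")
    hdr <- strsplit(trimws(lines[[nonblank[1L]]]), "[ \t]+")[[1]][1L]
    if (!identical(hdr, attribute_name))
      spn_stop("attribute_mismatch", sprintf(
        "edge-attribute file stores '%s', not the requested attribute '%s'",
        hdr, attribute_name))
    for (i in nonblank[-1L]) {
      m <- regmatches(lines[[i]],
                      regexec("^\\s*(\\S+)\\s+\\((.*)\\)\\s+(\\S+)\\s*=\\s*(\\S+)\\s*$",
                              lines[[i]]))[[1]]
      if (length(m) != 5L)
        spn_stop("parse", sprintf(
          "edge-attribute file line %d: expected 'source (label) target = value'", i))
      val <- suppressWarnings(as.numeric(m[5L]))
      if (is.na(val))
        spn_stop("parse", sprintf("edge-attribute file line %d: non-numeric weight '%s'",
                                  i, m[5L]))
      from <- c(from, m[2L])
      to <- c(to, m[4L])
      w <- c(w, val)
    }
  }

  key <- paste(from, to, sep = "\t")
  if (anyDuplicated(key)) {
    nuniq <- tapply(w, key, function(x) length(unique(x)))
    if (any(nuniq > 1L))
      warning("duplicate weight entries with differing values collapsed to the minimum")
    wmin <- tapply(w, key, min)
    keep <- !duplicated(key)
    from <- from[keep]
    to <- to[keep]
    w <- as.numeric(wmin[key[keep]])
  }
  structure(
    list(attribute = attribute_name,
         entries = data.frame(from = from, to = to, weight = w,
                              stringsAsFactors = FALSE)),
    class = "spn_weightmap"
  )
}

#' @export
print.spn_weightmap <- function(x, ...) {
  cat(sprintf("<spn_weightmap> attribute '%s': %d entries\n",
              x$attribute, nrow(x$entries)))
  invisible(x)
}

#' Attach a weight map to a graph
#'
#' Every edge of the graph must have an entry in the weight map (missing
#' entries are an error listing the uncovered edges, never a silent
#' default). In undirected mode the lookup is symmetric: an entry for
#' `(a, b)` also covers the edge `(b, a)`. The input graph is not modified.
#'
#' @param graph an [spn_graph()].
#' @param weightmap an `spn_weightmap` from [read_weights()].
#' @return a new, weighted `spn_graph`.
#' @export
attach_weights <- function(graph, weightmap) {
  stopifnot(inherits(graph, "spn_graph"), inherits(weightmap, "spn_weightmap"))
  e <- graph$edges
  lut <- structure(weightmap$entries$weight,
                   names = paste(weightmap$entries$from, weightmap$entries$to,
                                 sep = "\t"))
  w <- unname(lut[paste(e$from, e$to, sep = "\t")])
  if (!graph$directed) {
    w2 <- unname(lut[paste(e$to, e$from, sep = "\t")])
    w <- pmin(w, w2, na.rm = TRUE)
    w[is.na(w) & is.na(w2)] <- NA_real_
  }
  if (anyNA(w)) {
    miss <- paste(e$from[is.na(w)], e$to[is.na(w)], sep = " - ")
    spn_stop("missing_weight", sprintf(
      "no weight for %d edge(s): %s", length(miss), paste(miss, collapse = ", ")))
  }
  spn_graph(edges = e[, c("from", "to", "label")], nodes = graph$nodes,
            directed = graph$directed, weights = w)
}
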