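# Plain-text exporters/importers. All numeric scores are written with six
# decimal places so identical runs produce byte-identical files.

#' Write a labeled similarity matrix as TSV
#'
#' First row and first column carry the labels; a `# measure:` comment
#' line records provenance when the matrix has a `"measure"` attribute.
#'
#' @param matrix labeled numeric matrix ([term_matrix()],
#'   [entity_matrix()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  m <- as.matrix(matrix)
  if (!length(m)) data_error("refusing to write an empty matrix")
  con <- file(path, open = "wt")
  on.exit(close(con))
  meas <- attr(matrix, "measure")
  if (!is.null(meas)) writeLines(sprintf("# measure: %s", meas), con)
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], fmt_score(m[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read a similarity matrix written by [write_matrix()]
#'
#' @param path TSV file path.
#' @return Labeled numeric matrix (with the `"measure"` attribute when the
#'   provenance comment is present).
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meas <- NULL
  if (length(lines) && startsWith(lines[1], "# measure:")) {
    meas <- trimws(sub("^# measure:", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) < 2L) data_error("matrix file has no data rows")
  cols <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  labs <- vapply(body, `[`, "", 1L)
  m <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(length(cols))))
  dimnames(m) <- list(labs, cols)
  if (!is.null(meas)) attr(m, "measure") <- meas
  m
}

#' Write an enrichment table as TSV
#'
#' Header `term_id name k K n N p p_adj significant`; p-values with six
#' decimals, `significant` as `true`/`false`.
#'
#' @param table an [enrichment_table][enrich].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(table, path) {
  if (!nrow(table)) data_error("refusing to write an empty enrichment table")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("term_id", "name", "k", "K", "n", "N", "p", "p_adj",
                     "significant"), collapse = "\t"), con)
  for (i in seq_len(nrow(table))) {
    writeLines(paste(c(
      table$term_id[i], table$name[i],
      table$k[i], table$K[i], table$n[i], table$N[i],
      fmt_score(table$p[i]), fmt_score(table$p_adj[i]),
      if (table$significant[i]) "true" else "false"
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write an edge list as TSV or SIF
#'
#' TSV: header `source target weight`, one edge per line. SIF:
#' `source sim target`, space-delimited, weights not retained (SIF carries
#' interaction types, not weights). An empty edge set yields a header-only
#' TSV (or an empty SIF) without error.
#'
#' @param edges data frame with columns `source`, `target` and (for TSV)
#'   `weight`.
#' @param path output file path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines("source\ttarget\tweight", con)
    if (nrow(edges)) {
      writeLines(paste(edges$source, edges$target, fmt_score(edges$weight),
                       sep = "\t"), con)
    }
  } else {
    if (nrow(edges)) {
      writeLines(paste(edges$source, "sim", edges$target), con)
    }
  }
  invisible(path)
}

#' Read an entity edge list
#'
#' Accepts the TSV written by [write_network()] (with or without the
#' header and the weight column) and SIF (`source relation target`).
#'
#' @param path input file path.
#' @param format `"tsv"` or `"sif"`.
#' @return Data frame with columns `source`, `target` and `weight`
#'   (`NA` when absent from the input).
#' @export
read_network <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(source = character(0), target = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (format == "sif") {
    if (!length(lines)) return(empty)
    f <- strsplit(lines, "[ \t]+")
    bad <- lengths(f) < 3L
    if (any(bad)) data_error("malformed SIF line(s)")
    return(data.frame(
      source = vapply(f, `[`, "", 1L),
      target = vapply(f, `[`, "", 3L),
      weight = NA_real_,
      stringsAsFactors = FALSE
    ))
  }
  if (length(lines) && grepl("^source\t", lines[1])) lines <- lines[-1]
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) < 2L
  if (any(bad)) data_error("malformed edge-list line(s): need 2+ tab fields")
  data.frame(
    source = vapply(f, `[`, "", 1L),
    target = vapply(f, `[`, "", 2L),
    weight = vapply(f, function(x) {
      if (length(x) >= 3L) suppressWarnings(as.numeric(x[3])) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}
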