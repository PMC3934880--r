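#' Construct a raw count table
#'
#' A count table holds raw read counts R_ij for gene i in sample j, with
#' genes in rows and samples in columns. The first column must identify the
#' gene; all remaining columns are samples and must hold non-negative
#' integer counts. Library sizes R_j are always the column sums of the raw
#' counts.
#'
#' @param x A data frame with one gene-identifier column followed by one
#'   numeric column per sample.
#' @param gene_col Name of the gene-identifier column. It is renamed to
#'   `"gene"` and moved first.
#' @return A tibble of class `bsn_counts` with column `gene` followed by
#'   one integer column per sample.
#' @examples
#' counts <- count_tbl(data.frame(gene = c("g1", "g2", "g3"),
#'                                s1 = c(50L, 30L, 20L),
#'                                s2 = c(100L, 60L, 40L)))
#' lib_sizes(counts)
#' @export
count_tbl <- function(x, gene_col = names(x)[1]) {
  x <- as_tibble(x)
  if (!gene_col %in% names(x)) {
    abort(sprintf("gene column '%s' not found", gene_col))
  }
  x <- dplyr::relocate(dplyr::rename(x, gene = all_of(gene_col)), "gene")
  x$gene <- as.character(x$gene)
  if (ncol(x) < 2L) abort("count table needs at least one sample column")
  if (anyDuplicated(x$gene)) {
    dup <- unique(x$gene[duplicated(x$gene)])
    abort(sprintf("duplicate gene id(s): %s",
                  paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (anyDuplicated(names(x)[-1L])) abort("duplicate sample ids")
  for (s in names(x)[-1L]) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("counts in sample '%s' are not numeric", s))
    }
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf(
        "count for gene '%s' in sample '%s' is not a non-negative integer (got %s)",
        x$gene[bad[1L]], s, format(v[bad[1L]])))
    }
    x[[s]] <- as.double(v)  # doubles to survive lib sizes > .Machine$integer.max
  }
  class(x) <- c("bsn_counts", class(x))
  x
}

#' Sample identifiers of a gene-by-sample table
#' @param x A count or normalized table (gene column first).
#' @return Character vector of sample ids, in column order.
#' @export
sample_ids <- function(x) setdiff(names(x), "gene")

#' Library sizes (per-sample total mapped reads)
#'
#' @param x A count table as returned by [count_tbl()] or [read_count_table()].
#' @return Named numeric vector of column sums R_j.
#' @export
lib_sizes <- function(x) {
  m <- values_matrix(x)
  colSums(m)
}

# gene-by-sample numeric matrix view (rownames = gene ids)
values_matrix <- function(x) {
  stopifnot(is.data.frame(x), "gene" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "gene")])
  rownames(m) <- x$gene
  storage.mode(m) <- "double"
  m
}

# rebuild a tibble from a values matrix, preserving extra classes/attrs of template
matrix_to_tbl <- function(m, genes) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble(gene = genes), out)
}

#' Read a raw count table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"matrix"`}{a TSV with a header row of sample ids and a leading
#'     gene-id column; lines starting with `#` are ignored.}
#'   \item{`"htseq"`}{a directory of per-sample two-column TSV files as
#'     written by htseq-count (gene id, count; no header). The summary rows
#'     whose ids start with `"__"` (e.g. `__no_feature`) are removed so they
#'     never inflate library sizes; their counts are kept in the
#'     `htseq_summary` attribute. All files must contain the same gene set;
#'     gene order is the first file's order. Samples are named by file name
#'     without extension and ordered lexicographically unless `sample_order`
#'     is given.}
#' }
#'
#' @param path File (matrix dialect) or directory (htseq dialect).
#' @param dialect `"matrix"` or `"htseq"`.
#' @param sample_order Optional character vector of sample ids fixing the
#'   column order for the htseq dialect.
#' @return A [count_tbl()]; for `dialect = "htseq"` the attribute
#'   `htseq_summary` holds a tibble (sample, id, count) of the removed
#'   summary rows.
#' @export
read_count_table <- function(path, dialect = c("matrix", "htseq"),
                             sample_order = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
    if (nrow(x) == 0L) abort(sprintf("no counts in %s", path))
    return(count_tbl(x))
  }
  if (!dir.exists(path)) abort(sprintf("directory not found: %s", path))
  files <- list.files(path, pattern = "\\.(tsv|txt|counts)$", full.names = TRUE)
  if (length(files) < 1L) abort(sprintf("no htseq-count files in %s", path))
  samples <- sub("\\.[^.]*$", "", basename(files))
  files <- files[order(samples)]
  samples <- sort(samples)
  if (!is.null(sample_order)) {
    missing <- setdiff(sample_order, samples)
    if (length(missing)) {
      abort(sprintf("sample_order names absent from directory: %s",
                    paste(missing, collapse = ", ")))
    }
    files <- files[match(sample_order, samples)]
    samples <- sample_order
  }
  per_sample <- purrr::map(files, function(f) {
    readr::read_tsv(f, col_names = c("gene", "count"), comment = "#",
                    col_types = "cd", progress = FALSE)
  })
  special <- purrr::map2(per_sample, samples, function(tb, s) {
    sp <- tb[startsWith(tb$gene, "__"), ]
    if (nrow(sp)) tibble(sample = s, id = sp$gene, count = sp$count) else NULL
  })
  special <- dplyr::bind_rows(special)
  per_sample <- purrr::map(per_sample, ~ .x[!startsWith(.x$gene, "__"), ])
  genes <- per_sample[[1L]]$gene
  for (k in seq_along(per_sample)[-1L]) {
    gk <- per_sample[[k]]$gene
    if (!setequal(gk, genes) || length(gk) != length(genes)) {
      diff <- c(setdiff(genes, gk), setdiff(gk, genes))
      abort(sprintf("inconsistent gene sets across htseq files; differing ids: %s",
                    paste(utils::head(unique(diff), 10L), collapse = ", ")))
    }
  }
  mat <- purrr::map(per_sample, function(tb) tb$count[match(genes, tb$gene)])
  out <- tibble(gene = genes)
  for (k in seq_along(samples)) out[[samples[k]]] <- mat[[k]]
  out <- count_tbl(out)
  attr(out, "htseq_summary") <- special
  out
}

#' Write a count or normalized table to TSV
#'
#' Raw counts are written as integers and round-trip bit-exactly through
#' [read_count_table()]; normalized values are written with 6 significant
#' digits. Provenance (method tag, value space, scale note) is recorded in
#' leading comment lines prefixed `#`.
#'
#' @param x A [count_tbl()] or a normalized table from [bsn()], [rpm()],
#'   [rpkm()] or [tmm_log2()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  hdr <- character()
  if (inherits(x, "bsn_norm")) {
    hdr <- c(sprintf("# method=%s", attr(x, "method")),
             sprintf("# value_space=%s", attr(x, "value_space")))
    sc <- attr(x, "scale_note")
    if (!is.null(sc)) hdr <- c(hdr, sprintf("# scales=%s", sc))
    fmt <- function(v) formatC(v, digits = 6L, format = "g")
  } else {
    hdr <- "# method=raw"
    fmt <- function(v) sprintf("%.0f", v)
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(hdr, con)
  cols <- setdiff(names(x), "gene")
  writeLines(paste(c("gene", cols), collapse = "\t"), con)
  if (nrow(x)) {
    body <- vapply(seq_len(nrow(x)), function(i) {
      paste(c(x$gene[i], vapply(cols, function(s) fmt(x[[s]][i]), character(1))),
            collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}
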