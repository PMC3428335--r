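#' Expression matrix with phenotype labels
#'
#' A validated genes x samples intensity matrix with per-sample phenotype
#' labels (`"tumor"` / `"control"`). Intensities must be finite and
#' strictly positive; gene and sample identifiers must be unique.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param phenotype character vector of per-sample labels, or `NULL` for
#'   unlabeled data.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `phenotype`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_matrix(m, phenotype = c("tumor", "control"))
#' @export
expression_matrix <- function(values, phenotype = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("intensities must be finite")
  if (any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stop(
      "non-positive intensity at gene '", rownames(values)[bad[1]],
      "', sample '", colnames(values)[bad[2]], "'"
    )
  }
  if (!is.null(phenotype)) {
    phenotype <- as.character(phenotype)
    if (length(phenotype) != ncol(values)) {
      stop("phenotype length must equal the number of samples")
    }
    names(phenotype) <- colnames(values)
  }
  structure(
    list(
      values = values,
      gene_ids = rownames(values),
      sample_ids = colnames(values),
      phenotype = phenotype
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(
    "expression_matrix:", length(x$gene_ids), "genes x",
    length(x$sample_ids), "samples\n"
  )
  if (!is.null(x$phenotype)) {
    print(table(phenotype = x$phenotype))
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  ph <- if (is.null(x$phenotype)) NULL else x$phenotype[colnames(v)]
  expression_matrix(v, phenotype = unname(ph))
}

#' Read an expression matrix from TSV or GCT
#'
#' The TSV layout is a header row of sample ids followed by one row per
#' gene (first column = gene id). GCT v1.2 files carry the `#1.2` version
#' line, a dimensions line, and `Name`/`Description` columns; dimension
#' mismatches are rejected with the offending counts.
#'
#' @param path input file.
#' @param format `"tsv"` or `"gct"`; default guessed from the extension.
#' @param phenotype optional phenotype vector or path to a CLS file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            phenotype = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[1], "#1.2")) {
      stop("not a GCT v1.2 file (line 1): ", path)
    }
    dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
    tab <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2]) {
      stop(
        "GCT header declares ", dims[1], " x ", dims[2], " but body is ",
        nrow(tab), " x ", ncol(tab) - 2L
      )
    }
    vals <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(vals) <- tab[[1]]
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    vals <- as.matrix(tab[, -1, drop = FALSE])
    rownames(vals) <- tab[[1]]
  }
  if (!is.numeric(vals)) stop("non-numeric intensity values in ", path)
  if (is.character(phenotype) && length(phenotype) == 1L && file.exists(phenotype)) {
    phenotype <- read_cls(phenotype)
  }
  expression_matrix(vals, phenotype = phenotype)
}

#' Write an expression matrix as TSV or GCT v1.2
#'
#' @param em an [expression_matrix()].
#' @param path output file.
#' @param format `"tsv"` or `"gct"`; default guessed from the extension.
#' @export
write_expression <- function(em, path, format = c("auto", "tsv", "gct")) {
  stopifnot(inherits(em, "expression_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#1.2", con)
    writeLines(paste(nrow(em$values), ncol(em$values), sep = "\t"), con)
    tab <- data.frame(
      Name = em$gene_ids, Description = "na",
      em$values, check.names = FALSE, stringsAsFactors = FALSE
    )
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene_id = em$gene_ids, em$values,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read or write phenotype labels in CLS format
#'
#' Categorical CLS: line 1 `n_samples n_classes 1`, line 2 `# class names`,
#' line 3 space-separated per-sample labels (names or 0-based indices).
#'
#' @param path file path.
#' @return `read_cls` returns a character vector of per-sample labels.
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed CLS file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  classes <- strsplit(trimws(sub("^#\\s*", "", lines[2])), "\\s+")[[1]]
  toks <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(toks) != hdr[1]) {
    stop("CLS declares ", hdr[1], " samples but lists ", length(toks))
  }
  if (all(toks %in% classes)) {
    return(toks)
  }
  classes[as.integer(toks) + 1L]
}

#' @param phenotype character vector of per-sample labels.
#' @rdname read_cls
#' @export
write_cls <- function(phenotype, path) {
  classes <- unique(phenotype)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(phenotype), length(classes), 1), con)
  writeLines(paste("#", paste(classes, collapse = " ")), con)
  writeLines(paste(match(phenotype, classes) - 1L, collapse = " "), con)
  invisible(path)
}
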