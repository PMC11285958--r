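# Internal: stop with a classed condition so callers/tests can distinguish
# contract violations from ordinary errors.
abort <- function(msg, class) {
  stop(structure(class = c(class, "anchorsig_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

msg_log <- function(...) message("[anchorsig] ", ...)

#' Construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix of log-scale expression
#' values with genes in rows and samples in columns.  This constructor
#' validates the container invariants: unique gene and sample identifiers,
#' matching dimensions, and finite values throughout.  Values are assumed
#' already log-transformed and normalized upstream; no normalization is
#' applied anywhere in the package.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#' @return a numeric matrix with validated dimnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("values must be a numeric matrix", "anchorsig_format_error")
  if (is.null(gene_ids) || is.null(sample_ids))
    abort("gene and sample identifiers are required", "anchorsig_format_error")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    abort("identifier lengths do not match matrix dimensions",
          "anchorsig_format_error")
  if (anyDuplicated(gene_ids))
    abort("duplicate gene identifiers", "anchorsig_format_error")
  if (anyDuplicated(sample_ids))
    abort("duplicate sample identifiers", "anchorsig_format_error")
  if (!all(is.finite(values)))
    abort("expression values must all be finite", "anchorsig_format_error")
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV dialect: a header row of sample identifiers, first column of gene
#' identifiers, tab-separated numeric values.  GCT dialect (v1.2): a
#' version line `#1.2`, a dimension line `<n_genes>\t<n_samples>`, then a
#' header with `Name` and `Description` columns before the sample columns.
#' Duplicate gene identifiers are collapsed by keeping the row with the
#' highest mean expression (logged).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "anchorsig_io_error")
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3 || trimws(lines[1]) != "#1.2")
      abort("GCT file must start with version line '#1.2'",
            "anchorsig_format_error")
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
    if (length(dims) < 2 || anyNA(dims))
      abort("malformed GCT dimension line", "anchorsig_format_error")
    tab <- utils::read.table(text = lines[-(1:2)], sep = "\t", header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "")
    if (!identical(colnames(tab)[1:2], c("Name", "Description")))
      abort("GCT header must begin with Name and Description columns",
            "anchorsig_format_error")
    if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2])
      abort(sprintf(
        "GCT dimension line says %d x %d but file has %d rows x %d samples",
        dims[1], dims[2], nrow(tab), ncol(tab) - 2L),
        "anchorsig_format_error")
    ids <- tab$Name
    num <- tab[, -(1:2), drop = FALSE]
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE, colClasses = "character",
                             quote = "", comment.char = "#")
    if (ncol(tab) < 2)
      abort("TSV expression file needs a gene column and >= 1 sample column",
            "anchorsig_format_error")
    ids <- tab[[1]]
    num <- tab[, -1, drop = FALSE]
  }
  vals <- matrix(NA_real_, nrow(num), ncol(num),
                 dimnames = list(NULL, colnames(num)))
  for (j in seq_len(ncol(num))) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad) || anyNA(num[[j]]))
      abort(sprintf("non-numeric value at row %d, column '%s'",
                    if (length(bad)) bad[1] else which(is.na(num[[j]]))[1],
                    colnames(num)[j]),
            "anchorsig_parse_error")
    vals[, j] <- v
  }
  if (anyDuplicated(ids)) {
    keep <- tapply(seq_along(ids), ids, function(ii) {
      ii[which.max(rowMeans(vals[ii, , drop = FALSE]))]
    })
    keep <- sort(unname(keep))
    msg_log(sprintf(
      "collapsed %d duplicate gene ids, keeping highest-mean rows",
      length(ids) - length(keep)))
    vals <- vals[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  expression_matrix(vals, ids, colnames(vals))
}

#' Write an expression matrix
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(expr, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  expr <- expression_matrix(expr)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
    header <- paste(c("Name", "Description", colnames(expr)), collapse = "\t")
    writeLines(header, con)
    body <- apply(expr, 1, function(v)
      paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = "\t"))
    writeLines(paste(rownames(expr), "na", body, sep = "\t"), con)
  } else {
    tab <- data.frame(gene_id = rownames(expr),
                      format(expr, digits = 17, trim = TRUE,
                             scientific = FALSE),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Construct a gene-set collection
#'
#' A named list of character vectors (set members) with a parallel
#' `descriptions` attribute, mirroring the GMT format.
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param descriptions optional character vector, one per set.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    abort("sets must be a fully named list", "anchorsig_format_error")
  if (anyDuplicated(names(sets)))
    abort("duplicate gene-set names", "anchorsig_format_error")
  sets <- lapply(sets, function(m) {
    m <- as.character(m)
    if (length(m) < 1) abort("gene set with no members",
                             "anchorsig_format_error")
    unique(m)
  })
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(descriptions) == length(sets))
  structure(sets, descriptions = as.character(descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection with %d sets (sizes %s)\n", length(x),
              paste(range(lengths(x)), collapse = "-")))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Each line is `name TAB description TAB member TAB member ...`.
#' Duplicate members within one line are deduplicated with a warning;
#' duplicate set names are an error.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "anchorsig_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      abort(sprintf("GMT line %d has fewer than 3 fields", i),
            "anchorsig_format_error")
    nm <- fields[1]
    if (nm %in% names(sets))
      abort(sprintf("duplicate gene-set name '%s' at line %d", nm, i),
            "anchorsig_format_error")
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d ('%s'): duplicate members removed", i, nm))
      members <- unique(members)
    }
    sets[[nm]] <- members
    descs <- c(descs, fields[2])
  }
  gene_set_collection(sets, descs)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  descs <- attr(collection, "descriptions")
  descs[!nzchar(descs)] <- "na"
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], descs[i], collection[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct / validate a clinical table
#'
#' Required columns: `sample_id` (unique), `os_time` (positive overall
#' survival time, unit declared by the caller and never converted), and
#' `os_event` (1 = death observed, 0 = censored).  Optional columns:
#' `stage` (ordinal 1-4), `tissue_class` (`"tumor"`/`"normal"`),
#' `timepoint` (`"primary"`, `"metastatic"`, `"recurrent"`, `"pre"`,
#' `"post"`), and `patient_id` for longitudinal pairing.
#'
#' @param df a data.frame.
#' @return the validated data.frame with class `clinical_table` prepended.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "os_time", "os_event")
  if (!all(need %in% colnames(df)))
    abort(paste("clinical table missing columns:",
                paste(setdiff(need, colnames(df)), collapse = ", ")),
          "anchorsig_format_error")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    abort("duplicate sample_id in clinical table", "anchorsig_format_error")
  ok_time <- is.na(df$os_time) | df$os_time > 0
  if (!all(ok_time))
    abort("os_time must be positive where present", "anchorsig_format_error")
  if (!all(df$os_event %in% c(0, 1, NA)))
    abort("os_event must be 0 or 1", "anchorsig_format_error")
  if ("stage" %in% colnames(df) &&
      !all(is.na(df$stage) | df$stage %in% 1:4))
    abort("stage must be an integer in 1..4", "anchorsig_format_error")
  if ("tissue_class" %in% colnames(df) &&
      !all(is.na(df$tissue_class) | df$tissue_class %in% c("tumor", "normal")))
    abort("tissue_class must be 'tumor' or 'normal'", "anchorsig_format_error")
  if ("timepoint" %in% colnames(df) &&
      !all(is.na(df$timepoint) |
           df$timepoint %in% c("primary", "metastatic", "recurrent",
                               "pre", "post")))
    abort("invalid timepoint level", "anchorsig_format_error")
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' Read a clinical table from TSV
#'
#' @param path file path to a tab-separated table with a header.
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "anchorsig_io_error")
  clinical_table(utils::read.table(path, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE, quote = "",
                                   comment.char = "#",
                                   colClasses = c(sample_id = "character")))
}

#' Write a clinical table as TSV
#'
#' @param clin a [clinical_table()].
#' @param path output path.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(as.data.frame(clin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict expression and clinical data to their shared samples
#'
#' Both inputs are subset to the intersection of their sample identifiers,
#' in the expression matrix's column order.  The intersection size is
#' logged; an empty intersection is an error.
#'
#' @param expr an [expression_matrix()].
#' @param clin a [clinical_table()].
#' @return a list with elements `expression` and `clinical`.
#' @export
align_samples <- function(expr, clin) {
  shared <- intersect(colnames(expr), clin$sample_id)
  if (length(shared) == 0)
    abort("no samples shared between expression and clinical data",
          "anchorsig_align_error")
  shared <- colnames(expr)[colnames(expr) %in% shared]
  msg_log(sprintf("aligned %d shared samples (of %d expression, %d clinical)",
                  length(shared), ncol(expr), nrow(clin)))
  clin2 <- clin[match(shared, clin$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expression = expr[, shared, drop = FALSE],
       clinical = clinical_table(as.data.frame(clin2)))
}
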