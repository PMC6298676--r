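#' Expression set container
#'
#' A lightweight container for a log2 expression matrix (rows = probes or
#' genes, columns = samples) together with per-sample metadata. This is the
#' object every pipeline stage consumes and returns.
#'
#' @param values Numeric matrix of log2 intensities; rownames are probe or
#'   gene identifiers, colnames are sample identifiers.
#' @param samples A data.frame with one row per column of \code{values} and
#'   at least the columns \code{sample_id}, \code{dataset_id}, \code{cohort}
#'   (one of \code{"HC"}, \code{"SLE_inactive"}, \code{"SLE_active"}) and
#'   \code{sledai} (non-negative; \code{NA} allowed for healthy controls).
#' @param row_level Either \code{"probe"} or \code{"gene"}; at gene level
#'   duplicate row identifiers are an error.
#'
#' @return An object of class \code{expr_set}: a list with elements
#'   \code{values}, \code{samples}, \code{row_level}.
#' @export
expr_set <- function(values, samples, row_level = c("probe", "gene")) {
  row_level <- match.arg(row_level)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (features) and colnames (samples)")
  }
  if (!all(is.finite(values))) stop("all expression values must be finite")
  if (anyDuplicated(rownames(values))) {
    stop("duplicated row identifiers are not allowed")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "dataset_id", "cohort", "sledai")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) {
    stop("number of metadata rows must equal number of sample columns")
  }
  if (!identical(samples$sample_id, colnames(values))) {
    stop("metadata sample_id must match matrix colnames, in order")
  }
  bad <- !samples$cohort %in% c("HC", "SLE_inactive", "SLE_active")
  if (any(bad)) stop("unknown cohort label(s): ", paste(unique(samples$cohort[bad]), collapse = ", "))
  sled <- samples$sledai
  if (any(!is.na(sled) & sled < 0)) stop("sledai must be non-negative")
  is_sle <- samples$cohort != "HC"
  expected <- ifelse(is_sle,
                     ifelse(ifelse(is.na(sled), 0, sled) < 6, "SLE_inactive", "SLE_active"),
                     "HC")
  if (any(is_sle & samples$cohort != expected[seq_along(is_sle)])) {
    stop("cohort labels inconsistent with SLEDAI activity rule (>= 6 is active)")
  }
  structure(list(values = values, samples = samples, row_level = row_level),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d %ss x %d samples\n",
              nrow(x$values), x$row_level, ncol(x$values)))
  cat("  cohorts:", paste(sprintf("%s=%d", names(table(x$samples$cohort)),
                                  table(x$samples$cohort)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Assign a disease-activity cohort from a SLEDAI score
#'
#' SLE patients with a SLE Disease Activity Index (SLEDAI) below 6 are
#' classified as inactive disease; a score of 6 or greater is active disease.
#' Non-SLE subjects are healthy controls regardless of score.
#'
#' @param sledai Non-negative numeric vector of SLEDAI scores (NA treated as
#'   0 for controls, an error for SLE subjects).
#' @param is_sle Logical vector (recycled): is the subject an SLE patient?
#' @return Character vector with values \code{"HC"}, \code{"SLE_inactive"},
#'   \code{"SLE_active"}.
#' @export
assign_cohort <- function(sledai, is_sle) {
  n <- max(length(sledai), length(is_sle))
  sledai <- rep_len(sledai, n)
  is_sle <- rep_len(as.logical(is_sle), n)
  if (any(is_sle & is.na(sledai))) stop("SLE subjects must have a SLEDAI score")
  if (any(!is.na(sledai) & sledai < 0)) stop("sledai must be non-negative")
  out <- rep("HC", n)
  out[is_sle & sledai < 6] <- "SLE_inactive"
  out[is_sle & sledai >= 6] <- "SLE_active"
  out
}

#' Read an expression matrix and sample metadata from TSV files
#'
#' The expression file is tab-separated with the first row holding sample
#' identifiers and the first column holding row (probe/gene) identifiers.
#' The metadata file has columns \code{sample_id}, \code{dataset_id},
#' \code{cohort}, \code{sledai}. Samples are returned in metadata row order;
#' a matrix column with no metadata row (or vice versa) is an error.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @param row_level \code{"probe"} or \code{"gene"}.
#' @return An \code{\link{expr_set}}.
#' @export
read_expression_tsv <- function(path, metadata_path, row_level = "gene") {
  mat <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, colClasses = "character")
  vals <- suppressWarnings(vapply(mat, as.numeric, numeric(nrow(mat))))
  if (nrow(mat) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(mat)))
  if (any(is.na(vals))) stop("non-numeric expression cell in ", path)
  rownames(vals) <- rownames(mat)
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  missing_meta <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing_meta)) {
    stop("samples absent from metadata: ", paste(missing_meta, collapse = ", "))
  }
  extra_meta <- setdiff(meta$sample_id, colnames(vals))
  if (length(extra_meta)) {
    stop("metadata rows with no matrix column: ", paste(extra_meta, collapse = ", "))
  }
  vals <- vals[, meta$sample_id, drop = FALSE]
  expr_set(vals, meta, row_level = row_level)
}

#' Write an expression set to TSV files
#'
#' Inverse of \code{\link{read_expression_tsv}}: full numeric precision is
#' preserved (values survive a round trip to at least 1e-12).
#'
#' @param eset An \code{expr_set}.
#' @param path Output path for the expression TSV.
#' @param metadata_path Output path for the metadata TSV.
#' @return Invisibly, the two paths.
#' @export
write_expression_tsv <- function(eset, path, metadata_path) {
  stopifnot(inherits(eset, "expr_set"))
  df <- data.frame(row_id = rownames(eset$values),
                   format(eset$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(eset$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, metadata_path))
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated: name, description, then
#' member gene symbols. Duplicate members within a set are deduplicated;
#' duplicate set names or empty member lists are errors.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors, with a \code{"descriptions"}
#'   attribute mapping set name to description.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3L
  if (any(short)) stop("GMT line with fewer than 3 fields at line ", which(short)[1])
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- vapply(sets, length, 0L) == 0L
  if (any(empty)) stop("empty gene set(s) in GMT: ", paste(nm[empty], collapse = ", "))
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(desc, nm)
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character vectors (optionally carrying a
#'   \code{"descriptions"} attribute).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
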