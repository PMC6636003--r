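# quant_matrix: features x samples container for IPM intensities with
# per-run identification counts.

new_quant_matrix <- function(values, id_counts, level,
                             feature_meta = NULL) {
  stopifnot(is.matrix(values), level %in% c("peptide", "protein"))
  if (is.null(id_counts)) {
    id_counts <- matrix(0L, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  }
  stopifnot(identical(dim(values), dim(id_counts)))
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    ms1_abort("duplicate feature or sample ids in quant matrix")
  }
  structure(
    list(values = values, id_counts = id_counts, level = level,
         feature_meta = feature_meta),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> %s level: %d features x %d samples\n",
              x$level, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Tidy a quant matrix into a long tibble
#'
#' @param x A `quant_matrix`.
#' @param ... Unused.
#' @return A tibble with `feature_id`, `sample_id`, `ipm`, `id_count`.
#' @export
tidy.quant_matrix <- function(x, ...) {
  tibble::tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    ipm = as.vector(x$values),
    id_count = as.vector(x$id_counts)
  )
}

#' @export
as_tibble.quant_matrix <- function(x, ...) {
  tibble::as_tibble(cbind(
    tibble::tibble(feature_id = rownames(x$values)),
    tibble::as_tibble(x$values)
  ))
}

#' Write / read a quant matrix as TSV (features x samples)
#'
#' Two files are written: `<stem>.tsv` with the IPM values (first column
#' `feature_id`, one column per run) and `<stem>_id_counts.tsv` with the
#' identification counts in the same layout.
#'
#' @param x A `quant_matrix`.
#' @param stem Path stem (without extension).
#' @param level Quantification level when reading.
#' @return `write_quant_tsv()` returns `stem` invisibly;
#'   `read_quant_tsv()` returns a `quant_matrix`.
#' @export
write_quant_tsv <- function(x, stem) {
  stopifnot(inherits(x, "quant_matrix"))
  wt <- function(m, path) {
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(x$values, paste0(stem, ".tsv"))
  wt(x$id_counts, paste0(stem, "_id_counts.tsv"))
  invisible(stem)
}

#' @rdname write_quant_tsv
#' @export
read_quant_tsv <- function(stem, level = c("peptide", "protein")) {
  level <- match.arg(level)
  rd <- function(path) {
    df <- read.delim(path, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  values <- rd(paste0(stem, ".tsv"))
  id_path <- paste0(stem, "_id_counts.tsv")
  id_counts <- if (file.exists(id_path)) {
    storage_int <- rd(id_path)
    mode(storage_int) <- "integer"
    storage_int
  } else NULL
  new_quant_matrix(values, id_counts, level)
}
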