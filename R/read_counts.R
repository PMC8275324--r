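#' Paired alternate/total read-count matrices
#'
#' The sole observed data: droplet-by-locus matrices of total read counts and
#' alternate (variant) read counts. Rows are droplets, columns are mutation
#' loci; `alt <= total` element-wise and labels must be unique.
#'
#' @param alt,total Non-negative integer matrices of identical shape with
#'   matching dimnames (droplet ids as row names, locus ids as column names).
#'   If `alt` has the same labels in a different order it is realigned to
#'   `total` by label.
#' @return An object of class `read_counts`: a list with `alt`, `total`,
#'   `droplet_ids`, `locus_ids`.
#' @examples
#' tot <- matrix(10L, 2, 3, dimnames = list(c("d1", "d2"), c("A", "B", "C")))
#' alt <- matrix(c(0L, 5L), 2, 3, dimnames = dimnames(tot))
#' read_counts(alt, tot)
#' @export
read_counts <- function(alt, total) {
  alt <- as.matrix(alt)
  total <- as.matrix(total)
  if (is.null(rownames(total)) || is.null(colnames(total))) {
    stop("total counts must carry droplet (row) and locus (column) labels")
  }
  if (anyDuplicated(rownames(total)) || anyDuplicated(colnames(total))) {
    stop("droplet and locus labels must be unique")
  }
  if (!setequal(rownames(alt), rownames(total)) ||
      !setequal(colnames(alt), colnames(total))) {
    stop("alternate and total count matrices carry different labels")
  }
  alt <- alt[rownames(total), colnames(total), drop = FALSE]
  if (!all(dim(alt) == dim(total))) stop("shape mismatch between alt and total")
  if (any(total < 0) || any(alt < 0)) stop("read counts must be non-negative")
  bad <- which(alt > total, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "alt > total at droplet '%s', locus '%s'",
      rownames(total)[bad[1, 1]], colnames(total)[bad[1, 2]]))
  }
  structure(list(alt = alt, total = total,
                 droplet_ids = rownames(total),
                 locus_ids = colnames(total)),
            class = "read_counts")
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf("read_counts: %d droplets x %d loci; median depth %g\n",
              length(x$droplet_ids), length(x$locus_ids),
              stats::median(x$total)))
  invisible(x)
}

#' @export
dim.read_counts <- function(x) dim(x$total)

#' Read paired count matrices from TSV files
#'
#' Each file holds one integer matrix: first column droplet identifiers,
#' header row locus identifiers. Rows and columns of the alternate-count
#' matrix are aligned to the total-count matrix by label, so exports with
#' different orderings are accepted; differing label sets are an error.
#'
#' @param alt_file,total_file Paths to the alternate and total count TSVs.
#' @return A [read_counts] object.
#' @export
read_counts_tsv <- function(alt_file, total_file) {
  read_one <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
    as.matrix(df)
  }
  read_counts(read_one(alt_file), read_one(total_file))
}

#' Write a labelled matrix as TSV
#'
#' Inverse of the format accepted by [read_counts_tsv()]: first column
#' `droplet_id`, remaining columns one per locus.
#'
#' @param mat Matrix with droplet row names and locus column names.
#' @param path Output file path.
#' @param id_col Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "droplet_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
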