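#' OTU count tables
#'
#' An `otu_table` is a nonnegative integer matrix of counts with taxa as rows
#' and samples as columns, plus unique row (taxon) and column (sample) labels.
#' It is the container every pipeline stage consumes.
#'
#' @param counts numeric matrix of nonnegative integers, taxa x samples, with
#'   unique `rownames` (taxon ids) and `colnames` (sample ids).
#' @return An object of class `otu_table` (a validated integer matrix).
#' @examples
#' tab <- otu_table(matrix(1:4, 2, 2,
#'   dimnames = list(c("t1", "t2"), c("s1", "s2"))))
#' taxon_ids(tab)
#' @export
otu_table <- function(counts) {
  counts <- as.matrix(counts)
  # zero-extent dimensions legitimately carry no names
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("otu_table requires taxon rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and non-missing", call. = FALSE)
  if (any(counts < 0))
    stop("negative count at row ", which(counts < 0, arr.ind = TRUE)[1, 1],
         call. = FALSE)
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-integer count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d taxa x %d samples, total count %s\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' @rdname otu_table
#' @param x an `otu_table`.
#' @export
taxon_ids <- function(x) rownames(x)

#' @rdname otu_table
#' @export
sample_ids <- function(x) colnames(x)

#' Test or coerce to `otu_table`
#' @param x a matrix-like object with dimnames.
#' @export
as_otu_table <- function(x) {
  if (inherits(x, "otu_table")) x else otu_table(x)
}

#' Read an OTU table
#'
#' Two dialects are supported: `"tsv"` (first row sample ids, first column
#' taxon ids, integer cells) and `"biom_json"` (BIOM v1.0 JSON, dense or
#' sparse). Row and column ordering from the file is preserved.
#'
#' @param path path to the file.
#' @param dialect one of `"tsv"`, `"biom_json"`.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, dialect = c("tsv", "biom_json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                            check.names = FALSE, colClasses = "character",
                            comment.char = "", quote = "")
    # [.data.frame silently uniquifies duplicate names; check the header
    if (anyDuplicated(names(df)[-1]))
      stop("duplicate sample ids in header: ",
           paste(unique(names(df)[-1][duplicated(names(df)[-1])]),
                 collapse = ", "), call. = FALSE)
    taxa <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    if (anyNA(num) || any(num != round(num))) {
      bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)[1, ]
      stop(sprintf("non-integer cell at taxon '%s', sample '%s'",
                   taxa[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
    }
    dimnames(num) <- list(taxa, colnames(m))
    otu_table(num)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("biomformat is required for the biom_json dialect", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    # biomformat's dimnames are unreliable for degenerate shapes; the BIOM
    # row/column ids are authoritative
    row_ids <- vapply(b$rows, function(r) r$id, "")
    col_ids <- vapply(b$columns, function(r) r$id, "")
    if (!all(dim(m) == c(length(row_ids), length(col_ids))))
      stop("BIOM shape does not match row/column ids", call. = FALSE)
    dimnames(m) <- list(row_ids, col_ids)
    otu_table(m)
  }
}

#' Write an OTU table as TSV
#'
#' Inverse of [read_otu_table()] for the tsv dialect; integer counts
#' round-trip exactly.
#'
#' @param x an [otu_table].
#' @param path output path.
#' @export
write_otu_table <- function(x, path) {
  x <- as_otu_table(x)
  df <- data.frame(otu_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or validate sample metadata
#'
#' Metadata maps each sample to a community type (`leaf`, `root`, `water`,
#' `sediment`), a seagrass bed, and the site (spatial block) the bed nests in.
#'
#' @param path tab-separated file with columns `sample_id`, `community_type`,
#'   `bed_id`, `site_id`.
#' @return a `data.frame` with those four character columns.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param metadata a data.frame to validate.
#' @export
validate_sample_metadata <- function(metadata) {
  need <- c("sample_id", "community_type", "bed_id", "site_id")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  bad <- setdiff(unique(metadata$community_type),
                 c("leaf", "root", "water", "sediment"))
  if (length(bad))
    stop("unknown community_type: ", paste(bad, collapse = ", "),
         call. = FALSE)
  # each bed must sit inside exactly one site
  tab <- unique(metadata[, c("bed_id", "site_id")])
  if (anyDuplicated(tab$bed_id))
    stop("bed_id assigned to multiple site_id values", call. = FALSE)
  metadata
}
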