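#' Read and write pipeline file formats
#'
#' Plain-text interchange used across the pipeline: plate wells CSV,
#' long-format confluence CSV, expression matrices as GCT v1.2 or CSV,
#' gene sets as GMT, and truth/parameter records as YAML sidecars.
#'
#' @name dsrt-io
NULL

#' @rdname dsrt-io
#' @param wells plate wells data.frame (see \code{\link{gen_plate}})
#' @param path output / input file path
#' @export
write_plate_csv <- function(wells, path) {
  utils::write.csv(wells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname dsrt-io
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("plate_id", "well", "role", "compound", "concentration_nM",
              "cell_line", "signal")
  if (!all(needed %in% names(df))) {
    stop("plate CSV is missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df
}

#' @rdname dsrt-io
#' @param curves long confluence data.frame (see \code{\link{gen_growth_curves}})
#' @export
write_confluence_csv <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' @rdname dsrt-io
#' @export
read_confluence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_line", "compound", "concentration_nM", "replicate",
              "time_h", "confluence_pct")
  if (!all(needed %in% names(df))) {
    stop("confluence CSV is missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df
}

#' @rdname dsrt-io
#' @param mat numeric matrix, genes in rows (rownames), samples in columns
#' @param description optional per-gene description column for GCT output
#' @export
write_gct <- function(mat, path, description = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (is.null(description)) description <- rep("na", nrow(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  df <- data.frame(Name = rownames(mat), Description = description,
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dsrt-io
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2)
  if (header[1] != "#1.2") stop("not a GCT v1.2 file: ", path)
  dims <- as.integer(strsplit(header[2], "\t")[[1]])
  df <- utils::read.delim(path, skip = 2, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) != dims[1]) stop("GCT row count does not match its header")
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(mat) <- df$Name
  storage.mode(mat) <- "double"
  mat
}

#' @rdname dsrt-io
#' @param sets named list of character vectors
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname dsrt-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    if (length(parts) < 3) stop("GMT line has fewer than 3 fields")
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                        character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname dsrt-io
#' @param x list-like record (truth parameters, run configuration)
#' @export
write_truth_yaml <- function(x, path) {
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname dsrt-io
#' @export
read_truth_yaml <- function(path) {
  yaml::read_yaml(path)
}
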