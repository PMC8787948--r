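#' File readers and writers
#'
#' All genomic interval files use BED conventions: tab-separated, no header,
#' 0-based half-open coordinates. Internally intervals are held as
#' [GenomicRanges::GRanges] (1-based closed); these functions perform the
#' conversion at the boundary. Gzipped input is read transparently.
#'
#' @param path File to read or write.
#' @param minCols Minimum number of required BED columns.
#'
#' @return `readBed()` returns a `GRanges` with metadata columns `name` and
#'   `score` when the corresponding BED columns are present.
#' @name io
NULL

#' @rdname io
#' @export
#' @importFrom data.table fread fwrite as.data.table
readBed <- function(path, minCols = 3L) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "r")
      on.exit(close(con))
      lines <- readLines(con)
      if (!length(lines)) data.table::data.table()
      else data.table::fread(text = lines, header = FALSE, sep = "\t",
                             fill = TRUE)
    } else {
      data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
    }
  }, error = function(e) stop("failed to parse BED file ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  if (nrow(dt) == 0L) {
    return(GRanges())
  }
  if (ncol(dt) < minCols)
    stop(sprintf("%s: expected at least %d BED columns, found %d",
                 path, minCols, ncol(dt)))
  start0 <- dt[[2L]]
  end0 <- dt[[3L]]
  if (!is.numeric(start0) || !is.numeric(end0)) {
    bad <- which(is.na(suppressWarnings(as.numeric(dt[[2L]]))) |
                 is.na(suppressWarnings(as.numeric(dt[[3L]]))))[1L]
    stop(sprintf("%s: non-numeric coordinates at line %d", path, bad))
  }
  bad <- which(end0 <= start0)
  if (length(bad))
    stop(sprintf("%s: end <= start at line %d (start=%s, end=%s)",
                 path, bad[1L], start0[bad[1L]], end0[bad[1L]]))
  gr <- GRanges(as.character(dt[[1L]]),
                IRanges(as.integer(start0) + 1L, as.integer(end0)))
  if (ncol(dt) >= 4L) mcols(gr)$name <- as.character(dt[[4L]])
  if (ncol(dt) >= 5L) mcols(gr)$score <- as.numeric(dt[[5L]])
  gr
}

#' @rdname io
#' @param gr Intervals to write.
#' @param format One of `"bed3"`, `"bed5"`, `"bed6"`. BED5 writes
#'   `name`/`score` metadata columns; BED6 additionally writes strand.
#' @export
writeBed <- function(gr, path, format = c("bed3", "bed5", "bed6")) {
  format <- match.arg(format)
  dt <- data.table::data.table(chrom = as.character(seqnames(gr)),
                               start = start(gr) - 1L,
                               end = end(gr))
  if (format %in% c("bed5", "bed6")) {
    nm <- mcols(gr)$name
    if (is.null(nm)) nm <- if (!is.null(names(gr))) names(gr) else
      paste0("feature_", seq_along(gr))
    sc <- mcols(gr)$score
    if (is.null(sc)) sc <- 0
    dt$name <- nm
    dt$score <- sc
  }
  if (format == "bed6") dt$strand <- rep(".", length(gr))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readChromSizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2L || !is.numeric(dt[[2L]]))
    stop(path, ": chrom.sizes must have columns <name>\\t<length>")
  sizes <- as.integer(dt[[2L]])
  names(sizes) <- as.character(dt[[1L]])
  if (anyDuplicated(names(sizes))) stop(path, ": duplicate chromosome names")
  if (any(sizes <= 0L)) stop(path, ": non-positive chromosome length")
  sizes
}

#' @rdname io
#' @export
writeChromSizes <- function(sizes, path) {
  data.table::fwrite(data.table::data.table(names(sizes), as.integer(sizes)),
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readSampleSheet <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = 1:2))
  req <- c("sample_id", "group")
  if (!all(req %in% colnames(dt)))
    stop(path, ": sample sheet must have columns sample_id and group")
  df <- as.data.frame(dt)
  if (anyDuplicated(df$sample_id))
    stop(path, ": duplicate sample ids")
  if (nrow(df) && !all(df$group %in% c("cancer", "healthy")))
    stop(path, ": group must be 'cancer' or 'healthy'")
  df
}

#' @rdname io
#' @param x A samples x features numeric matrix with dimnames.
#' @export
writeTsvMatrix <- function(x, path) {
  dt <- data.table::as.data.table(x, keep.rownames = "sample_id")
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readTsvMatrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (colnames(dt)[1L] != "sample_id")
    stop(path, ": first column must be 'sample_id'")
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) stop(path, ": duplicate sample ids")
  m <- as.matrix(dt[, -1L])
  rownames(m) <- ids
  m
}
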