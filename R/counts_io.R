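# The methylation count-table container and its on-disk TSV dialect:
# columns chrom, pos (1-based), strand, context, then one "meth,total"
# column per sample. Sample annotation travels in a separate TSV.

#' Construct a methylation count table
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `strand`,
#'   `context` (`"CpG"`/`"CpH"`); site keys must be unique on
#'   (chrom, pos, strand).
#' @param meth,total Integer matrices (sites x samples) of methylated and
#'   total read counts, with sample ids as column names;
#'   `0 <= meth <= total` cell-wise.
#' @return An object of class `meth_counts`.
#' @export
meth_counts <- function(sites, meth, total) {
  need <- c("chrom", "pos", "strand", "context")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    stop_invalid("sites must be a data.frame with columns ",
                 paste(need, collapse = ", "))
  if (!all(sites$context %in% c("CpG", "CpH")))
    stop_invalid("context must be 'CpG' or 'CpH'")
  key <- paste(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(key))
    stop_invalid("duplicate site key (chrom, pos, strand)")
  if (!is.matrix(meth) || !is.matrix(total) ||
      !identical(dim(meth), dim(total)) || nrow(meth) != nrow(sites))
    stop_invalid("meth and total must be matrices of dimension sites x samples")
  if (is.null(colnames(meth)))
    stop_invalid("count matrices need sample ids as column names")
  if (any(meth < 0) || any(total < 0) || any(meth > total))
    stop_invalid("counts must satisfy 0 <= meth <= total in every cell")
  structure(list(sites = sites, meth = meth, total = total),
            class = "meth_counts")
}

#' @export
print.meth_counts <- function(x, ...) {
  cat("meth_counts: ", nrow(x$sites), " sites x ", ncol(x$meth), " samples (",
      sum(x$sites$context == "CpG"), " CpG, ",
      sum(x$sites$context == "CpH"), " CpH)\n", sep = "")
  invisible(x)
}

#' Write / read a methylation count table as TSV
#'
#' One row per site; the first four columns are `chrom`, `pos`, `strand`,
#' `context`, followed by one `"meth,total"` pair per sample.
#' `read_count_table(write_count_table(x, path))` round-trips exactly.
#'
#' @param counts A `meth_counts` object.
#' @param path File path.
#' @return `write_count_table` returns `path` invisibly; `read_count_table`
#'   returns a `meth_counts`.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(inherits(counts, "meth_counts"))
  samp <- colnames(counts$meth)
  header <- paste(c("chrom", "pos", "strand", "context", samp), collapse = "\t")
  cells <- matrix(paste0(counts$meth, ",", counts$total),
                  nrow = nrow(counts$meth))
  body <- do.call(paste, c(
    list(counts$sites$chrom, counts$sites$pos, counts$sites$strand,
         counts$sites$context),
    lapply(seq_along(samp), function(j) cells[, j]),
    sep = "\t"
  ))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  if (!file.exists(path))
    stop_invalid("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "context")
  if (!all(need %in% names(raw)))
    stop_invalid("malformed count table header in ", path,
                 ": need columns ", paste(need, collapse = ", "))
  samp <- setdiff(names(raw), need)
  S <- nrow(raw)
  sites <- data.frame(chrom = raw$chrom, pos = as.integer(raw$pos),
                      strand = raw$strand, context = raw$context,
                      stringsAsFactors = FALSE)
  if (any(is.na(sites$pos)))
    stop_invalid("parse error in ", path, " at row ",
                 which(is.na(sites$pos))[1], ": non-integer position")
  meth <- total <- matrix(0L, nrow = S, ncol = length(samp),
                          dimnames = list(NULL, samp))
  for (j in seq_along(samp)) {
    parts <- strsplit(raw[[samp[j]]], ",", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad))
      stop_invalid("parse error in ", path, " at row ", bad[1],
                   ", sample ", samp[j], ": expected 'meth,total'")
    m <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1)))
    t <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
    bad <- which(is.na(m) | is.na(t) | m < 0 | t < 0 | m > t)
    if (length(bad))
      stop_invalid("parse error in ", path, " at row ", bad[1],
                   ", sample ", samp[j],
                   ": counts must satisfy 0 <= meth <= total")
    meth[, j] <- m; total[, j] <- t
  }
  meth_counts(sites = sites, meth = meth, total = total)
}

#' Write / read a sample annotation table as TSV
#'
#' Columns: `sample`, `mouse`, `segment` (1-9), `age`, `diet`, `sex`.
#'
#' @param annot data.frame of sample annotation.
#' @param path File path.
#' @export
write_sample_annotation <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_annotation
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path))
    stop_invalid("file not found: ", path)
  annot <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "mouse", "segment") %in% names(annot)))
    stop_invalid("malformed annotation in ", path,
                 ": need columns sample, mouse, segment")
  if (!all(annot$segment %in% 1:9))
    stop_invalid("annotation in ", path, ": segment must be in 1..9")
  annot
}

#' Write intervals as BED6
#'
#' Converts 1-based inclusive `start`/`end` coordinates to BED's 0-based
#' half-open convention. Used both for planted-cluster truth sets and for
#' called clusters.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive) and optionally `name`, `score`, `strand`.
#' @param path File path.
#' @export
write_bed6 <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else
    if ("cluster_id" %in% names(x)) x$cluster_id else
    if ("label" %in% names(x)) x$label else "."
  score <- if ("score" %in% names(x)) x$score else 0L
  strand <- if ("strand" %in% names(x)) x$strand else "."
  lines <- paste(x$chrom, x$start - 1L, x$end, name, score, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
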