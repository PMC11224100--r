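#' Build a fixed-width genomic bin lattice
#'
#' Tiles each chromosome left to right with non-overlapping, 0-based
#' half-open intervals of width `bin_size`. A trailing partial bin is kept
#' (so indices stay aligned with external annotation) but is masked when it
#' is shorter than half a bin.
#'
#' @param chrom_sizes Named numeric vector or list, chromosome -> length in bp.
#' @param bin_size Bin width in bp. Default 500 kb, the resolution at which
#'   low-pass WGS read counts carry copy-number signal.
#' @return A `bin_grid`: a data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, `centromere`, `mask` and attribute `bin_size`. `gc` is `NA` until
#'   annotated (see [read_bin_table()] or the simulator). Chromosomes are
#'   sorted by name so grid construction is independent of input order.
#' @examples
#' grid <- make_bin_grid(c(chr1 = 1.5e6), bin_size = 5e5)
#' nrow(grid)  # 3
#' @export
make_bin_grid <- function(chrom_sizes, bin_size = 500000L) {
  chrom_sizes <- unlist(chrom_sizes)
  if (length(chrom_sizes) == 0L) stop("no chromosomes")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chromosome sizes must be named")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  if (bin_size <= 0) stop("bin_size must be positive")
  chrom_sizes <- chrom_sizes[order(names(chrom_sizes))]

  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    data.frame(
      chrom = ch, start = starts, end = ends,
      gc = NA_real_, centromere = FALSE,
      mask = (ends - starts) < bin_size / 2,
      stringsAsFactors = FALSE
    )
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  attr(grid, "bin_size") <- as.numeric(bin_size)
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf(
    "bin_grid: %d bins of %s bp on %d chromosome(s); %d masked, %d centromeric\n",
    nrow(x), format(attr(x, "bin_size"), big.mark = ","),
    length(unique(x$chrom)), sum(x$mask), sum(x$centromere)
  ))
  invisible(x)
}

validate_bin_grid <- function(grid) {
  stopifnot(is.data.frame(grid))
  need <- c("chrom", "start", "end", "gc", "centromere", "mask")
  if (!all(need %in% names(grid)))
    stop("bin grid lacks columns: ", paste(setdiff(need, names(grid)), collapse = ", "))
  ord <- order(grid$chrom, grid$start)
  if (!identical(ord, seq_len(nrow(grid)))) stop("bin grid is not sorted by (chrom, start)")
  if (any(grid$end <= grid$start)) stop("bin grid has empty or inverted intervals")
  bad_gc <- !grid$mask & !is.na(grid$gc) & (grid$gc < 0 | grid$gc > 1)
  if (any(bad_gc)) stop("unmasked bins with gc outside [0,1]")
  invisible(grid)
}

#' Count aligned read starts in genomic bins
#'
#' Each read is assigned to the unique half-open bin containing its 0-based
#' start position. Reads on chromosomes absent from the grid are dropped and
#' counted in the `dropped` attribute.
#'
#' @param read_starts data.frame with columns `chrom` and `pos` (0-based).
#' @param grid A `bin_grid` from [make_bin_grid()].
#' @return A `bin_counts` object: list with `sample_id`, integer `counts`
#'   aligned index-for-index with `grid`, `total_reads`, and `dropped`.
#' @param sample_id Label carried through to outputs.
#' @export
count_reads_in_bins <- function(read_starts, grid, sample_id = "sample") {
  validate_bin_grid(grid)
  stopifnot(is.data.frame(read_starts), all(c("chrom", "pos") %in% names(read_starts)))
  if (nrow(read_starts) > 0 && any(read_starts$pos < 0))
    stop("negative read position")

  counts <- integer(nrow(grid))
  dropped <- 0L
  for (ch in unique(read_starts$chrom)) {
    pos <- read_starts$pos[read_starts$chrom == ch]
    idx <- which(grid$chrom == ch)
    if (length(idx) == 0L) {
      dropped <- dropped + length(pos)
      next
    }
    # bins tile the chromosome contiguously: locate by start coordinate
    j <- findInterval(pos, grid$start[idx])
    off <- j < 1L | pos >= grid$end[idx][pmax(j, 1L)]
    dropped <- dropped + sum(off)
    tab <- tabulate(j[!off], nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  if (dropped > 0L)
    message(dropped, " read(s) outside the bin grid were dropped")
  bin_counts(counts, sample_id = sample_id, dropped = dropped)
}

#' Construct a bin-counts object
#'
#' @param counts Non-negative integer vector, one entry per grid bin.
#' @param sample_id Sample label.
#' @param dropped Reads not assignable to any bin (bookkeeping only).
#' @return A `bin_counts` list with fields `sample_id`, `counts`,
#'   `total_reads`, `dropped`.
#' @export
bin_counts <- function(counts, sample_id = "sample", dropped = 0L) {
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  structure(
    list(sample_id = sample_id, counts = as.integer(round(counts)),
         total_reads = sum(counts), dropped = as.integer(dropped)),
    class = "bin_counts"
  )
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("bin_counts '%s': %d bins, %s reads (%d dropped)\n",
              x$sample_id, length(x$counts),
              format(x$total_reads, big.mark = ","), x$dropped))
  invisible(x)
}

#' Read a bin table (TSV or fixedStep WIG)
#'
#' The TSV dialect carries the full grid annotation with header
#' `chrom start end gc centromere count`. The WIG dialect (fixedStep with
#' `step == span == bin_size`) carries counts only; coordinates are rebuilt
#' from the headers and `gc`/`centromere` are left unannotated.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"wig"`.
#' @param bin_size Expected bin width (validated against the file).
#' @param sample_id Sample label for the returned counts.
#' @return list(grid = bin_grid, counts = bin_counts)
#' @export
read_bin_table <- function(path, dialect = c("tsv", "wig"),
                           bin_size = 500000L, sample_id = "sample") {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") read_bin_tsv(path, bin_size, sample_id)
  else read_bin_wig(path, bin_size, sample_id)
}

read_bin_tsv <- function(path, bin_size, sample_id) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("bin table has no data rows: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("chrom", "start", "end", "gc", "centromere", "count")
  if (!identical(header, need))
    stop("bad TSV header, expected ", paste(need, collapse = "\t"))
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  n_fields <- lengths(rows)
  if (any(n_fields != 6L))
    stop("ragged row at line ", which(n_fields != 6L)[1L] + 1L)
  m <- do.call(rbind, rows)
  num <- function(col, what, line_off = 1L) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) stop("non-numeric ", what, " at line ", which(is.na(v))[1L] + line_off)
    v
  }
  start <- num(2L, "start"); end <- num(3L, "end")
  gc <- num(4L, "gc"); cen <- num(5L, "centromere"); count <- num(6L, "count")
  bad <- which(count != round(count) | count < 0)
  if (length(bad)) stop("non-integer count at line ", bad[1L] + 1L)
  grid <- data.frame(chrom = m[, 1L], start = start, end = end,
                     gc = gc, centromere = cen != 0,
                     mask = (end - start) < bin_size / 2,
                     stringsAsFactors = FALSE)
  ord <- order(grid$chrom, grid$start)
  if (!identical(ord, seq_len(nrow(grid)))) stop("bins are not sorted by (chrom, start)")
  grid$mask <- grid$mask | is.na(grid$gc) | grid$gc < 0 | grid$gc > 1
  attr(grid, "bin_size") <- as.numeric(bin_size)
  class(grid) <- c("bin_grid", "data.frame")
  validate_bin_grid(grid)
  list(grid = grid, counts = bin_counts(count, sample_id = sample_id))
}

read_bin_wig <- function(path, bin_size, sample_id) {
  lines <- readLines(path)
  chrom <- character(0); start <- numeric(0); count <- numeric(0)
  cur_chrom <- NULL; cur_pos <- NA_real_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "track")) next
    if (startsWith(ln, "fixedStep")) {
      kv <- strsplit(strsplit(ln, "\\s+")[[1L]][-1L], "=", fixed = TRUE)
      pars <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
      if (!all(c("chrom", "start", "step") %in% names(pars)))
        stop("malformed fixedStep header at line ", i)
      step <- as.numeric(pars[["step"]])
      span <- if ("span" %in% names(pars)) as.numeric(pars[["span"]]) else 1
      if (step != bin_size || span != bin_size)
        stop("fixedStep step/span must equal bin_size at line ", i)
      cur_chrom <- pars[["chrom"]]
      cur_pos <- as.numeric(pars[["start"]]) - 1  # WIG is 1-based
    } else {
      if (is.null(cur_chrom)) stop("data before fixedStep header at line ", i)
      v <- suppressWarnings(as.numeric(ln))
      if (is.na(v) || v != round(v) || v < 0)
        stop("non-integer count at line ", i)
      chrom <- c(chrom, cur_chrom); start <- c(start, cur_pos); count <- c(count, v)
      cur_pos <- cur_pos + bin_size
    }
  }
  if (length(count) == 0L) stop("no data rows in WIG: ", path)
  grid <- data.frame(chrom = chrom, start = start, end = start + bin_size,
                     gc = NA_real_, centromere = FALSE, mask = FALSE,
                     stringsAsFactors = FALSE)
  ord <- order(grid$chrom, grid$start)
  grid <- grid[ord, , drop = FALSE]
  rownames(grid) <- NULL
  attr(grid, "bin_size") <- as.numeric(bin_size)
  class(grid) <- c("bin_grid", "data.frame")
  validate_bin_grid(grid)
  list(grid = grid, counts = bin_counts(count[ord], sample_id = sample_id))
}

#' Write a bin table
#'
#' Inverse of [read_bin_table()]: a TSV write followed by a read reproduces
#' coordinates and counts exactly.
#'
#' @inheritParams read_bin_table
#' @param grid,counts The grid and counts to serialize.
#' @export
write_bin_table <- function(grid, counts, path, dialect = c("tsv", "wig")) {
  dialect <- match.arg(dialect)
  validate_bin_grid(grid)
  stopifnot(length(counts$counts) == nrow(grid))
  if (dialect == "tsv") {
    df <- data.frame(chrom = grid$chrom, start = fmt_num(grid$start),
                     end = fmt_num(grid$end), gc = ifelse(is.na(grid$gc), "NA", format(grid$gc, digits = 10)),
                     centromere = as.integer(grid$centromere),
                     count = counts$counts)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bs <- attr(grid, "bin_size")
    con <- file(path, "w"); on.exit(close(con))
    for (ch in unique(grid$chrom)) {
      idx <- which(grid$chrom == ch & (grid$end - grid$start) == bs)
      writeLines(sprintf("fixedStep chrom=%s start=%s step=%s span=%s",
                         ch, fmt_num(grid$start[idx[1L]] + 1), fmt_num(bs), fmt_num(bs)), con)
      writeLines(as.character(counts$counts[idx]), con)
    }
  }
  invisible(path)
}

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read 0-based read-start positions from a 2-column BED-like file
#'
#' @param path Tab-separated file: chromosome, 0-based position.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
read_read_starts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) > 0 && any(df$pos < 0)) stop("negative read position")
  df
}
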