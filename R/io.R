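read_table_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a BED file
#'
#' Parses BED3/BED6 (tab-separated, `#` comments skipped) into a 0-based
#' half-open interval data frame. Malformed lines and empty intervals
#' (`start >= end`) are errors that name the offending line.
#'
#' @param path Path to a BED file.
#' @return Interval data frame with `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand` columns.
#' @export
read_bed <- function(path) {
  tl <- read_table_lines(path)
  if (length(tl$lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  fields <- split_fields(tl$lines)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("%s line %d: expected >= 3 tab-separated columns",
                 path, tl$lineno[which(nf < 3L)[1]]))
  ncol <- max(nf)
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
           character(1))
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("%s line %d: non-numeric coordinates", path, tl$lineno[bad[1]]))
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop(sprintf("%s line %d: requires 0 <= start < end", path, tl$lineno[bad[1]]))
  df <- data.frame(chrom = get(1), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (ncol >= 4L) df$name <- get(4, default = ".")
  if (ncol >= 5L) df$score <- suppressWarnings(as.numeric(get(5, default = "0")))
  if (ncol >= 6L) {
    df$strand <- get(6, default = ".")
    if (!all(df$strand %in% c("+", "-", ".")))
      stop(path, ": strand column must be '+', '-' or '.'")
  }
  df
}

#' Write intervals as BED
#'
#' Writes BED3, or BED6 when `name`/`score`/`strand` columns are present
#' (missing optional columns are filled with `.`/`0`).
#'
#' @param df Interval data frame.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  cols <- list(df$chrom, format_coord(df$start), format_coord(df$end))
  extra <- c("name", "score", "strand") %in% names(df)
  if (any(extra)) {
    cols <- c(cols, list(
      if (is.null(df$name)) rep(".", nrow(df)) else df$name,
      if (is.null(df$score)) rep("0", nrow(df)) else format_num(df$score),
      if (is.null(df$strand)) rep(".", nrow(df)) else df$strand))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
format_num <- function(x) formatC(x, format = "g", digits = 10)

#' Read a bedGraph file into a binned signal track
#'
#' Records are rebinned to `bin_size` by length-weighted averaging; bases not
#' covered by any record contribute zero. Overlapping records are rejected as
#' ambiguous signal.
#'
#' @param path Path to a 4-column bedGraph file.
#' @param bin_size Target bin width in bp (default 50).
#' @param chrom_sizes Optional named chromosome lengths; defaults to the last
#'   covered coordinate per chromosome rounded up to a full bin.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, bin_size = 50L, chrom_sizes = NULL) {
  tl <- read_table_lines(path)
  fields <- split_fields(tl$lines)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("%s line %d: bedGraph requires 4 columns",
                 path, tl$lineno[which(nf < 4L)[1]]))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  df <- data.frame(chrom = get(1),
                   start = suppressWarnings(as.numeric(get(2))),
                   end = suppressWarnings(as.numeric(get(3))),
                   value = suppressWarnings(as.numeric(get(4))),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value))
  if (length(bad))
    stop(sprintf("%s line %d: non-numeric field", path, tl$lineno[bad[1]]))
  validate_intervals(df, what = paste0(path, " record"))
  bedgraph_to_track(df, bin_size, chrom_sizes)
}

#' Build a signal track from bedGraph-style records
#'
#' @param df Data frame with `chrom`, `start`, `end`, `value`.
#' @inheritParams read_bedgraph
#' @return A [signal_track()].
#' @export
bedgraph_to_track <- function(df, bin_size = 50L, chrom_sizes = NULL) {
  bs <- as.integer(bin_size)
  stopifnot(bs >= 1)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(split(df$end, df$chrom), max, numeric(1))
    chrom_sizes <- ceiling(chrom_sizes / bs) * bs
  }
  values <- list()
  for (ch in names(chrom_sizes)) {
    n <- ceiling(chrom_sizes[[ch]] / bs)
    acc <- numeric(n)
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub)) {
      o <- order(sub$start)
      sub <- sub[o, , drop = FALSE]
      if (any(sub$start[-1] < sub$end[-nrow(sub)]))
        stop("overlapping bedGraph records on ", ch, ": ambiguous signal")
      if (max(sub$end) > n * bs)
        stop("record beyond chromosome end on ", ch)
      s <- sub$start; e <- sub$end; v <- sub$value
      i0 <- floor(s / bs); i1 <- ceiling(e / bs) - 1
      single <- i0 == i1
      add <- function(idx, amt) {
        t <- tapply(amt, idx, sum)
        acc[as.integer(names(t)) + 1L] <<- acc[as.integer(names(t)) + 1L] + t
      }
      if (any(single)) add(i0[single], v[single] * (e[single] - s[single]))
      if (any(!single)) {
        m <- which(!single)
        add(i0[m], v[m] * ((i0[m] + 1) * bs - s[m]))
        add(i1[m], v[m] * (e[m] - i1[m] * bs))
        nmid <- i1[m] - i0[m] - 1L
        has <- nmid > 0L
        if (any(has)) {
          mids <- sequence(nmid[has], from = i0[m][has] + 1L)
          add(mids, rep(v[m][has] * bs, nmid[has]))
        }
      }
    }
    values[[ch]] <- acc / bs
  }
  signal_track(values, bs, chrom_sizes)
}

#' Write a signal track as bedGraph
#'
#' Adjacent equal-valued bins are collapsed into single records; zero-valued
#' runs are omitted.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @param digits Significant digits for values (fixed for reproducible files).
#' @export
write_bedgraph <- function(track, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths) * bs
    starts <- ends - r$lengths * bs
    keep <- r$values != 0
    if (!any(keep)) next
    ends <- pmin(ends, track$chrom_sizes[[ch]])
    writeLines(paste(ch, format_coord(starts[keep]), format_coord(ends[keep]),
                     formatC(r$values[keep], format = "g", digits = digits),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' Five tab-separated columns: chrom, start, end, gene_id, strand (0-based
#' half-open; `#` comments skipped). TSS/TTS are derived from strand: on `+`
#' the TSS is `start`, on `-` it is `end`.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with `chrom`, `start`, `end`, `gene_id`, `strand`,
#'   `tss`, `tts`.
#' @export
read_gene_annotation <- function(path) {
  tl <- read_table_lines(path)
  fields <- split_fields(tl$lines)
  nf <- lengths(fields)
  if (any(nf < 5L))
    stop(sprintf("%s line %d: annotation requires 5 columns",
                 path, tl$lineno[which(nf < 5L)[1]]))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  df <- data.frame(chrom = get(1),
                   start = as.numeric(get(2)), end = as.numeric(get(3)),
                   gene_id = get(4), strand = get(5),
                   stringsAsFactors = FALSE)
  validate_intervals(df, what = paste0(path, " gene"))
  if (!all(df$strand %in% c("+", "-")))
    stop(path, ": gene strand must be '+' or '-'")
  if (anyDuplicated(df$gene_id)) stop(path, ": duplicated gene_id")
  add_tss_tts(df)
}

add_tss_tts <- function(df) {
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tts <- ifelse(df$strand == "+", df$end, df$start)
  df
}

#' Write a gene annotation table
#' @param genes Annotation data frame (see [read_gene_annotation()]).
#' @param path Output path.
#' @export
write_gene_annotation <- function(genes, path) {
  writeLines(paste(genes$chrom, format_coord(genes$start),
                   format_coord(genes$end), genes$gene_id, genes$strand,
                   sep = "\t"), path)
  invisible(path)
}

#' Read per-CpG methylation records from bedGraph
#'
#' Column 4 is the methylation level in `[0, 1]`; an optional column 5 gives
#' read coverage. The site position is the record start.
#'
#' @param path Path to the methylation bedGraph.
#' @return Data frame with `chrom`, `pos`, `level`, `coverage` (NA when
#'   absent), sorted by chromosome and position.
#' @export
read_methylation <- function(path) {
  tl <- read_table_lines(path)
  fields <- split_fields(tl$lines)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("%s line %d: methylation bedGraph requires 4 columns",
                 path, tl$lineno[which(nf < 4L)[1]]))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  df <- data.frame(chrom = get(1), pos = as.numeric(get(2)),
                   level = as.numeric(get(4)),
                   coverage = if (min(nf) >= 5L) as.numeric(get(5)) else NA_real_,
                   stringsAsFactors = FALSE)
  if (any(df$level < 0 | df$level > 1, na.rm = TRUE))
    stop(path, ": methylation levels must be in [0, 1]")
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Write methylation records as bedGraph
#' @param records Data frame with `chrom`, `pos`, `level`, optionally
#'   `coverage`.
#' @param path Output path.
#' @export
write_methylation <- function(records, path) {
  lines <- paste(records$chrom, format_coord(records$pos),
                 format_coord(records$pos + 1),
                 formatC(records$level, format = "g", digits = 6), sep = "\t")
  if (!is.null(records$coverage) && !all(is.na(records$coverage)))
    lines <- paste(lines, format_coord(records$coverage), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-condition gene count table
#'
#' Tab-separated with header `gene_id`, `count_a`, `count_b`. Library sizes
#' default to the column sums.
#'
#' @param path Path to the TSV.
#' @param lib_a,lib_b Optional externally supplied library sizes (> 0).
#' @return A list with `gene_id`, `count_a`, `count_b`, `lib_a`, `lib_b`.
#' @export
read_count_table <- function(path, lib_a = NULL, lib_b = NULL) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*lib_a=([0-9.eE+]+)\\s+lib_b=([0-9.eE+]+)", first))[[1]]
  if (length(m) == 3L) {
    if (is.null(lib_a)) lib_a <- as.numeric(m[2])
    if (is.null(lib_b)) lib_b <- as.numeric(m[3])
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "count_a", "count_b")
  if (!all(need %in% names(df)))
    stop(path, ": count table needs columns gene_id, count_a, count_b")
  count_table(df$gene_id, df$count_a, df$count_b, lib_a, lib_b)
}

#' Construct a two-condition count table
#' @param gene_id Character vector of gene ids.
#' @param count_a,count_b Non-negative integer counts per gene.
#' @param lib_a,lib_b Library sizes (> 0); default to `sum(count_a)` /
#'   `sum(count_b)`.
#' @export
count_table <- function(gene_id, count_a, count_b, lib_a = NULL, lib_b = NULL) {
  stopifnot(length(gene_id) == length(count_a),
            length(count_a) == length(count_b),
            all(count_a >= 0), all(count_b >= 0))
  if (is.null(lib_a)) lib_a <- sum(count_a)
  if (is.null(lib_b)) lib_b <- sum(count_b)
  stopifnot(lib_a > 0, lib_b > 0)
  structure(list(gene_id = as.character(gene_id),
                 count_a = as.numeric(count_a), count_b = as.numeric(count_b),
                 lib_a = lib_a, lib_b = lib_b),
            class = "count_table")
}

#' Write a count table as TSV
#' @param table A [count_table()].
#' @param path Output path.
#' @export
write_count_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lib_a=%s lib_b=%s", format_coord(table$lib_a),
                     format_coord(table$lib_b)), con)
  writeLines("gene_id\tcount_a\tcount_b", con)
  writeLines(paste(table$gene_id, format_coord(table$count_a),
                   format_coord(table$count_b), sep = "\t"), con)
  invisible(path)
}
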