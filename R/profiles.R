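#' Metagene matrix: scaled gene bodies with fixed flanks
#'
#' For every gene, signal is averaged over (i) `flank / flank_bin`
#' fixed-width bins upstream of the TSS, (ii) `n_body_bins` equal-length
#' segments of the gene body (TSS to TTS), and (iii) the downstream flank
#' after the TTS. Rows of minus-strand genes are reversed so that column 1
#' is always biologically upstream. Positions outside the chromosome yield
#' `NA` and are excluded from column means. Genes shorter than
#' `n_body_bins` bp are skipped (their count is recorded in attribute
#' `n_skipped`).
#'
#' @param track A [signal_track()].
#' @param genes Gene annotation data frame (see [read_gene_annotation()]).
#' @param flank Flank width in bp on each side; must be a multiple of
#'   `flank_bin`.
#' @param n_body_bins Number of scaled gene-body segments (default 100).
#' @param flank_bin Fixed flank bin width in bp (default 300).
#' @param rpm Depth-normalize the track to signal-per-million first
#'   (default `TRUE`).
#' @return A numeric matrix of class `profile_matrix` (genes x columns) with
#'   row names = gene ids, and attributes `flank`, `flank_bin`,
#'   `n_body_bins`, `n_skipped`.
#' @export
metagene_matrix <- function(track, genes, flank, n_body_bins = 100L,
                            flank_bin = 300L, rpm = TRUE) {
  stopifnot(flank %% flank_bin == 0, n_body_bins >= 1)
  if (rpm) track <- track_rpm(track)
  nf <- flank / flank_bin
  keep <- (genes$end - genes$start) >= n_body_bins
  n_skipped <- sum(!keep)
  if (n_skipped)
    warning(n_skipped, " gene(s) shorter than n_body_bins bp skipped")
  genes <- genes[keep, , drop = FALSE]
  ncol <- 2 * nf + n_body_bins
  mat <- matrix(NA_real_, nrow(genes), ncol,
                dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    up <- seq(g$start - flank, g$start, by = flank_bin)
    body <- seq(g$start, g$end, length.out = n_body_bins + 1)
    down <- seq(g$end, g$end + flank, by = flank_bin)
    bounds <- c(up, body[-1], down[-1])
    row <- track_means(track, rep(g$chrom, ncol),
                       bounds[-length(bounds)], bounds[-1])
    if (g$strand == "-") row <- rev(row)
    mat[i, ] <- row
  }
  colnames(mat) <- c(sprintf("up_%d", seq_len(nf)),
                     sprintf("body_%d", seq_len(n_body_bins)),
                     sprintf("down_%d", seq_len(nf)))
  structure(mat, class = c("profile_matrix", "matrix"),
            flank = flank, flank_bin = flank_bin, n_body_bins = n_body_bins,
            n_skipped = n_skipped)
}

#' Column-wise mean profile of a profile matrix
#'
#' @param matrix A [metagene_matrix()] or [tss_signal()] matrix.
#' @return Named numeric vector of per-column means, ignoring `NA` cells.
#' @export
column_summary <- function(matrix) {
  stopifnot(nrow(matrix) >= 1)
  colMeans(unclass(matrix), na.rm = TRUE)
}

#' Log2 ratio profile between conditions, optionally H3-normalized
#'
#' Computes a per-column `log2` ratio from column summaries. In single mode
#' (`num_h3`/`den_h3` absent): `log2((num + c) / (den + c))`. In double
#' (H3-normalized) mode: `log2((num/num_h3 + c) / (den/den_h3 + c))`, the
#' standard "mark change normalized to H3" profile.
#'
#' @param num,den Profile matrices with identical geometry and gene sets
#'   (e.g. KO mark and WT mark).
#' @param num_h3,den_h3 Optional H3 profile matrices for double
#'   normalization.
#' @param pseudocount Pseudocount `c` (default 0.01; signals are
#'   per-million scale).
#' @return Named numeric vector: per-column log2 ratio.
#' @export
ratio_profile <- function(num, den, num_h3 = NULL, den_h3 = NULL,
                          pseudocount = 0.01) {
  check_geometry <- function(a, b) {
    if (!all(dim(a) == dim(b)) || !identical(rownames(a), rownames(b)))
      stop("profile matrices have mismatched geometry or gene sets")
  }
  check_geometry(num, den)
  sn <- column_summary(num)
  sd <- column_summary(den)
  if (!is.null(num_h3)) {
    stopifnot(!is.null(den_h3))
    check_geometry(num, num_h3); check_geometry(den, den_h3)
    sn <- sn / column_summary(num_h3)
    sd <- sd / column_summary(den_h3)
  }
  log2(sn + pseudocount) - log2(sd + pseudocount)
}

#' TSS-centred signal matrix and promoter means
#'
#' Strand-oriented fixed-width window around every TSS, binned at `bin` bp;
#' the promoter mean is the mean signal over the whole window.
#'
#' @param track A [signal_track()].
#' @param genes Gene annotation data frame.
#' @param half_width Half window width in bp (default 2500); must be a
#'   multiple of `bin`.
#' @param bin Bin width in bp (default 50).
#' @param rpm Depth-normalize first (default `TRUE`).
#' @return List with `matrix` (class `profile_matrix`; genes x bins, column
#'   1 most upstream) and `promoter_mean` (named vector; mean over the
#'   window, `NA` if fully out of range).
#' @export
tss_signal <- function(track, genes, half_width = 2500L, bin = 50L,
                       rpm = TRUE) {
  stopifnot(half_width %% bin == 0)
  if (rpm) track <- track_rpm(track)
  nb <- 2 * half_width / bin
  mat <- matrix(NA_real_, nrow(genes), nb,
                dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    bounds <- seq(g$tss - half_width, g$tss + half_width, by = bin)
    row <- track_means(track, rep(g$chrom, nb),
                       bounds[-length(bounds)], bounds[-1])
    if (g$strand == "-") row <- rev(row)
    mat[i, ] <- row
  }
  colnames(mat) <- sprintf("tss_%+d", seq(-half_width, half_width - bin,
                                          by = bin) + bin %/% 2)
  pm <- track_means(track, genes$chrom, genes$tss - half_width,
                    genes$tss + half_width)
  names(pm) <- genes$gene_id
  list(matrix = structure(mat, class = c("profile_matrix", "matrix"),
                          half_width = half_width, bin = bin),
       promoter_mean = pm)
}

#' Write a profile (matrix or summary vector) as TSV
#' @param x A `profile_matrix` or named numeric vector.
#' @param path Output path.
#' @export
write_profile <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.matrix(x)) {
    writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
    writeLines(paste(rownames(x),
                     apply(unclass(x), 1, function(r)
                       paste(formatC(r, format = "g", digits = 8),
                             collapse = "\t")), sep = "\t"), con)
  } else {
    writeLines(paste(names(x),
                     formatC(x, format = "g", digits = 8), sep = "\t"), con)
  }
  invisible(path)
}
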