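#' Default chromosome ordering
#'
#' Human autosomes 1-22 followed by X, Y and MT, the order used for the
#' shared cumulative x-axis.
#'
#' @return Character vector of chromosome labels.
#' @export
default_chrom_order <- function() c(as.character(1:22), "X", "Y", "MT")

# Reference chromosome lengths (bp) for the fixed-extent axis mode.
.chrom_lengths <- list(
  hg19 = c(
    "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
    "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
    "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
    "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
    "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
    "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566,
    "MT" = 16569),
  hg38 = c(
    "1" = 248956422, "2" = 242193529, "3" = 198295559, "4" = 190214555,
    "5" = 181538259, "6" = 170805979, "7" = 159345973, "8" = 145138636,
    "9" = 138394717, "10" = 133797422, "11" = 135086622, "12" = 133275309,
    "13" = 114364328, "14" = 107043718, "15" = 101991189, "16" = 90338345,
    "17" = 83257441, "18" = 80373285, "19" = 58617616, "20" = 64444167,
    "21" = 46709983, "22" = 50818468, "X" = 156040895, "Y" = 57227415,
    "MT" = 16569)
)

#' Reference chromosome lengths
#'
#' @param build Genome build, `"hg19"` (default) or `"hg38"`.
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
chrom_lengths <- function(build = c("hg19", "hg38")) {
  build <- match.arg(build)
  .chrom_lengths[[build]]
}

#' Build the cumulative genome axis
#'
#' Places chromosomes end to end, as in a Manhattan plot. In `observed` mode
#' (the default) each chromosome's extent is the maximum position seen in the
#' data, so the axis adapts to the input; in `fixed` mode reference lengths
#' for the selected build are used, making axes comparable across files.
#'
#' @param variants Variant data frame (needs `chrom` and `pos`); may be
#'   omitted in fixed mode.
#' @param mode `"observed"` or `"fixed"`.
#' @param padding Inter-chromosome gap in bp (default 0: contiguous blocks).
#' @param chrom_order Chromosome ordering for the axis.
#' @param build Genome build for fixed mode.
#' @return A `genome_axis` object: `chrom_order` (chromosomes on the axis, in
#'   order), `extent` and `offset` (named numeric, bp) and `padding`.
#' @examples
#' v <- data.frame(variant_id = c("a", "b"), chrom = c("1", "2"),
#'                 pos = c(100L, 50L), p = c(0.5, 0.5))
#' build_axis(v)$offset
#' @export
build_axis <- function(variants = NULL, mode = c("observed", "fixed"),
                       padding = 0, chrom_order = default_chrom_order(),
                       build = c("hg19", "hg38")) {
  mode <- match.arg(mode)
  if (padding < 0) stop_config("padding must be >= 0")
  if (mode == "observed") {
    if (is.null(variants) || nrow(variants) == 0L) {
      stop_input("observed-mode axis requires a non-empty variant table")
    }
    unknown <- setdiff(unique(variants$chrom), chrom_order)
    if (length(unknown) > 0L) {
      stop_input(sprintf("chromosome label(s) not in chrom_order: %s",
                         paste(unknown, collapse = ", ")))
    }
    extent <- tapply(as.numeric(variants$pos), variants$chrom, max)
    chroms <- chrom_order[chrom_order %in% names(extent)]
    extent <- as.numeric(extent[chroms])
  } else {
    lens <- chrom_lengths(match.arg(build))
    chroms <- chrom_order[chrom_order %in% names(lens)]
    if (length(chroms) == 0L) stop_config("no chrom_order label has a reference length")
    extent <- as.numeric(lens[chroms])
  }
  offset <- cumsum(c(0, utils::head(extent, -1L) + padding))
  structure(list(chrom_order = chroms,
                 extent = stats::setNames(extent, chroms),
                 offset = stats::setNames(offset, chroms),
                 padding = padding),
            class = "genome_axis")
}

#' @export
print.genome_axis <- function(x, ...) {
  cat(sprintf("<genome_axis> %d chromosome(s), span %.0f bp, padding %.0f bp\n",
              length(x$chrom_order), axis_span(x), x$padding))
  invisible(x)
}

# Total cumulative span of the axis (end of the last chromosome).
axis_span <- function(axis) {
  n <- length(axis$chrom_order)
  unname(axis$offset[n] + axis$extent[n])
}

#' Map (chromosome, position) to the cumulative coordinate
#'
#' Returns `offset[chrom] + pos`, the genome-wide x-axis coordinate; strictly
#' monotone in position within each chromosome and across the chromosome
#' order.
#'
#' @param axis A `genome_axis`.
#' @param chrom Chromosome labels (vectorised).
#' @param pos 1-based positions in bp (vectorised).
#' @return Numeric vector of cumulative coordinates.
#' @export
to_cumulative <- function(axis, chrom, pos) {
  idx <- match(as.character(chrom), axis$chrom_order)
  if (anyNA(idx)) {
    stop_input(sprintf("chromosome label(s) not on axis: %s",
                       paste(unique(chrom[is.na(idx)]), collapse = ", ")))
  }
  unname(axis$offset[idx]) + as.numeric(pos)
}

#' Midpoint tick position for each chromosome
#'
#' @param axis A `genome_axis`.
#' @return Named numeric vector: cumulative coordinate of each chromosome's
#'   midpoint, for x-axis labelling.
#' @export
chrom_tick_positions <- function(axis) {
  axis$offset + axis$extent / 2
}
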