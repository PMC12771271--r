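#' Column mapping for association summary tables
#'
#' Declares which columns of the input tables hold each required field.
#' Fields left `NULL` are auto-detected against the common GWAS
#' summary-statistics dialects (PLINK-style `SNP`/`CHR`/`BP`/`P`,
#' `ID`/`CHROM`/`POS`/`PVAL`, lowercase variants, and the usual
#' `MAF`/`AF`/`freq` spellings). Explicitly named columns must exist in the
#' file they map, otherwise reading fails with a configuration error.
#'
#' @param variant_id,chrom,pos,p,af Column names in the variant-level table
#'   (`af` is optional and may stay unmapped).
#' @param set_id,set_p Column names in the set-level results table; `set_id`
#'   is also used for the membership table together with `variant_id`.
#' @return An object of class `column_mapping`.
#' @examples
#' column_mapping(p = "P.VALUE", chrom = "Chromosome")
#' @export
column_mapping <- function(variant_id = NULL, chrom = NULL, pos = NULL,
                           p = NULL, af = NULL,
                           set_id = NULL, set_p = NULL) {
  m <- list(variant_id = variant_id, chrom = chrom, pos = pos, p = p, af = af,
            set_id = set_id, set_p = set_p)
  for (f in names(m)) {
    if (!is.null(m[[f]]) && (!is.character(m[[f]]) || length(m[[f]]) != 1L)) {
      stop_config(sprintf("column_mapping field '%s' must be a single column name", f))
    }
  }
  structure(m, class = "column_mapping")
}

# Synonym tables covering the dialects of the cited summary-statistics
# sources. Matching is case-insensitive, first hit wins.
.col_synonyms <- list(
  variant_id = c("variant_id", "snp", "id", "rsid", "rs_id", "variant", "markername"),
  chrom = c("chrom", "chr", "chromosome", "#chrom", "chr_name"),
  pos = c("pos", "bp", "position", "base_pair_location", "bp_pos"),
  p = c("p", "pval", "p_value", "pvalue", "p.value"),
  af = c("af", "maf", "freq", "allele_frequency", "effect_allele_frequency", "a1freq"),
  set_id = c("set_id", "set", "group", "gene", "pathway", "group_id"),
  set_p = c("p", "pval", "p_value", "pvalue", "p.value", "set_p")
)

resolve_column <- function(mapping, field, header, required = TRUE) {
  explicit <- mapping[[field]]
  if (!is.null(explicit)) {
    if (!explicit %in% header) {
      stop_config(sprintf("mapped column '%s' (field '%s') not found in header: %s",
                          explicit, field, paste(header, collapse = ", ")))
    }
    return(explicit)
  }
  hit <- header[match(.col_synonyms[[field]], tolower(header), nomatch = 0L)]
  if (length(hit) >= 1L) return(hit[[1L]])
  if (required) {
    stop_config(sprintf(
      "no column for field '%s' found (tried: %s); supply it via column_mapping()",
      field, paste(.col_synonyms[[field]], collapse = ", ")))
  }
  NULL
}

#' Normalise chromosome labels
#'
#' Strips an optional `chr` prefix, uppercases X/Y/MT and maps `M` to `MT`,
#' so mixed hg19/hg38-dialect inputs share one label set.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalised labels (`"1"`..`"22"`, `"X"`,
#'   `"Y"`, `"MT"` for human inputs).
#' @examples
#' normalise_chrom(c("chr7", "chrX", "M", "12"))
#' @export
normalise_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  x <- toupper(trimws(x))
  x[x == "M"] <- "MT"
  x
}

# Delimited read with delimiter auto-detection (tab default, comma fallback)
# and transparent gzip via base R connections.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("input file not found: %s", path))
  con <- file(path, "rt")  # file() auto-detects gzip magic bytes
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L) stop_input(sprintf("empty input file: %s", path))
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"",
                          colClasses = "character")
  if (nrow(df) == 0L) stop_input(sprintf("no data rows in input file: %s", path))
  df
}

#' Read a variant-level association table
#'
#' Parses a delimited (TSV/CSV, optionally gzipped) table of single-variant
#' association results. Chromosome labels are normalised
#' (`"chr1"` becomes `"1"`). Rows with an unparsable position, a P value
#' outside (0, 1], or a chromosome outside `chrom_order` are rejected row by
#' row; the rejection report is attached as attribute `"rejections"` and
#' summarised in a warning. P values equal to zero (underflow in biobank
#' summary statistics) are clamped to the smallest positive double with a
#' warning rather than rejected.
#'
#' @param path Path to the table.
#' @param mapping A [column_mapping()].
#' @param chrom_order Permitted chromosome labels after normalisation.
#' @return A data frame with columns `variant_id`, `chrom`, `pos`, `p` and,
#'   when mapped or auto-detected, `af`; attribute `"rejections"` holds a data
#'   frame (`row`, `variant_id`, `reason`) of discarded rows.
#' @export
read_variant_table <- function(path, mapping = column_mapping(),
                               chrom_order = default_chrom_order()) {
  raw <- read_delim_auto(path)
  header <- names(raw)
  cid <- resolve_column(mapping, "variant_id", header)
  cch <- resolve_column(mapping, "chrom", header)
  cpo <- resolve_column(mapping, "pos", header)
  cp <- resolve_column(mapping, "p", header)
  caf <- resolve_column(mapping, "af", header, required = FALSE)

  ids <- raw[[cid]]
  chrom <- normalise_chrom(raw[[cch]])
  pos <- suppressWarnings(as.numeric(raw[[cpo]]))
  p <- suppressWarnings(as.numeric(raw[[cp]]))
  af <- if (!is.null(caf)) suppressWarnings(as.numeric(raw[[caf]])) else NULL

  n_clamped <- sum(!is.na(p) & p == 0)
  if (n_clamped > 0L) {
    warning(sprintf("%d zero P value(s) clamped to %.3g", n_clamped,
                    .Machine$double.xmin), call. = FALSE)
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }

  reason <- rep(NA_character_, nrow(raw))
  bad_pos <- is.na(pos) | pos < 1 | pos != floor(pos)
  bad_p <- is.na(p) | p <= 0 | p > 1
  bad_chr <- !chrom %in% chrom_order
  reason[bad_chr] <- "chromosome not in configured order"
  reason[bad_p] <- "P value outside (0, 1]"
  reason[bad_pos] <- "unparsable or non-positive position"
  keep <- is.na(reason)

  rejections <- data.frame(row = which(!keep), variant_id = ids[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  if (nrow(rejections) > 0L) {
    warning(sprintf("rejected %d of %d variant row(s); see attr(., 'rejections')",
                    nrow(rejections), nrow(raw)), call. = FALSE)
  }

  out <- data.frame(variant_id = ids[keep], chrom = chrom[keep],
                    pos = as.integer(pos[keep]), p = p[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(af)) out$af <- af[keep]
  dup <- unique(out$variant_id[duplicated(out$variant_id)])
  if (length(dup) > 0L) {
    stop_input(sprintf("duplicate variant ID(s): %s",
                       paste(utils::head(dup, 5L), collapse = ", ")))
  }
  attr(out, "rejections") <- rejections
  out
}

#' Read a set-level association results table
#'
#' @param path Path to a delimited table with one row per variant-set test.
#' @param mapping A [column_mapping()]; fields `set_id` and `set_p` are used.
#' @return A data frame with columns `set_id` and `p`.
#' @export
read_set_results <- function(path, mapping = column_mapping()) {
  raw <- read_delim_auto(path)
  header <- names(raw)
  cid <- resolve_column(mapping, "set_id", header)
  cp <- resolve_column(mapping, "set_p", header)
  set_id <- raw[[cid]]
  p <- suppressWarnings(as.numeric(raw[[cp]]))

  dup <- unique(set_id[duplicated(set_id)])
  if (length(dup) > 0L) {
    stop_input(sprintf("duplicate set ID(s): %s", paste(dup, collapse = ", ")))
  }
  n_clamped <- sum(!is.na(p) & p == 0)
  if (n_clamped > 0L) {
    warning(sprintf("%d zero set P value(s) clamped to %.3g", n_clamped,
                    .Machine$double.xmin), call. = FALSE)
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  bad <- is.na(p) | p <= 0 | p > 1
  if (any(bad)) {
    stop_input(sprintf("set P value outside (0, 1] for: %s",
                       paste(utils::head(set_id[bad], 5L), collapse = ", ")))
  }
  data.frame(set_id = set_id, p = p, stringsAsFactors = FALSE)
}

#' Read a set-membership table
#'
#' Long-format two-column table linking each set to its constituent variants.
#' First-seen member order is preserved; duplicate (set, variant) pairs are
#' collapsed with a warning count. Variant IDs absent from the variant table
#' are retained here and resolved downstream when anchors are computed.
#'
#' @inheritParams read_set_results
#' @return A named list: `set_id` to character vector of `variant_id`s.
#' @export
read_membership <- function(path, mapping = column_mapping()) {
  raw <- read_delim_auto(path)
  header <- names(raw)
  cid <- resolve_column(mapping, "set_id", header)
  cv <- resolve_column(mapping, "variant_id", header)
  key <- paste(raw[[cid]], raw[[cv]], sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate (set, variant) membership pair(s)",
                    sum(dup)), call. = FALSE)
  }
  sid <- raw[[cid]][!dup]
  vid <- raw[[cv]][!dup]
  split(vid, factor(sid, levels = unique(sid)))
}

.layout_cols <- c("id", "layer", "chrom", "x_cumulative", "p", "neglog10_p",
                  "significant", "colour_group")

#' Write a computed layout to TSV
#'
#' Serialises the point table of an [assemble_layout()] result (or a
#' compatible data frame) with columns `id`, `layer`, `chrom`,
#' `x_cumulative`, `p`, `neglog10_p`, `significant`, `colour_group`.
#' Numeric fields are written at full precision so that [read_layout()]
#' reproduces every finite value bit-exactly.
#'
#' @param layout An `archipelago_layout` object or its points data frame.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_layout <- function(layout, path) {
  pts <- if (inherits(layout, "archipelago_layout")) layout$points else layout
  df <- data.frame(
    id = as.character(pts$id %||% character(0)),
    layer = as.character(pts$layer %||% character(0)),
    chrom = as.character(pts$chrom %||% character(0)),
    x_cumulative = fmt_num(as.numeric(pts$x %||% pts$x_cumulative %||% numeric(0))),
    p = fmt_num(as.numeric(pts$p %||% numeric(0))),
    neglog10_p = fmt_num(as.numeric(pts$y %||% pts$neglog10_p %||% numeric(0))),
    significant = as.logical(pts$significant %||% logical(0)),
    colour_group = as.integer(pts$colour_group %||% integer(0)),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_config(sprintf("cannot write layout to: %s", path))
  invisible(path)
}

#' Read back a layout TSV written by [write_layout()]
#'
#' @param path Path to a layout TSV.
#' @return Data frame with the layout columns in their native types.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("layout file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = "NA")
  missing <- setdiff(.layout_cols, names(df))
  if (length(missing) > 0L) {
    stop_input(sprintf("layout file lacks column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  df$x_cumulative <- as.numeric(df$x_cumulative)
  df$p <- as.numeric(df$p)
  df$neglog10_p <- as.numeric(df$neglog10_p)
  df$significant <- as.logical(df$significant)
  df$colour_group <- as.integer(df$colour_group)
  df
}
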