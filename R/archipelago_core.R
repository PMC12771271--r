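#' Genomic anchors for variant sets
#'
#' Assigns each set-level P value a genomic x-coordinate: the arithmetic mean
#' of the cumulative coordinates of its member variants. Members not present
#' in the variant table are excluded from the mean (a per-set warning count
#' is reported); sets with no resolvable member are dropped with a warning,
#' or raise an error when `on_empty = "error"`.
#'
#' @param sets Data frame of set results (`set_id`, `p`).
#' @param membership Named list mapping `set_id` to member `variant_id`s, as
#'   from [read_membership()].
#' @param variants Variant data frame (`variant_id`, `chrom`, `pos`).
#' @param axis A [build_axis()] result.
#' @param on_empty `"drop"` (default) or `"error"` for sets whose members are
#'   all unresolvable.
#' @return Named numeric vector of anchor coordinates, one per retained set;
#'   attribute `"unresolved"` counts members per set that were skipped.
#' @export
anchor_sets <- function(sets, membership, variants, axis,
                        on_empty = c("drop", "error")) {
  on_empty <- match.arg(on_empty)
  x_var <- stats::setNames(to_cumulative(axis, variants$chrom, variants$pos),
                           variants$variant_id)
  anchors <- rep(NA_real_, nrow(sets))
  names(anchors) <- sets$set_id
  unresolved <- stats::setNames(integer(nrow(sets)), sets$set_id)
  for (i in seq_len(nrow(sets))) {
    sid <- sets$set_id[i]
    members <- membership[[sid]]
    xs <- x_var[members]
    miss <- is.na(xs)
    unresolved[i] <- sum(miss) + is.null(members)
    if (any(!miss)) anchors[i] <- mean(xs[!miss])
  }
  if (sum(unresolved) > 0L) {
    warning(sprintf("%d membership entr(y/ies) across %d set(s) had no matching variant record",
                    sum(unresolved), sum(unresolved > 0L)), call. = FALSE)
  }
  empty <- is.na(anchors)
  if (any(empty)) {
    msg <- sprintf("%d set(s) with zero resolvable members: %s", sum(empty),
                   paste(utils::head(names(anchors)[empty], 5L), collapse = ", "))
    if (on_empty == "error") stop_input(msg)
    warning(paste(msg, "- dropped"), call. = FALSE)
    anchors <- anchors[!empty]
    unresolved <- unresolved[!empty]
  }
  attr(anchors, "unresolved") <- unresolved
  anchors
}

#' Priority ranking of variant sets
#'
#' Orders sets by ascending P value, strongest association first, so the
#' strongest signal keeps its exact genomic anchor during dispersion. Ties
#' are broken lexicographically by set ID for deterministic layouts.
#'
#' @param sets Data frame with `set_id` and `p`.
#' @return Character vector of `set_id`s in priority order.
#' @export
rank_sets <- function(sets) {
  sets$set_id[order(sets$p, sets$set_id, method = "radix")]
}

#' Disperse overlapping set anchors
#'
#' Variant sets built from narrow or genome-wide regions can anchor to nearly
#' identical x positions (genome-wide sets cluster near the centre).
#' Dispersion separates them while preserving the left-to-right order of the
#' anchors.
#'
#' Modes:
#' \describe{
#'   \item{none}{identity; anchors returned unchanged.}
#'   \item{priority}{sets are placed strongest association first; a point
#'     conflicting with already-placed points moves the minimal distance
#'     that restores `min_gap` against every placed point while keeping the
#'     anchor order. For exact anchor ties the weaker point is pushed toward
#'     the side of the axis with more free span, toward +Inf on an exact
#'     tie. The globally strongest set always keeps its exact anchor.}
#'   \item{even}{adjusted coordinates are equally spaced over
#'     `[min(anchor), max(anchor)]` in anchor-rank order.}
#' }
#'
#' In priority mode the feasible interval for each new point reserves
#' `min_gap` per intervening rank step against every already-placed point,
#' which guarantees the interval is never empty and that the final
#' configuration has all pairwise gaps at least `min_gap` in anchor-rank
#' order.
#'
#' @param anchors Named numeric vector of anchor coordinates.
#' @param priority Character vector of the same names in priority order
#'   (see [rank_sets()]).
#' @param mode Dispersion mode.
#' @param min_gap Minimum pairwise separation in cumulative bp (priority
#'   mode).
#' @param axis_range Numeric length-2 range used for the tie side rule and
#'   the feasibility check; defaults to the anchor range padded by
#'   `min_gap` on each side.
#' @return Named numeric vector of adjusted coordinates, same order and
#'   names as `anchors`.
#' @export
disperse <- function(anchors, priority = names(sort(anchors)),
                     mode = c("priority", "none", "even"), min_gap = 0,
                     axis_range = NULL) {
  mode <- match.arg(mode)
  if (min_gap < 0) stop_config("min_gap must be >= 0")
  m <- length(anchors)
  if (mode == "none" || m <= 1L) return(anchors)
  if (!setequal(priority, names(anchors))) {
    stop_config("priority must be a permutation of the anchor names")
  }

  # priority rank per set: 1 = strongest
  prank <- stats::setNames(seq_along(priority), priority)

  if (mode == "even") {
    ord <- order(anchors, prank[names(anchors)])
    out <- anchors
    out[ord] <- seq(min(anchors), max(anchors), length.out = m)
    return(out)
  }

  if (is.null(axis_range)) {
    axis_range <- range(anchors) + c(-1, 1) * min_gap
  }
  span <- diff(axis_range)
  if ((m - 1) * min_gap > span) {
    stop_config(sprintf(
      "infeasible min_gap: %d points need %.4g bp but the axis spans %.4g bp; try min_gap <= %.4g",
      m, (m - 1) * min_gap, span, span / (m - 1)))
  }

  # Fixed left-to-right order: by anchor; exact ties resolved so the weaker
  # point sits on the roomier side of the tied anchor (+Inf side on a tie).
  nm <- names(anchors)
  ties_right <- (axis_range[2L] - anchors) >= (anchors - axis_range[1L])
  tie_rank <- ifelse(ties_right[nm], prank[nm], -prank[nm])
  ord <- nm[order(anchors, tie_rank, method = "radix")]
  pos_in_order <- stats::setNames(seq_along(ord), ord)

  out <- anchors
  placed <- character(0)
  for (sid in priority) {
    i <- pos_in_order[[sid]]
    a <- anchors[[sid]]
    lo <- -Inf
    hi <- Inf
    for (q in placed) {
      j <- pos_in_order[[q]]
      if (j < i) lo <- max(lo, out[[q]] + (i - j) * min_gap)
      else hi <- min(hi, out[[q]] - (j - i) * min_gap)
    }
    out[[sid]] <- min(max(a, lo), hi)
    placed <- c(placed, sid)
  }
  out
}

#' Significance threshold from the number of set tests
#'
#' The Bonferroni-style threshold `alpha / n_sets`, the multiple-testing
#' correction over the number of independent variant-set tests (e.g.
#' 0.05 / 250 = 2e-4 for 250 set tests).
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_sets Positive number of set-level tests performed.
#' @return The per-test significance threshold.
#' @examples
#' compute_threshold(0.05, 250)
#' @export
compute_threshold <- function(alpha, n_sets) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_config("alpha must be a single value in (0, 1)")
  }
  if (!is.numeric(n_sets) || length(n_sets) != 1L || n_sets < 1) {
    stop_config("n_sets must be a positive count")
  }
  alpha / n_sets
}

#' Flag significant layout points
#'
#' Set-layer points are flagged when `p < threshold_set` (strictly below:
#' the boundary value is not significant); variant-layer points only when a
#' `threshold_variant` is supplied. Re-flagging with the same thresholds is
#' idempotent.
#'
#' @param points Layout points data frame (`layer`, `p`, `significant`).
#' @param threshold_set Set-layer threshold.
#' @param threshold_variant Optional variant-layer threshold.
#' @return `points` with the `significant` column (re)computed.
#' @export
flag_significant <- function(points, threshold_set, threshold_variant = NULL) {
  sig <- rep(FALSE, nrow(points))
  is_set <- points$layer == "set"
  sig[is_set] <- points$p[is_set] < threshold_set
  if (!is.null(threshold_variant)) {
    sig[!is_set] <- points$p[!is_set] < threshold_variant
  }
  points$significant <- sig
  points
}

#' Build set-to-variant edges
#'
#' Edges visually link each set-level point to its constituent variants.
#' With `significant_only = TRUE` (the figure default) edges are drawn only
#' for sets in the significantly enriched group; otherwise one edge per
#' (set, member) pair.
#'
#' @param sets Set results data frame (`set_id`, `p`).
#' @param membership Named list `set_id` -> member `variant_id`s.
#' @param flagged Character vector of significant `set_id`s.
#' @param significant_only Restrict edges to flagged sets?
#' @param variant_ids Optional vector of known variant IDs; members outside
#'   it are skipped (unresolvable in the layout).
#' @return Data frame of edges (`set_id`, `variant_id`, `significant`).
#' @export
build_edges <- function(sets, membership, flagged = character(0),
                        significant_only = TRUE, variant_ids = NULL) {
  keep <- if (significant_only) sets$set_id[sets$set_id %in% flagged] else sets$set_id
  members <- membership[keep]
  lens <- lengths(members)
  edges <- data.frame(set_id = rep(keep, lens),
                      variant_id = unlist(members, use.names = FALSE) %||% character(0),
                      stringsAsFactors = FALSE)
  if (!is.null(variant_ids)) {
    edges <- edges[edges$variant_id %in% variant_ids, , drop = FALSE]
  }
  edges$significant <- edges$set_id %in% flagged
  rownames(edges) <- NULL
  edges
}

#' Layout assembly options
#'
#' @param alpha Family-wise error rate for the auto threshold (default 0.05).
#' @param threshold `"auto"` (Bonferroni over the number of set tests) or an
#'   explicit value in (0, 1).
#' @param dispersion Dispersion mode: `"priority"`, `"none"` or `"even"`.
#' @param min_gap Minimum set-point separation in cumulative bp; `NULL`
#'   defaults to 0.5\% of the axis span, capped at `span / (n_sets - 1)` so
#'   the all-pairs gap requirement stays feasible for dense set collections
#'   (visible separation at figure scale without distorting genome
#'   positions).
#' @param significant_only Draw edges only for significant sets?
#' @param threshold_variant Optional significance threshold for the variant
#'   layer.
#' @param dual_colour_significant_sets Alternate two colour groups over the
#'   significant sets (useful with several enriched sets)?
#' @param copy_set_x_to_variants If `TRUE`, member variants inherit their
#'   set's x-coordinate instead of their own genomic position (an alternative
#'   set-to-variant mapping, off by default).
#' @return An `arch_options` list.
#' @export
arch_options <- function(alpha = 0.05, threshold = "auto",
                         dispersion = c("priority", "none", "even"),
                         min_gap = NULL, significant_only = TRUE,
                         threshold_variant = NULL,
                         dual_colour_significant_sets = FALSE,
                         copy_set_x_to_variants = FALSE) {
  dispersion <- match.arg(dispersion)
  if (!identical(threshold, "auto")) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold <= 0 || threshold >= 1) {
      stop_config("threshold must be \"auto\" or a value in (0, 1)")
    }
  }
  structure(list(alpha = alpha, threshold = threshold, dispersion = dispersion,
                 min_gap = min_gap, significant_only = significant_only,
                 threshold_variant = threshold_variant,
                 dual_colour_significant_sets = dual_colour_significant_sets,
                 copy_set_x_to_variants = copy_set_x_to_variants),
            class = "arch_options")
}

#' Assemble the full archipelago layout
#'
#' Runs the whole pipeline: cumulative coordinates for every variant, set
#' anchors (mean member coordinate), priority ranking, dispersion,
#' significance threshold and flags, set-to-variant edges, and colour
#' groups (variants alternate by chromosome parity; sets are one group, or
#' two alternating groups over the significant sets when requested).
#' Deterministic for fixed inputs and invariant to input row order.
#'
#' @param variants Variant data frame from [read_variant_table()].
#' @param sets Set results data frame from [read_set_results()].
#' @param membership Named list from [read_membership()].
#' @param axis Optional [build_axis()] result; built in observed mode with
#'   zero padding when `NULL`.
#' @param options An [arch_options()] list.
#' @return An `archipelago_layout`: `points` (id, layer, chrom, x, p, y,
#'   significant, colour_group), `edges`, `threshold`, `axis`, `options`.
#'   Sets whose members span several chromosomes carry `NA` chrom and rely
#'   on their anchor.
#' @export
assemble_layout <- function(variants, sets, membership, axis = NULL,
                            options = arch_options()) {
  if (is.null(axis)) axis <- build_axis(variants)
  n_tests <- nrow(sets)
  threshold <- if (identical(options$threshold, "auto")) {
    compute_threshold(options$alpha, n_tests)
  } else {
    options$threshold
  }

  anchors <- anchor_sets(sets, membership, variants, axis)
  sets <- sets[sets$set_id %in% names(anchors), , drop = FALSE]
  # stable canonical row order regardless of input order
  variants <- variants[order(match(variants$chrom, axis$chrom_order),
                             variants$pos, variants$variant_id,
                             method = "radix"), , drop = FALSE]
  sets <- sets[order(sets$set_id, method = "radix"), , drop = FALSE]
  anchors <- anchors[sets$set_id]

  priority <- rank_sets(sets)
  span <- axis_span(axis)
  min_gap <- options$min_gap %||%
    min(0.005 * span, span / max(1L, length(anchors) - 1L))
  x_set <- disperse(anchors, priority, mode = options$dispersion,
                    min_gap = min_gap, axis_range = c(0, axis_span(axis)))

  x_var <- to_cumulative(axis, variants$chrom, variants$pos)
  chrom_idx <- match(variants$chrom, axis$chrom_order)

  # chromosome of a set: its members' chromosome if unique, else NA
  set_chrom <- vapply(sets$set_id, function(sid) {
    ch <- unique(variants$chrom[variants$variant_id %in% membership[[sid]]])
    if (length(ch) == 1L) ch else NA_character_
  }, character(1))

  var_points <- data.frame(
    id = variants$variant_id, layer = "variant", chrom = variants$chrom,
    x = x_var, p = variants$p, y = -log10(variants$p),
    significant = FALSE,
    colour_group = ((chrom_idx - 1L) %% 2L) + 1L,
    stringsAsFactors = FALSE)
  set_points <- data.frame(
    id = sets$set_id, layer = "set", chrom = unname(set_chrom),
    x = unname(x_set[sets$set_id]), p = sets$p, y = -log10(sets$p),
    significant = FALSE, colour_group = 1L, stringsAsFactors = FALSE)

  points <- rbind(var_points, set_points)
  points <- flag_significant(points, threshold, options$threshold_variant)

  flagged <- points$id[points$layer == "set" & points$significant]
  if (options$dual_colour_significant_sets && length(flagged) > 0L) {
    sig_rows <- which(points$layer == "set" & points$significant)
    sig_rows <- sig_rows[order(points$x[sig_rows])]
    points$colour_group[sig_rows] <- ((seq_along(sig_rows) - 1L) %% 2L) + 1L
  }

  edges <- build_edges(sets, membership, flagged,
                       significant_only = options$significant_only,
                       variant_ids = variants$variant_id)

  if (options$copy_set_x_to_variants && nrow(edges) > 0L) {
    sx <- stats::setNames(set_points$x, set_points$id)
    hit <- match(points$id, edges$variant_id)
    repl <- !is.na(hit) & points$layer == "variant"
    points$x[repl] <- sx[edges$set_id[hit[repl]]]
  }

  rownames(points) <- NULL
  structure(list(points = points, edges = edges, threshold = threshold,
                 axis = axis, options = options),
            class = "archipelago_layout")
}

#' @export
print.archipelago_layout <- function(x, ...) {
  n_var <- sum(x$points$layer == "variant")
  n_set <- sum(x$points$layer == "set")
  n_sig <- sum(x$points$significant & x$points$layer == "set")
  cat(sprintf(paste0("<archipelago_layout> %d variant point(s), %d set point(s)",
                     " (%d significant at p < %.3g), %d edge(s)\n"),
              n_var, n_set, n_sig, x$threshold, nrow(x$edges)))
  invisible(x)
}

#' Allele-frequency summary of a variant selection
#'
#' Characterises the allele-frequency architecture of a selection of
#' variants - e.g. the significant GWAS hits versus the members of a top
#' variant set, which typically differ (common-variant peaks vs. rare-variant
#' collapse).
#'
#' @param variants Variant data frame carrying an `af` column.
#' @param ids Optional `variant_id` selection; `NULL` selects all rows.
#' @return List with `n`, `mean_af`, `min_af`, `max_af`. An empty selection
#'   yields `n = 0` and `NA` moments (with a message); a selected variant
#'   without `af` is an error.
#' @export
af_summary <- function(variants, ids = NULL) {
  sel <- if (is.null(ids)) variants else variants[variants$variant_id %in% ids, , drop = FALSE]
  if (nrow(sel) == 0L) {
    message("af_summary: empty selection")
    return(list(n = 0L, mean_af = NA_real_, min_af = NA_real_, max_af = NA_real_))
  }
  if (is.null(sel$af) || anyNA(sel$af)) {
    stop_input("af_summary: selected variant(s) lack an allele frequency")
  }
  list(n = nrow(sel), mean_af = mean(sel$af),
       min_af = min(sel$af), max_af = max(sel$af))
}
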