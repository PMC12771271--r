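# Per-variant annotation P values form a third information layer on top of
# the set and single-variant layers (the STAAR-style hierarchy): each
# variant's P value is itself a Cauchy-combination (ACAT) aggregate of
# annotation-weighted P values.

.p_eps <- 1e-15

clamp_p <- function(p, warn = TRUE) {
  out <- pmin(pmax(p, .p_eps), 1 - .p_eps)
  n <- sum(out != p, na.rm = TRUE)
  if (warn && n > 0L) {
    warning(sprintf("%d P value(s) clamped into [%.0e, 1 - %.0e]", n,
                    .p_eps, .p_eps), call. = FALSE)
  }
  out
}

#' Annotation P-value matrix
#'
#' One row per variant, one column per annotation layer; values are P values
#' strictly inside (0, 1) (clamped to `[1e-15, 1 - 1e-15]` with a warning,
#' since the Cauchy transform diverges at 0 and 1). Missing cells are
#' rejected by default; `impute = "layer_mean"` replaces them with the
#' layer's observed mean instead.
#'
#' @param p Numeric matrix (or data frame) of P values, variants x layers.
#' @param variant_ids Row identifiers; defaults to existing rownames.
#' @param layer_names Column identifiers; defaults to existing colnames.
#' @param weights Optional positive per-layer weights (default all 1).
#' @param impute `"none"` (reject missing cells) or `"layer_mean"`.
#' @return An `annotation_matrix` object.
#' @export
annotation_matrix <- function(p, variant_ids = rownames(p),
                              layer_names = colnames(p), weights = NULL,
                              impute = c("none", "layer_mean")) {
  impute <- match.arg(impute)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (is.null(variant_ids)) variant_ids <- sprintf("v%d", seq_len(nrow(p)))
  if (is.null(layer_names)) layer_names <- sprintf("layer%d", seq_len(ncol(p)))
  if (length(variant_ids) != nrow(p) || length(layer_names) != ncol(p)) {
    stop_config("variant_ids / layer_names must match the matrix dimensions")
  }
  if (anyNA(p)) {
    if (impute == "none") {
      stop_input(sprintf("annotation matrix has %d missing cell(s); set impute = \"layer_mean\" to impute",
                         sum(is.na(p))))
    }
    for (j in seq_len(ncol(p))) {
      mis <- is.na(p[, j])
      if (all(mis)) stop_input(sprintf("annotation layer '%s' is entirely missing", layer_names[j]))
      p[mis, j] <- mean(p[!mis, j])
    }
  }
  p <- clamp_p(p)
  dimnames(p) <- list(variant_ids, layer_names)
  weights <- weights %||% rep(1, ncol(p))
  if (length(weights) != ncol(p) || any(weights <= 0)) {
    stop_config("weights must be one positive value per layer")
  }
  structure(list(p = p, weights = as.numeric(weights)),
            class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("<annotation_matrix> %d variant(s) x %d layer(s)\n",
              nrow(x$p), ncol(x$p)))
  invisible(x)
}

#' Read an annotation P-value matrix from TSV
#'
#' First column is the variant ID; every remaining column is one annotation
#' layer. Optional per-layer weights come from a two-column side file
#' (`layer`, `weight`).
#'
#' @param path Path to the annotation table.
#' @param weights_path Optional path to the weights side file.
#' @param impute Passed to [annotation_matrix()].
#' @return An `annotation_matrix`.
#' @export
read_annotation_matrix <- function(path, weights_path = NULL,
                                   impute = c("none", "layer_mean")) {
  raw <- read_delim_auto(path)
  if (ncol(raw) < 2L) stop_input("annotation table needs a variant ID column plus at least one layer")
  ids <- raw[[1L]]
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  weights <- NULL
  if (!is.null(weights_path)) {
    w <- read_delim_auto(weights_path)
    wv <- stats::setNames(suppressWarnings(as.numeric(w[[2L]])), w[[1L]])
    missing <- setdiff(colnames(m), names(wv))
    if (length(missing) > 0L) {
      stop_config(sprintf("weights file lacks layer(s): %s",
                          paste(missing, collapse = ", ")))
    }
    weights <- unname(wv[colnames(m)])
  }
  annotation_matrix(m, variant_ids = ids, layer_names = colnames(m),
                    weights = weights, impute = impute)
}

#' Cauchy combination (ACAT) of dependent P values
#'
#' Combines P values via the weighted Cauchy transformation
#' `T = sum(w_i * tan((0.5 - p_i) * pi)) / sum(w_i)` and returns the
#' upper-tail standard Cauchy probability `0.5 - atan(T) / pi`. Valid under
#' arbitrary dependence between the inputs; combining identical values
#' returns that value exactly, and the result is strictly decreasing in each
#' input. The exact Cauchy tail is used throughout (no small-p
#' approximation), preserving the fixed-point property.
#'
#' @param p Numeric vector of P values in (0, 1); values outside
#'   `[1e-15, 1 - 1e-15]` are clamped with a warning.
#' @param weights Optional positive weights, one per P value (default
#'   equal); rescaling all weights by a constant leaves the result
#'   unchanged.
#' @return The combined P value in (0, 1).
#' @examples
#' acat_combine(c(0.01, 0.5))
#' acat_combine(rep(0.3, 4)) # fixed point: 0.3
#' @export
acat_combine <- function(p, weights = NULL) {
  if (length(p) == 0L) stop_config("acat_combine needs at least one P value")
  weights <- weights %||% rep(1, length(p))
  if (length(weights) != length(p)) stop_config("weights must match p in length")
  if (any(weights <= 0)) stop_config("weights must be strictly positive")
  if (anyNA(p)) stop_input("acat_combine: missing P value(s)")
  if (any(p <= 0 | p >= 1)) {
    stop_input("acat_combine: P value(s) outside the open interval (0, 1); clamp on load")
  }
  p <- clamp_p(p)
  # tan((0.5 - p) * pi) == cot(p * pi); the cospi/sinpi form keeps full
  # precision for p near 0 and 1 where the direct tangent degrades
  weights <- weights / sum(weights)  # exact scale invariance
  t_stat <- sum(weights * cospi(p) / sinpi(p))
  # upper Cauchy tail; the atan(1/T) branch avoids catastrophic cancellation
  # in 0.5 - atan(T)/pi when T is large (small combined p)
  out <- if (t_stat > 1) {
    atan(1 / t_stat) / pi
  } else {
    0.5 - atan(t_stat) / pi
  }
  min(max(out, .p_eps), 1 - .p_eps)
}

#' Per-variant ACAT aggregate of an annotation matrix
#'
#' @param m An [annotation_matrix()].
#' @return Named numeric vector: one combined P value per variant, using the
#'   matrix's per-layer weights.
#' @export
acat_combine_matrix <- function(m) {
  stopifnot(inherits(m, "annotation_matrix"))
  apply(m$p, 1L, acat_combine, weights = m$weights)
}

#' Mean annotation P value per layer
#'
#' The per-layer average over variants, an estimate of each annotation
#' layer's hierarchy of contribution (drawn as horizontal lines in the
#' drill-down panel); ordering layers by this mean ranks their contribution.
#'
#' @param m An [annotation_matrix()].
#' @return Named numeric vector of layer means.
#' @export
layer_means <- function(m) {
  stopifnot(inherits(m, "annotation_matrix"))
  colMeans(m$p)
}

#' Per-variant spread of annotation P values
#'
#' @param m An [annotation_matrix()].
#' @return Data frame (`variant_id`, `p_min`, `p_max`): the range of each
#'   variant's annotation P values across layers.
#' @export
variant_spread <- function(m) {
  stopifnot(inherits(m, "annotation_matrix"))
  data.frame(variant_id = rownames(m$p),
             p_min = apply(m$p, 1L, min),
             p_max = apply(m$p, 1L, max),
             stringsAsFactors = FALSE)
}

#' Correlation between annotation layers
#'
#' Pearson correlation computed on `-log10(p)` — the association scale on
#' which annotation layers are expected to be linearly related. Highly
#' correlated layers are common because many prediction tools share
#' population-frequency inputs. A layer with zero variance yields `NA`
#' off-diagonal entries (flagged with a warning), never a silent 0.
#'
#' @param m An [annotation_matrix()].
#' @return Symmetric layer x layer correlation matrix with unit diagonal.
#' @export
layer_correlation <- function(m) {
  stopifnot(inherits(m, "annotation_matrix"))
  y <- -log10(m$p)
  sds <- apply(y, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(y))
  if (any(sds == 0)) {
    warning(sprintf("annotation layer(s) with zero variance: %s; correlations undefined (NA)",
                    paste(colnames(y)[sds == 0], collapse = ", ")), call. = FALSE)
    cc[sds == 0, ] <- NA_real_
    cc[, sds == 0] <- NA_real_
  }
  diag(cc) <- 1
  cc
}
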