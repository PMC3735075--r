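#' Standardize morphometric characters
#'
#' Centers each character to mean 0 and scales to variance 1 (sample
#' variance, divisor `n - 1`), computed over non-missing entries; missing
#' entries stay missing. Idempotent up to numerical tolerance.
#'
#' @param t Numeric matrix (specimens x characters) with specimen rownames.
#' @param drop_constant Drop zero-variance characters instead of erroring.
#' @return Standardized matrix of the same shape (minus dropped columns).
#' @export
standardize <- function(t, drop_constant = FALSE) {
  t <- as.matrix(t)
  sds <- apply(t, 2L, stats::sd, na.rm = TRUE)
  nn <- colSums(!is.na(t))
  if (any(nn < 2L)) {
    stop(sprintf("character(s) with fewer than 2 values: %s",
                 toString(colnames(t)[nn < 2L])))
  }
  zero <- !is.na(sds) & sds == 0
  if (any(zero)) {
    if (!drop_constant) {
      stop(sprintf("zero-variance character(s): %s",
                   toString(colnames(t)[zero])))
    }
    t <- t[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  scale(t, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Specimen distances on morphometric characters
#'
#' Euclidean distance between specimen vectors, pairwise-complete over
#' non-missing characters and rescaled by `sqrt(p / observed)` so partially
#' measured specimens remain comparable (the behaviour of
#' [stats::dist()]).
#'
#' @param t Standardized morphometric matrix.
#' @return A `stats::dist` object.
#' @export
morpho_dist <- function(t) {
  t <- as.matrix(t)
  all_na <- rowSums(!is.na(t)) == 0L
  if (any(all_na)) {
    stop(sprintf("specimen(s) with all characters missing: %s",
                 toString(rownames(t)[all_na])))
  }
  stats::dist(t, method = "euclidean")
}

#' Average-linkage dendrogram of specimens
#'
#' UPGMA-style agglomeration on Euclidean distances between (standardized)
#' character vectors. Average linkage on a metric yields non-decreasing
#' merge heights; a violation is reported as a warning rather than an
#' error.
#'
#' @param t Standardized morphometric matrix (see [standardize()]).
#' @return A `stats::hclust` object.
#' @export
average_linkage <- function(t) {
  hc <- stats::hclust(morpho_dist(t), method = "average")
  if (any(diff(hc$height) < -1e-8)) {
    warning("non-monotone merge heights in average-linkage dendrogram",
            call. = FALSE)
  }
  hc
}

#' Cut a dendrogram into morphospecies
#'
#' Either into exactly `k` clusters or at height `h` (all merges at height
#' `<= h` kept). Cluster labels are `MS_01`, `MS_02`, ... in order of first
#' appearance.
#'
#' @param d A `stats::hclust` dendrogram.
#' @param k Number of clusters (1..n), or
#' @param h Cut height (>= 0); exactly one of `k`/`h` must be given.
#' @return Named character vector (specimen id -> morphospecies label).
#' @export
cut_dendrogram <- function(d, k = NULL, h = NULL) {
  if (is.null(k) == is.null(h)) stop("supply exactly one of k or h")
  grp <- if (!is.null(k)) stats::cutree(d, k = k) else stats::cutree(d, h = h)
  relabel <- stats::setNames(sprintf("MS_%02d", seq_along(unique(grp))),
                             unique(grp))
  stats::setNames(unname(relabel[as.character(grp)]), names(grp))
}
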