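#' Count site patterns between two aligned sequences
#'
#' Sites where either sequence carries `N` or `-` are excluded (pairwise
#' deletion). Transitions are A<->G and C<->T; every other mismatch is a
#' transversion.
#'
#' @param a,b Equal-length character vectors (or single strings) over
#'   `A,C,G,T,N,-`.
#' @return A list of class `pairwise_comparison` with `L` (compared sites),
#'   `transitions`, `transversions`, and proportions `P`, `Q`.
#' @export
count_site_patterns <- function(a, b) {
  a <- .as_chars(a)
  b <- .as_chars(b)
  if (length(a) != length(b)) {
    stop("sequences must have equal aligned length")
  }
  ok <- a %in% .dna_core & b %in% .dna_core
  L <- sum(ok)
  if (L == 0L) stop("undefined comparison: no comparable sites (all N/gap)")
  a <- a[ok]
  b <- b[ok]
  diff <- a != b
  ts <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                    (a == "C" & b == "T") | (a == "T" & b == "C")))
  tv <- sum(diff) - ts
  structure(
    list(L = L, transitions = ts, transversions = tv, P = ts / L, Q = tv / L),
    class = "pairwise_comparison"
  )
}

.as_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "", fixed = TRUE)[[1L]] else x
}

#' Kimura two-parameter distance from transition/transversion proportions
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, the expected number of
#' substitutions per site correcting for multiple hits with distinct
#' transition (`P`) and transversion (`Q`) observed proportions.
#'
#' @param P Observed transition proportion(s).
#' @param Q Observed transversion proportion(s).
#' @param on_saturation What to do when a logarithm argument is <= 0
#'   (divergence beyond the model's reach): `"error"` (default) or
#'   `"undefined"`, which returns `NA` with a warning.
#' @return Distance(s) in substitutions per site.
#' @export
k2p_distance <- function(P, Q, on_saturation = c("error", "undefined")) {
  on_saturation <- match.arg(on_saturation)
  n <- max(length(P), length(Q))
  P <- rep_len(P, n)
  Q <- rep_len(Q, n)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  bad <- w1 <= 0 | w2 <= 0
  if (any(bad)) {
    if (on_saturation == "error") {
      stop(sprintf(
        "saturation error: K2P distance undefined for P=%g, Q=%g",
        P[bad][1L], Q[bad][1L]
      ))
    }
    warning(sprintf("%d saturated pair(s) flagged undefined", sum(bad)),
            call. = FALSE)
  }
  d <- rep(NA_real_, length(w1))
  d[!bad] <- -0.5 * log(w1[!bad] * sqrt(w2[!bad]))
  # exact zero for identical sequences (guards tiny negative rounding)
  d[!bad & P + Q == 0] <- 0
  d
}

#' Pairwise K2P distance matrix
#'
#' All pairs are computed by site-pattern counting with pairwise deletion
#' followed by the K2P closed form. Implemented with indicator-matrix cross
#' products so bootstrap replication stays cheap; the result is identical
#' to looping [count_site_patterns()] + [k2p_distance()] over pairs.
#'
#' @param aln A [barcode_alignment()] (or plain character matrix with
#'   rownames).
#' @param on_saturation Passed to [k2p_distance()]; with `"undefined"`,
#'   saturated or zero-overlap pairs become `NA` entries.
#' @return Symmetric numeric matrix (substitutions/site) with specimen ids
#'   as dimnames.
#' @export
distance_matrix <- function(aln, on_saturation = c("error", "undefined")) {
  on_saturation <- match.arg(on_saturation)
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- rownames(aln)
  X <- lapply(.dna_core, function(bb) (aln == bb) * 1)
  names(X) <- .dna_core
  V <- X$A + X$C + X$G + X$T
  L <- tcrossprod(V)
  ag <- tcrossprod(X$A, X$G)
  ct <- tcrossprod(X$C, X$T)
  ts <- ag + t(ag) + ct + t(ct)
  eq <- tcrossprod(X$A) + tcrossprod(X$C) + tcrossprod(X$G) + tcrossprod(X$T)
  tv <- L - eq - ts
  no_sites <- L == 0
  if (any(no_sites[upper.tri(no_sites)])) {
    if (on_saturation == "error") {
      stop("undefined comparison: a pair shares no comparable sites")
    }
    warning("pair(s) with no comparable sites flagged undefined", call. = FALSE)
    L[no_sites] <- 1 # placeholder; entries overwritten with NA below
  }
  P <- ts / L
  Q <- tv / L
  d <- suppressWarnings(
    matrix(k2p_distance(as.vector(P), as.vector(Q),
                        on_saturation = on_saturation), n, n)
  )
  if (on_saturation == "error" && anyNA(d)) {
    stop("saturation error: K2P undefined for at least one pair")
  }
  d[no_sites] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  off_all_na <- vapply(seq_len(n), function(i) all(is.na(d[i, -i])), logical(1))
  if (any(off_all_na)) {
    stop(sprintf(
      "fully undefined row(s): %s", toString(ids[off_all_na])
    ))
  }
  d
}

#' Base-composition statistics, overall and by codon position
#'
#' `N` and `-` are excluded from counts. Codon position of column `c` is
#' `((c - 1 - offset) mod 3) + 1`.
#'
#' @param aln A [barcode_alignment()].
#' @param reading_frame_offset 0, 1 or 2; column `1 + offset` is codon
#'   position 1.
#' @return List with `overall` (named frequency vector over A,C,G,T),
#'   `by_position` (3 x 4 matrix), `at_overall`, and `at_by_position`.
#' @export
composition_stats <- function(aln, reading_frame_offset = 0) {
  stopifnot(reading_frame_offset %in% 0:2)
  pos <- ((seq_len(ncol(aln)) - 1L - reading_frame_offset) %% 3L) + 1L
  count_freq <- function(cols) {
    tab <- table(factor(as.vector(aln[, cols, drop = FALSE]),
                        levels = .dna_core))
    tot <- sum(tab)
    if (tot == 0) return(stats::setNames(rep(NA_real_, 4L), .dna_core))
    stats::setNames(as.vector(tab) / tot, .dna_core)
  }
  overall <- count_freq(seq_len(ncol(aln)))
  by_pos <- t(vapply(1:3, function(p) count_freq(which(pos == p)),
                     numeric(4L)))
  rownames(by_pos) <- paste0("pos", 1:3)
  list(
    overall = overall,
    by_position = by_pos,
    at_overall = unname(overall["A"] + overall["T"]),
    at_by_position = unname(by_pos[, "A"] + by_pos[, "T"])
  )
}

#' Histogram of pairwise distances
#'
#' Bins the upper-triangle entries of a distance matrix into half-open
#' intervals `[lo, hi)`. Undefined (`NA`) pairs are dropped from the counts.
#'
#' @param m Distance matrix (proportions).
#' @param bin_width Bin width in proportion units (default 0.01 = 1%).
#' @return data.frame with `lower`, `upper`, `count`; counts sum to the
#'   number of defined upper-triangle pairs.
#' @export
distance_histogram <- function(m, bin_width = 0.01) {
  stopifnot(bin_width > 0)
  d <- m[upper.tri(m)]
  d <- d[!is.na(d)]
  idx <- floor(d / bin_width)
  nbin <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nbin)
  data.frame(
    lower = (seq_len(nbin) - 1L) * bin_width,
    upper = seq_len(nbin) * bin_width,
    count = counts
  )
}

#' Export a distance matrix as square CSV
#' @param m Distance matrix.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_distance_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Export a distance matrix in square PHYLIP format
#' @param m Distance matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_distance_phylip <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(
      formatC(rownames(m)[i], width = -12),
      paste(sprintf("%.8f", m[i, ]), collapse = " ")
    ), con)
  }
  invisible(path)
}
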