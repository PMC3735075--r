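#' Percent identity between two aligned sequences
#'
#' Identity = matching sites / compared sites, as a percentage, with
#' pairwise deletion of sites where either sequence has `N` or `-`.
#'
#' @param a,b Equal-length character vectors or strings.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  a <- .as_chars(a)
  b <- .as_chars(b)
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  ok <- a %in% .dna_core & b %in% .dna_core
  if (!any(ok)) stop("zero comparable sites between the two sequences")
  100 * sum(a[ok] == b[ok]) / sum(ok)
}

#' Assign species names to MOTUs from a local reference library
#'
#' For each MOTU, the best [pairwise_identity()] over all (member,
#' reference) pairs is found; the reference's name is assigned when the
#' best identity reaches `min_identity`, otherwise the MOTU is reported as
#' `"unidentified"`. Exact identity ties are broken by the first reference
#' in file order and flagged in the `tie` column.
#'
#' @param motus A `motu_result` or named partition (id -> MOTU label).
#' @param aln The query [barcode_alignment()] containing the MOTU members.
#' @param ref A [barcode_alignment()] of named reference barcodes, aligned
#'   to the same coordinates as `aln` (record names are taken as species
#'   names).
#' @param min_identity Minimum percent identity for a name (default 95).
#' @return data.frame with one row per MOTU: `motu`, `best_reference`,
#'   `best_identity`, `name`, `tie`.
#' @export
assign_names <- function(motus, aln, ref, min_identity = 95) {
  mp <- .as_partition(motus)
  motu_labels <- unique(mp)
  if (is.null(ref) || nrow(ref) == 0L) {
    warning("empty reference library: all MOTUs unidentified", call. = FALSE)
    return(data.frame(
      motu = motu_labels, best_reference = NA_character_,
      best_identity = NA_real_, name = "unidentified", tie = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  if (ncol(ref) != ncol(aln)) {
    stop("reference sequences must be aligned to the query coordinates")
  }
  ref_names <- rownames(ref)
  rows <- lapply(motu_labels, function(cl) {
    members <- names(mp)[mp == cl]
    idents <- sapply(ref_names, function(rn) {
      max(vapply(members, function(id) {
        tryCatch(pairwise_identity(aln[id, ], ref[rn, ]),
                 error = function(e) NA_real_)
      }, numeric(1)), na.rm = TRUE)
    })
    best <- max(idents)
    hits <- ref_names[idents == best]
    tie <- length(hits) > 1L
    if (tie) {
      message(sprintf(
        "MOTU %s: identity tie at %.2f%% between %s; keeping '%s' (file order)",
        cl, best, toString(hits), hits[1L]
      ))
    }
    data.frame(
      motu = cl, best_reference = hits[1L], best_identity = best,
      name = if (best >= min_identity) hits[1L] else "unidentified",
      tie = tie, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
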