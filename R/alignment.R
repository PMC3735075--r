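#' @keywords internal
"_PACKAGE"

# Characters accepted in input sequences. Ambiguity codes other than N are
# collapsed to N on read; anything else is rejected.
.dna_core <- c("A", "C", "G", "T")
.dna_keep <- c(.dna_core, "N", "-")
.dna_ambig <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a barcode alignment
#'
#' An alignment is stored as a character matrix with one row per specimen
#' (rownames are the specimen ids) and one column per site, over the
#' alphabet `A, C, G, T, N, -`. Optional per-specimen morphospecies labels
#' and site (locality) strings travel with the object as attributes.
#'
#' @param seqs Character matrix of single characters, or a named character
#'   vector of equal-length sequence strings.
#' @param labels Optional character vector of morphospecies labels, one per
#'   specimen (NA allowed).
#' @param sites Optional character vector of locality strings.
#' @return An object of class `barcode_alignment`.
#' @export
barcode_alignment <- function(seqs, labels = NULL, sites = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    ids <- names(seqs)
    if (is.null(ids) || any(!nzchar(ids))) {
      stop("sequence vector must be named by nonempty specimen ids")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- ids[lens != lens[1L]][1L]
      stop(sprintf(
        "alignment error: record '%s' has length %d, expected %d",
        bad, nchar(seqs[[bad]]), lens[1L]
      ))
    }
    seqs <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(seqs) <- ids
  }
  if (!is.matrix(seqs) || !is.character(seqs)) {
    stop("seqs must be a character matrix or named character vector")
  }
  if (nrow(seqs) < 1L || ncol(seqs) < 1L) stop("alignment must be non-empty")
  ids <- rownames(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all specimen ids must be nonempty")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate specimen id: '%s'", ids[duplicated(ids)][1L]))
  }
  bad <- setdiff(unique(as.vector(seqs)), .dna_keep)
  if (length(bad) > 0L) {
    stop(sprintf("invalid character(s) in alignment: %s", toString(bad)))
  }
  structure(seqs,
    labels = labels, sites = sites,
    class = c("barcode_alignment", "matrix", "array")
  )
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf(
    "barcode_alignment: %d sequences x %d sites\n", nrow(x), ncol(x)
  ))
  show <- utils::head(rownames(x), 5L)
  for (id in show) {
    cat(sprintf(
      "  %-20s %s%s\n", id,
      paste(x[id, seq_len(min(40L, ncol(x)))], collapse = ""),
      if (ncol(x) > 40L) "..." else ""
    ))
  }
  if (nrow(x) > 5L) cat(sprintf("  ... and %d more\n", nrow(x) - 5L))
  invisible(x)
}

#' Specimen ids of an alignment
#' @param aln A `barcode_alignment`.
#' @return Character vector of specimen ids.
#' @export
specimen_ids <- function(aln) rownames(aln)

# Normalize raw sequence characters: uppercase, U -> T, ambiguity -> N.
# Returns the cleaned vector; errors on characters outside the IUPAC set.
.normalize_chars <- function(chars, id) {
  chars <- toupper(chars)
  chars[chars == "U"] <- "T"
  is_ambig <- chars %in% .dna_ambig
  if (any(is_ambig)) {
    warning(sprintf(
      "record '%s': %d IUPAC ambiguity code(s) collapsed to N",
      id, sum(is_ambig)
    ), call. = FALSE)
    chars[is_ambig] <- "N"
  }
  bad <- setdiff(unique(chars), .dna_keep)
  if (length(bad) > 0L) {
    stop(sprintf(
      "record '%s' contains invalid character(s): %s", id, toString(bad)
    ), call. = FALSE)
  }
  chars
}
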