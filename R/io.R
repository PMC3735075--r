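#' Read an aligned FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, IUPAC ambiguity codes
#' other than `N` are collapsed to `N` with a warning, and any character
#' outside the IUPAC nucleotide set is rejected. All records must share one
#' length; the offending record is named otherwise. Morphospecies labels are
#' parsed from the ids with [parse_label()] (the default pattern matches
#' ids such as `JHB03285G01`, whose first five characters encode the
#' morphospecies).
#'
#' @param path Path to a FASTA file of aligned nucleotide sequences.
#' @param label_pattern Regex with one capture group handed to
#'   [parse_label()]; `NULL` disables label parsing.
#' @return A [barcode_alignment()].
#' @export
read_fasta <- function(path, label_pattern = default_label_pattern()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  recs <- seqinr::read.fasta(path,
    seqtype = "DNA", as.string = FALSE,
    forceDNAtolower = FALSE, set.attributes = FALSE
  )
  if (length(recs) == 0L) stop(sprintf("format error: no FASTA records in %s", path))
  ids <- names(recs)
  lens <- lengths(recs)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf(
      "alignment error: record '%s' has length %d, expected %d",
      ids[bad], lens[bad], lens[1L]
    ))
  }
  mat <- do.call(rbind, lapply(seq_along(recs), function(i) {
    .normalize_chars(recs[[i]], ids[i])
  }))
  rownames(mat) <- ids
  labels <- NULL
  if (!is.null(label_pattern)) {
    labels <- parse_label(ids, label_pattern)$label
  }
  barcode_alignment(mat, labels = labels)
}

#' Write an alignment to FASTA
#'
#' @param aln A [barcode_alignment()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(aln, path) {
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
    names = rownames(aln), file.out = path, nbchar = 80
  )
  invisible(path)
}

#' Default specimen-id pattern for morphospecies labels
#'
#' Matches ids whose leading `JHB` plus two digits encode the
#' morphospecies, e.g. `JHB03285G01` carries label `JHB03`.
#'
#' @return A regex string with one capture group.
#' @export
default_label_pattern <- function() "^(JHB[0-9]{2})"

#' Parse morphospecies labels out of specimen ids
#'
#' Total function: ids that do not match the pattern get `NA` label and
#' remainder; no input ever raises an error.
#'
#' @param id Character vector of specimen ids.
#' @param pattern Regex whose first capture group is the morphospecies
#'   label; the rest of the id is returned as the remainder.
#' @return A data.frame with columns `id`, `label`, `remainder`.
#' @export
parse_label <- function(id, pattern = default_label_pattern()) {
  m <- regexec(pattern, id)
  label <- rep(NA_character_, length(id))
  remainder <- rep(NA_character_, length(id))
  for (i in seq_along(id)) {
    hit <- regmatches(id[i], m[i])[[1L]]
    if (length(hit) >= 2L && nzchar(hit[2L])) {
      label[i] <- hit[2L]
      remainder[i] <- sub(pattern, "", id[i])
    }
  }
  data.frame(id = id, label = label, remainder = remainder,
             stringsAsFactors = FALSE)
}

#' Read a specimen metadata table
#'
#' CSV with columns `id`, `label` and optionally `site`. When supplied to
#' the pipeline, these labels override any parsed from sequence ids.
#'
#' @param path CSV path.
#' @return data.frame with columns `id`, `label`, `site`.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("metadata missing column(s): %s", toString(miss)))
  }
  if (anyDuplicated(tab$id)) stop("metadata ids must be unique")
  if (any(is.na(tab$label) | !nzchar(tab$label))) {
    stop("metadata labels must be nonempty")
  }
  if (is.null(tab$site)) tab$site <- NA_character_
  tab[, c("id", "label", "site")]
}

#' Write a tree to Newick
#'
#' Branch lengths are written to 6 decimal places and internal-node support
#' labels verbatim, so that `read_newick(write_newick(t))` preserves
#' topology, lengths (to 1e-6) and supports exactly.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file path.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop(sprintf("format error: no tree in %s", path))
  tr
}

#' The 16 morphometric characters
#'
#' Worker measurements (mm) used to sort specimens into morphospecies:
#' head and eye dimensions, appendage lengths, mesosoma and waist widths.
#'
#' @return Character vector of the 16 expected column names.
#' @export
morphometric_characters <- function() {
  c(
    "head_width", "distance_between_eyes", "head_length",
    "anterior_head_length", "scape_length", "mandible_length",
    "eye_length", "eye_width", "mesosoma_length",
    "promesonotal_groove_depth", "propodeal_spine_length",
    "femur_length", "tibia_length", "propodeal_spiracle_width",
    "petiole_width", "postpetiole_width"
  )
}

#' Read a morphometric table
#'
#' Expects a CSV with an `id` column plus exactly the 16 character columns
#' of [morphometric_characters()] (any order). Cells that are empty or `NA`
#' become missing values, never zeros.
#'
#' @param path CSV path.
#' @return Numeric matrix (specimens x 16) with specimen ids as rownames.
#' @export
read_morphometrics <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(tab)) stop("morphometric table needs an 'id' column")
  chars <- morphometric_characters()
  have <- setdiff(names(tab), "id")
  miss <- setdiff(chars, have)
  extra <- setdiff(have, chars)
  if (length(miss) > 0L || length(extra) > 0L) {
    stop(sprintf(
      paste0(
        "schema error: morphometric table must have exactly the 16 columns\n",
        "  expected: %s\n  missing: %s\n  unknown: %s"
      ),
      toString(chars),
      if (length(miss)) toString(miss) else "(none)",
      if (length(extra)) toString(extra) else "(none)"
    ))
  }
  if (anyDuplicated(tab$id)) stop("morphometric specimen ids must be unique")
  m <- as.matrix(tab[, chars])
  if (!is.numeric(m)) stop("morphometric characters must be numeric")
  rownames(m) <- tab$id
  m
}

#' Write a morphometric table
#' @param m Numeric matrix with specimen rownames (see [read_morphometrics()]).
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_morphometrics <- function(m, path) {
  tab <- data.frame(id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a partition to CSV
#' @param partition Named character vector (specimen id -> cluster label).
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.csv(
    data.frame(id = names(partition), cluster = unname(partition),
               stringsAsFactors = FALSE),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read a partition written by [write_partition()]
#' @param path CSV path.
#' @return Named character vector (specimen id -> cluster label).
#' @export
read_partition <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(tab$cluster), tab$id)
}
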