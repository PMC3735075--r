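#' Score congruence between MOTUs and morphospecies
#'
#' A MOTU "matches" if and only if its member set is exactly equal to one
#' morphospecies' member set. Match success is the matched count divided by
#' the number of MOTUs (displayed rounded to the nearest integer percent;
#' the exact fraction is retained). Discordant cases are classified as
#' merges (a MOTU containing more than one morphospecies) and splits (a
#' morphospecies spanning more than one MOTU); morphospecies untouched by
#' any MOTU match or discordance are surfaced as `unaccounted_morpho`
#' rather than silently reconciled.
#'
#' @param motus A `motu_result` or a named character partition
#'   (id -> MOTU label).
#' @param morpho Named character partition (id -> morphospecies label).
#' @return A `congruence_report` list; see Details.
#' @export
match_success <- function(motus, morpho) {
  mp <- .as_partition(motus)
  ids_m <- sort(names(mp))
  ids_o <- sort(names(morpho))
  if (!identical(ids_m, ids_o)) {
    diffs <- c(setdiff(ids_m, ids_o), setdiff(ids_o, ids_m))
    stop(sprintf("partitions cover different ids: %s", toString(diffs)))
  }
  motu_sets <- .cluster_sets(mp)
  morpho_sets <- .cluster_sets(morpho)
  morpho_keys <- vapply(morpho_sets, paste, character(1), collapse = "\r")
  motu_keys <- vapply(motu_sets, paste, character(1), collapse = "\r")
  matched <- names(motu_sets)[motu_keys %in% morpho_keys]
  # morphospecies composition of each MOTU and vice versa
  n_morpho_in_motu <- vapply(motu_sets, function(s) {
    length(unique(morpho[s]))
  }, integer(1))
  n_motu_in_morpho <- vapply(morpho_sets, function(s) {
    length(unique(mp[s]))
  }, integer(1))
  merges <- names(motu_sets)[n_morpho_in_motu > 1L]
  splits <- names(morpho_sets)[n_motu_in_morpho > 1L]
  sizes <- lengths(motu_sets)
  matched_morpho <- names(morpho_sets)[morpho_keys %in% motu_keys]
  unaccounted <- setdiff(names(morpho_sets), c(matched_morpho, splits))
  unaccounted <- unaccounted[!vapply(unaccounted, function(ms) {
    any(vapply(motu_sets[merges], function(s) {
      all(morpho_sets[[ms]] %in% s)
    }, logical(1)))
  }, logical(1))]
  res <- list(
    n_motus = length(motu_sets),
    n_morphospecies = length(morpho_sets),
    matched = length(matched),
    matched_motus = matched,
    match_success = length(matched) / length(motu_sets),
    match_success_pct = round(100 * length(matched) / length(motu_sets)),
    merges = merges,
    splits = splits,
    singleton_motus = names(motu_sets)[sizes == 1L],
    unaccounted_morpho = unaccounted
  )
  class(res) <- "congruence_report"
  res
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf(
    "congruence_report: %d of %d MOTUs match a morphospecies (%d%% match success)\n",
    x$matched, x$n_motus, x$match_success_pct
  ))
  cat(sprintf("  morphospecies: %d; merged MOTUs: %s; split morphospecies: %s\n",
              x$n_morphospecies,
              if (length(x$merges)) toString(x$merges) else "none",
              if (length(x$splits)) toString(x$splits) else "none"))
  if (length(x$unaccounted_morpho)) {
    cat(sprintf("  unaccounted morphospecies: %s\n",
                toString(x$unaccounted_morpho)))
  }
  invisible(x)
}

#' Annotate discordant cases with their divergences
#'
#' Each merge (MOTU holding several morphospecies) is annotated with the
#' mean K2P divergence between the morphospecies groups inside the MOTU;
#' each split (morphospecies spread over several MOTUs) with the mean
#' divergence between its MOTU groups.
#'
#' @param motus A `motu_result` or named partition.
#' @param morpho Named morphospecies partition.
#' @param m K2P distance matrix (proportions).
#' @return List with data.frames `merges` (`motu`, `n_morphospecies`,
#'   `mean_divergence`) and `splits` (`morphospecies`, `n_motus`,
#'   `mean_divergence`); divergences in proportions.
#' @export
classify_discordance <- function(motus, morpho, m) {
  mp <- .as_partition(motus)
  rep0 <- match_success(mp, morpho)
  cross_mean <- function(members, grouping) {
    sm <- m[members, members, drop = FALSE]
    g <- grouping[members]
    diffg <- outer(g, g, "!=")
    mean(sm[upper.tri(sm) & diffg])
  }
  merges <- data.frame(
    motu = rep0$merges,
    n_morphospecies = vapply(rep0$merges, function(cl) {
      length(unique(morpho[names(mp)[mp == cl]]))
    }, integer(1)),
    mean_divergence = vapply(rep0$merges, function(cl) {
      cross_mean(names(mp)[mp == cl], morpho)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  splits <- data.frame(
    morphospecies = rep0$splits,
    n_motus = vapply(rep0$splits, function(cl) {
      length(unique(mp[names(morpho)[morpho == cl]]))
    }, integer(1)),
    mean_divergence = vapply(rep0$splits, function(cl) {
      cross_mean(names(morpho)[morpho == cl], mp)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(merges = merges, splits = splits, report = rep0)
}

.as_partition <- function(x) {
  if (inherits(x, "motu_result")) x$partition else x
}

.cluster_sets <- function(partition) {
  lapply(split(names(partition), partition), sort)
}
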