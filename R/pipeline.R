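#' Run the full barcode-to-MOTU pipeline
#'
#' Orchestrates all stages in analysis order — distances, composition,
#' histogram, NJ tree with bootstrap, MOTU delineation at each threshold,
#' within/between summary, congruence against morphospecies, and reference
#' naming — and writes every result as a plain-text artifact re-readable
#' by this package's own readers, plus a run log that records the
#' parameters and seed needed to reproduce the run exactly. A stage
#' failure is reported with its stage name; artifacts written before the
#' failure are preserved.
#'
#' Morphospecies labels come from, in order of precedence: the `metadata`
#' table, labels parsed from sequence ids, or average-linkage clustering
#' of `morphometrics` cut at `k_morpho`.
#'
#' @param fasta Path to an aligned FASTA, or `NULL` to use `scenario`.
#' @param scenario `"paper"` or `"discordant"`: generate a synthetic
#'   dataset with [paper_scale_scenario()] / [discordant_scenario()]
#'   seeded by `seed`.
#' @param out_dir Output directory (created if needed).
#' @param thresholds MOTU thresholds in percent (default `c(2, 3)`).
#' @param bootstrap Bootstrap replicate count; 0 skips bootstrapping.
#' @param seed Integer seed for bootstrap (and scenario generation).
#' @param outgroup Optional outgroup tip ids (rooted there, excluded from
#'   MOTU delineation).
#' @param metadata Optional metadata CSV path (see [read_metadata()]).
#' @param reference Optional reference FASTA of named barcodes.
#' @param morphometrics Optional morphometric CSV path; for synthetic
#'   scenarios the generated table is used automatically.
#' @param k_morpho Number of morphospecies for the dendrogram cut; for
#'   synthetic scenarios defaults to the true species count.
#' @param min_identity Naming identity threshold, percent (default 95).
#' @return Invisibly, a list with every intermediate object (`alignment`,
#'   `distance_matrix`, `tree`, `motus` per threshold, `congruence`,
#'   `discordance`, `naming`, `composition`, `histogram`, `morpho_partition`).
#' @export
run_pipeline <- function(fasta = NULL, scenario = NULL, out_dir,
                         thresholds = c(2, 3), bootstrap = 1000, seed = 1,
                         outgroup = NULL, metadata = NULL, reference = NULL,
                         morphometrics = NULL, k_morpho = NULL,
                         min_identity = 95) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  res <- list()

  morpho_tab <- NULL
  res$alignment <- stage("input", {
    if (!is.null(fasta)) {
      read_fasta(fasta)
    } else if (!is.null(scenario)) {
      scen <- switch(scenario,
        paper = paper_scale_scenario(seed = seed),
        discordant = discordant_scenario(seed = seed),
        stop(sprintf("unknown scenario '%s'", scenario))
      )
      res$truth <- scen$truth
      morpho_tab <- scen$morphometrics
      write_fasta(scen$alignment, file.path(out_dir, "alignment.fasta"))
      write_morphometrics(morpho_tab,
                          file.path(out_dir, "morphometrics.csv"))
      scen$alignment
    } else {
      stop("supply a fasta path or a scenario name")
    }
  })
  if (!is.null(morphometrics)) {
    morpho_tab <- stage("morphometrics-input", read_morphometrics(morphometrics))
  }

  res$distance_matrix <- stage("distances", distance_matrix(res$alignment))
  stage("distances-export", {
    write_distance_csv(res$distance_matrix,
                       file.path(out_dir, "distance_matrix.csv"))
    write_distance_phylip(res$distance_matrix,
                          file.path(out_dir, "distance_matrix.phy"))
  })
  res$composition <- stage("composition", composition_stats(res$alignment))
  stage("composition-export", {
    comp <- cbind(
      data.frame(position = c("overall", "pos1", "pos2", "pos3")),
      rbind(res$composition$overall, res$composition$by_position),
      AT = c(res$composition$at_overall, res$composition$at_by_position)
    )
    utils::write.csv(comp, file.path(out_dir, "composition.csv"),
                     row.names = FALSE)
  })
  res$histogram <- stage("histogram",
                         distance_histogram(res$distance_matrix))
  utils::write.csv(res$histogram, file.path(out_dir, "distance_histogram.csv"),
                   row.names = FALSE)

  res$tree <- stage("tree", {
    if (bootstrap > 0) {
      bootstrap_support(res$alignment, B = bootstrap, seed = seed)
    } else {
      nj_tree(res$distance_matrix)
    }
  })
  if (!is.null(outgroup)) {
    res$tree_rooted <- stage("rooting", root_at_outgroup(res$tree, outgroup))
  }
  stage("tree-export",
        write_newick(res$tree, file.path(out_dir, "nj_tree.nwk")))

  res$motus <- stage("motu", {
    out <- lapply(thresholds, function(thr) {
      mr <- tree_guided_motus(res$tree, res$distance_matrix, thr,
                              outgroup = outgroup)
      write_partition(mr$partition,
                      file.path(out_dir, sprintf("motu_%gpct.csv", thr)))
      mr
    })
    names(out) <- sprintf("pct%g", thresholds)
    out
  })
  stage("within-between-export", {
    wb <- do.call(rbind, lapply(res$motus, function(mr) {
      data.frame(threshold = mr$threshold, n_motus = mr$n_motus,
                 mean_within_pct = 100 * mr$mean_within,
                 mean_between_pct = 100 * mr$mean_between,
                 ratio = mr$ratio)
    }))
    utils::write.csv(wb, file.path(out_dir, "within_between.csv"),
                     row.names = FALSE)
  })

  res$morpho_partition <- stage("morphospecies", {
    ids <- specimen_ids(res$alignment)
    if (!is.null(metadata)) {
      md <- read_metadata(metadata)
      stats::setNames(md$label, md$id)[ids]
    } else {
      labels <- attr(res$alignment, "labels")
      if (!is.null(labels) && !anyNA(labels)) {
        stats::setNames(labels, ids)
      } else if (!is.null(morpho_tab)) {
        k <- if (!is.null(k_morpho)) k_morpho else
          length(unique(res$truth$partition))
        cut_dendrogram(average_linkage(standardize(morpho_tab)), k = k)[ids]
      } else {
        NULL
      }
    }
  })
  if (!is.null(res$morpho_partition)) {
    first <- res$motus[[1L]]
    res$congruence <- stage("congruence",
                            match_success(first, res$morpho_partition))
    res$discordance <- stage("discordance", classify_discordance(
      first, res$morpho_partition, res$distance_matrix
    ))
    stage("congruence-export", {
      con <- file(file.path(out_dir, "congruence.txt"), "w")
      sink(con); print(res$congruence); sink(); close(con)
      per <- data.frame(
        motu = sort(unique(res$congruence$matched_motus)),
        outcome = "matched", stringsAsFactors = FALSE
      )
      if (length(res$congruence$merges)) {
        per <- rbind(per, data.frame(motu = res$congruence$merges,
                                     outcome = "merge"))
      }
      utils::write.csv(per, file.path(out_dir, "congruence_per_motu.csv"),
                       row.names = FALSE)
      if (nrow(res$discordance$merges) || nrow(res$discordance$splits)) {
        utils::write.csv(res$discordance$merges,
                         file.path(out_dir, "discordance_merges.csv"),
                         row.names = FALSE)
        utils::write.csv(res$discordance$splits,
                         file.path(out_dir, "discordance_splits.csv"),
                         row.names = FALSE)
      }
    })
  }

  if (!is.null(reference)) {
    ref <- stage("reference-input", read_fasta(reference, label_pattern = NULL))
    res$naming <- stage("naming", assign_names(
      res$motus[[1L]], res$alignment, ref, min_identity = min_identity
    ))
    utils::write.csv(res$naming, file.path(out_dir, "motu_names.csv"),
                     row.names = FALSE)
  }

  stage("run-log", {
    log <- c(
      sprintf("motubar %s / R %s", utils::packageVersion("motubar"),
              getRversion()),
      sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("input: %s", if (!is.null(fasta)) fasta else
        sprintf("scenario '%s'", scenario)),
      sprintf("seed: %s", format(seed)),
      sprintf("thresholds (pct): %s", toString(thresholds)),
      sprintf("bootstrap replicates: %s", format(bootstrap)),
      sprintf("outgroup: %s",
              if (is.null(outgroup)) "none" else toString(outgroup)),
      sprintf("min_identity: %g", min_identity)
    )
    writeLines(log, file.path(out_dir, "run_log.txt"))
  })
  invisible(res)
}
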