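#' Classify a sample pair into an assembly process
#'
#' Applies the two-step null-model decision rule: `bnti > +2` gives variable
#' selection, `bnti < -2` homogeneous selection; otherwise the pair is
#' stochastic and RC-bray decides — `rc > +0.95` dispersal limitation,
#' `rc < -0.95` homogenizing dispersal, and anything in between
#' undominated. Boundary values (betaNTI exactly +/-2, RC exactly +/-0.95)
#' fall to the weaker, non-selection/undominated side. Vectorized;
#' non-finite `bnti` yields `NA` (pair unclassifiable).
#'
#' @param bnti numeric vector of betaNTI values.
#' @param rc numeric vector of RC-bray values, recycled; only consulted when
#'   `|bnti| <= 2`.
#' @return factor with levels `variable_selection`, `homogeneous_selection`,
#'   `dispersal_limitation`, `homogenizing_dispersal`, `undominated`.
#' @export
#' @examples
#' classify_pair(c(2.5, -2.5, 1.0, 0), c(0, 0, 0.97, 0))
classify_pair <- function(bnti, rc = NA_real_) {
  n <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, n)
  rc <- rep_len(rc, n)
  out <- rep(NA_character_, n)
  ok <- is.finite(bnti)
  out[ok & bnti > 2] <- "variable_selection"
  out[ok & bnti < -2] <- "homogeneous_selection"
  mid <- ok & abs(bnti) <= 2
  if (any(mid & !is.finite(rc)))
    warning("RC-bray missing for ", sum(mid & !is.finite(rc)),
            " pair(s) with |betaNTI| <= 2; left unclassified")
  out[mid & is.finite(rc) & rc > 0.95] <- "dispersal_limitation"
  out[mid & is.finite(rc) & rc < -0.95] <- "homogenizing_dispersal"
  out[mid & is.finite(rc) & abs(rc) <= 0.95] <- "undominated"
  factor(out, levels = process_levels())
}

process_levels <- function() {
  c("variable_selection", "homogeneous_selection", "dispersal_limitation",
    "homogenizing_dispersal", "undominated")
}

#' Assemble the per-pair turnover record
#'
#' Joins betaNTI and RC-bray results with sample metadata into the long
#' table consumed by [aggregate_processes()].
#'
#' @param bn a `beta_nti` object.
#' @param rc a `rc_bray` object over the same samples.
#' @param metadata data.frame with `sample_id`, `stage`, `time` (see
#'   [read_sample_metadata()]).
#' @param component label attached to every row (`"rare"`, `"common"` or
#'   `"whole"`).
#' @return data.frame, one row per unordered pair: ids, group labels,
#'   `bnti`, `rc_bray`, `process`.
#' @export
pairwise_turnover <- function(bn, rc, metadata, component = "whole") {
  df <- as.data.frame(bn)
  rcdf <- as.data.frame(rc)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  df$rc_bray <- rcdf$rc_bray[match(key(df$sample_a, df$sample_b),
                                   key(rcdf$sample_a, rcdf$sample_b))]
  i_a <- match(df$sample_a, metadata$sample_id)
  i_b <- match(df$sample_b, metadata$sample_id)
  if (anyNA(i_a) || anyNA(i_b)) stop("samples missing from metadata")
  df$stage_a <- metadata$stage[i_a]
  df$stage_b <- metadata$stage[i_b]
  df$time_a <- metadata$time[i_a]
  df$time_b <- metadata$time[i_b]
  df$component <- component
  df$process <- classify_pair(df$bnti, df$rc_bray)
  df
}

#' Aggregate pairwise classifications into process percentages
#'
#' Converts classified pairs into the relative influence of each assembly
#' process. Groupings: `"all"` uses every pair; `"within_stage"` (temporal
#' turnover) keeps pairs from the same successional stage;
#' `"within_time"` (spatial turnover) keeps pairs sampled at the same time
#' but from different stages. Pairs with `NA` classification are excluded
#' from denominators and reported as `n_unclassifiable`.
#'
#' @param pairs data.frame from [pairwise_turnover()].
#' @param grouping one of `"all"`, `"within_stage"`, `"within_time"`.
#' @param by_level also split the report by stage (within_stage) or time
#'   (within_time) level?
#' @return data.frame with `component`, `grouping`, `level`, one percentage
#'   column per process (summing to 100 per row), `n_pairs`,
#'   `n_unclassifiable`.
#' @export
aggregate_processes <- function(pairs,
                                grouping = c("all", "within_stage",
                                             "within_time"),
                                by_level = FALSE) {
  grouping <- match.arg(grouping)
  sel <- switch(grouping,
    all = rep(TRUE, nrow(pairs)),
    within_stage = pairs$stage_a == pairs$stage_b,
    within_time = pairs$time_a == pairs$time_b &
      pairs$stage_a != pairs$stage_b)
  sub <- pairs[sel, , drop = FALSE]
  if (!nrow(sub)) {
    warning("no pairs in grouping '", grouping, "'; empty report")
    return(data.frame())
  }
  lev <- if (!by_level) rep("all", nrow(sub))
         else if (grouping == "within_stage") as.character(sub$stage_a)
         else if (grouping == "within_time") as.character(sub$time_a)
         else rep("all", nrow(sub))
  do.call(rbind, lapply(split(seq_len(nrow(sub)), lev), function(ix) {
    s <- sub[ix, , drop = FALSE]
    cls <- s$process
    n_un <- sum(is.na(cls))
    n_ok <- sum(!is.na(cls))
    pct <- if (n_ok) 100 * table(cls) / n_ok else table(cls) * NA_real_
    out <- data.frame(component = s$component[1], grouping = grouping,
                      level = lev[ix[1]], stringsAsFactors = FALSE)
    for (p in process_levels()) out[[p]] <- as.numeric(pct[p])
    out$n_pairs <- n_ok
    out$n_unclassifiable <- n_un
    out
  }))
}

#' Run the full assembly-inference pipeline
#'
#' Orchestrates rarefaction, biosphere partitioning, rarity typing, betaNTI
#' and RC-bray per community component, pair classification and aggregation
#' into an assembly report. Deterministic under a fixed seed.
#'
#' @param table `feature_table` (or count matrix) of the whole community.
#' @param metadata sample metadata data.frame (`sample_id`, `stage`, `time`,
#'   `replicate`).
#' @param tree rooted `phylo` with branch lengths covering the table taxa.
#' @param depth rarefaction depth; `NULL` skips rarefaction (table must
#'   already have uniform column sums).
#' @param cutoff rarity cutoff passed to [partition_biospheres()]; may be a
#'   vector of several fixed cutoffs, producing one report set each.
#' @param recalibrate,direction see [partition_biospheres()].
#' @param components which community components to analyze.
#' @param groupings which pair groupings to report.
#' @param n_null_bnti,n_null_rc null replicates for betaNTI and RC-bray.
#' @param full_tree_null shuffle tips across the full supplied tree instead
#'   of the pruned (observed-taxa) tree in the betaNTI null; appropriate
#'   when the tree represents a known regional pool, as for
#'   [simulate_dataset()] output.
#' @param seed master seed for rarefaction and both null models.
#' @param min_taxa_per_sample samples whose component community retains
#'   fewer taxa than this are dropped from that component with a warning.
#' @param out_dir optional directory; when given, writes `report.tsv`,
#'   `pairwise.tsv`, `types.tsv`, `cutoffs.tsv` and `manifest.json`.
#' @return list of class `assembly_run`: `report` (data.frame over cutoffs,
#'   components, groupings), `pairwise`, `types`, `cutoffs`, `partitions`.
#' @export
run_full_analysis <- function(table, metadata, tree, depth = NULL,
                              cutoff = 0.001, recalibrate = FALSE,
                              direction = "multiply",
                              components = c("rare", "common", "whole"),
                              groupings = c("all", "within_stage",
                                            "within_time"),
                              n_null_bnti = 999, n_null_rc = 999,
                              full_tree_null = FALSE,
                              seed = 1, min_taxa_per_sample = 2,
                              out_dir = NULL) {
  table <- as_feature_table(table)
  if (!is.null(depth)) {
    table <- rarefy_table(table, depth, seed = seed)
  } else if (!table$is_rarefied) {
    cs <- colSums(table$counts)
    if (length(unique(cs)) != 1)
      stop("table is not rarefied and no `depth` given")
    table <- feature_table(table$counts, is_rarefied = TRUE)
  }
  metadata <- metadata[match(colnames(table$counts), metadata$sample_id), ,
                       drop = FALSE]
  if (anyNA(metadata$sample_id)) stop("metadata missing retained samples")

  cutoffs <- if (is.character(cutoff)) list(cutoff) else as.list(cutoff)
  all_reports <- list(); all_pairs <- list(); all_types <- list()
  all_cutoffs <- list(); partitions <- list()

  for (ci in seq_along(cutoffs)) {
    co <- cutoffs[[ci]]
    co_label <- if (is.character(co)) co else format(co)
    part <- partition_biospheres(table, cutoff = co,
                                 recalibrate = recalibrate,
                                 direction = direction)
    partitions[[co_label]] <- part
    ty <- classify_rarity_types(part)
    ty$cutoff <- co_label
    all_types[[co_label]] <- ty
    cdf <- part$cutoffs; cdf$cutoff <- co_label
    all_cutoffs[[co_label]] <- cdf

    comp_tables <- list(rare = part$rare, common = part$common,
                        whole = table)
    for (comp in components) {
      m <- ft_counts(comp_tables[[comp]])
      m <- m[rowSums(m) > 0, , drop = FALSE]
      keep <- colSums(m > 0) >= min_taxa_per_sample
      if (!all(keep))
        warning(sum(!keep), " sample(s) dropped from component '", comp,
                "' (fewer than ", min_taxa_per_sample, " taxa)")
      m <- m[, keep, drop = FALSE]
      if (ncol(m) < 2) {
        warning("component '", comp, "' has < 2 usable samples; skipped")
        next
      }
      bn <- beta_nti(m, tree = tree, n_null = n_null_bnti,
                     prune = !full_tree_null, seed = seed + 1000 * ci)
      rcv <- rc_bray(m, n_null = n_null_rc, seed = seed + 1000 * ci + 1)
      pw <- pairwise_turnover(bn, rcv, metadata, component = comp)
      pw$cutoff <- co_label
      all_pairs[[paste(co_label, comp)]] <- pw
      for (g in groupings) {
        rep_g <- aggregate_processes(pw, grouping = g)
        if (nrow(rep_g)) {
          rep_g$cutoff <- co_label
          all_reports[[paste(co_label, comp, g)]] <- rep_g
        }
      }
    }
  }
  res <- structure(list(
    report = do.call(rbind, c(all_reports, list(make.row.names = FALSE))),
    pairwise = do.call(rbind, c(all_pairs, list(make.row.names = FALSE))),
    types = do.call(rbind, c(all_types, list(make.row.names = FALSE))),
    cutoffs = do.call(rbind, c(all_cutoffs, list(make.row.names = FALSE))),
    partitions = partitions,
    config = list(depth = depth, cutoff = cutoff, recalibrate = recalibrate,
                  n_null_bnti = n_null_bnti, n_null_rc = n_null_rc,
                  seed = seed)
  ), class = "assembly_run")
  if (!is.null(out_dir)) write_assembly_run(res, out_dir)
  res
}

#' @export
print.assembly_run <- function(x, ...) {
  cat("assembly_run\n")
  print(x$report[, c("cutoff", "component", "grouping", process_levels(),
                     "n_pairs")], digits = 3)
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' @param run an `assembly_run`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_assembly_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(run$report, "report.tsv")
  tsv(run$pairwise, "pairwise.tsv")
  tsv(run$types, "types.tsv")
  tsv(run$cutoffs, "cutoffs.tsv")
  manifest <- c(run$config,
                list(r_version = as.character(getRversion()),
                     package_version =
                       as.character(utils::packageVersion("rarescape"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
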