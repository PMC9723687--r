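#' Sample-specific rarity cutoff (h-index rule)
#'
#' Walks the sample's rank abundance curve (counts sorted in decreasing
#' order) and finds the first rank `r` whose abundance is no greater than
#' `r` — the same crossing rule as the h-index. The abundance at that
#' crossing, divided by the sample total, is the raw rarity cutoff. With
#' `recalibrate = TRUE` the raw fraction is adjusted by the sample's
#' completeness `S_obs / S_chao1`, shrinking the cutoff for under-sampled
#' communities.
#'
#' @param sample_counts non-negative integer vector for one sample.
#' @param recalibrate adjust by completeness (`S_obs / S_chao1`)?
#' @param direction how the completeness ratio is applied; the default
#'   `"multiply"` shrinks the cutoff (ratio <= 1), `"divide"` inflates it.
#' @return rarity cutoff as a relative-abundance fraction in (0, 1).
#' @export
#' @examples
#' sample_specific_cutoff(c(500, 100, 50, 10, 5, 3, 2, 1, 1, 1)) # 5/673
sample_specific_cutoff <- function(sample_counts, recalibrate = FALSE,
                                   direction = c("multiply", "divide")) {
  direction <- match.arg(direction)
  x <- sample_counts[sample_counts > 0]
  if (!length(x)) stop("sample has no positive counts")
  s <- sort(x, decreasing = TRUE)
  r <- seq_along(s)
  cross <- which(s <= r)
  if (!length(cross)) {
    warning("no rank-abundance crossing found; using the smallest abundance")
    h <- min(s)
  } else {
    # first crossing = largest qualifying abundance (ties resolved by value)
    h <- s[cross[1]]
  }
  frac <- h / sum(s)
  if (recalibrate) {
    completeness <- length(x) / chao1(sample_counts)
    frac <- if (direction == "multiply") frac * completeness
            else frac / completeness
  }
  frac
}

#' Per-sample rarity cutoffs for a whole table
#'
#' @param table a `feature_table` or count matrix.
#' @inheritParams sample_specific_cutoff
#' @return data.frame with columns `sample_id`, `raw`, `adjusted` (equal to
#'   `raw` when `recalibrate = FALSE`).
#' @export
sample_specific_cutoffs <- function(table, recalibrate = FALSE,
                                    direction = c("multiply", "divide")) {
  direction <- match.arg(direction)
  m <- ft_counts(table)
  raw <- apply(m, 2, sample_specific_cutoff, recalibrate = FALSE)
  adj <- if (recalibrate)
    apply(m, 2, sample_specific_cutoff, recalibrate = TRUE,
          direction = direction)
  else raw
  data.frame(sample_id = colnames(m), raw = unname(raw),
             adjusted = unname(adj), stringsAsFactors = FALSE)
}

#' Partition a community into rare and common biospheres
#'
#' Per sample, an ASV is rare iff its relative abundance is positive and no
#' greater than the cutoff (boundary inclusive), common iff strictly above
#' it; an absent ASV belongs to neither. The two component tables sum back
#' to the input entrywise.
#'
#' @param table a rarefied `feature_table` (uniform depth, so relative
#'   abundance is count/depth).
#' @param cutoff either a single relative-abundance fraction in (0, 1), a
#'   named per-sample numeric vector, or `"sample_specific"` to apply the
#'   h-index rule of [sample_specific_cutoff()] per sample.
#' @param recalibrate only used with `cutoff = "sample_specific"`: adjust
#'   each cutoff by the sample's `S_obs / S_chao1` completeness.
#' @param direction see [sample_specific_cutoff()].
#' @return an object of class `biosphere_partition`: list with
#'   `feature_table`s `rare` and `common`, and `cutoffs` (data.frame
#'   `sample_id`, `raw`, `adjusted`, `mode`).
#' @export
partition_biospheres <- function(table, cutoff = 0.001, recalibrate = FALSE,
                                 direction = c("multiply", "divide")) {
  direction <- match.arg(direction)
  table <- as_feature_table(table)
  m <- table$counts
  if (is.character(cutoff)) {
    if (!identical(cutoff, "sample_specific") && !identical(cutoff, "auto"))
      stop("unknown cutoff mode: ", cutoff)
    cut_df <- sample_specific_cutoffs(table, recalibrate = recalibrate,
                                      direction = direction)
    cut_df$mode <- "sample_specific"
    per_sample <- setNames(cut_df$adjusted, cut_df$sample_id)
  } else if (length(cutoff) == 1L && is.null(names(cutoff))) {
    if (cutoff <= 0 || cutoff >= 1)
      stop("fixed cutoff must lie strictly between 0 and 1")
    per_sample <- setNames(rep(cutoff, ncol(m)), colnames(m))
    cut_df <- data.frame(sample_id = colnames(m), raw = cutoff,
                         adjusted = cutoff, mode = "fixed",
                         stringsAsFactors = FALSE)
  } else {
    if (!all(colnames(m) %in% names(cutoff)))
      stop("per-sample cutoff vector must name every sample")
    per_sample <- cutoff[colnames(m)]
    if (any(per_sample <= 0) || any(per_sample >= 1))
      stop("cutoffs must lie strictly between 0 and 1")
    cut_df <- data.frame(sample_id = colnames(m), raw = unname(per_sample),
                         adjusted = unname(per_sample), mode = "supplied",
                         stringsAsFactors = FALSE)
  }
  relab <- relative_abundance(m)
  rare_mask <- relab > 0 &
    relab <= matrix(per_sample, nrow(m), ncol(m), byrow = TRUE)
  rare <- m * rare_mask
  common <- m - rare
  structure(list(
    rare = feature_table(rare),
    common = feature_table(common),
    cutoffs = cut_df
  ), class = "biosphere_partition")
}

#' @export
print.biosphere_partition <- function(x, ...) {
  ra <- sum(x$rare$counts) / max(1, sum(x$rare$counts) + sum(x$common$counts))
  cat(sprintf("biosphere_partition (%s cutoff): rare fraction of reads %.2f%%\n",
              x$cutoffs$mode[1], 100 * ra))
  invisible(x)
}

#' Classify ASVs into rarity/commonness types
#'
#' Applies the four occurrence rules across all samples of a partition:
#' `permanently_common` — detected and common in every sample;
#' `conditionally_rare_common` — common in at least one sample and rare in
#' at least one other; `permanently_rare` — never common, rare in two or
#' more samples; `transiently_rare` — never common, rare in exactly one
#' sample. ASVs common somewhere, absent elsewhere and never rare fall
#' outside the four rules; they are labelled `conditionally_rare_common`
#' (absence read as sub-detection rarity) and flagged. Never-detected ASVs
#' are excluded with a warning.
#'
#' @param partition a `biosphere_partition` over at least two samples.
#' @return data.frame with columns `asv`, `type` (factor over the four
#'   types), `n_rare`, `n_common`, and logical `flagged`.
#' @export
classify_rarity_types <- function(partition) {
  stopifnot(inherits(partition, "biosphere_partition"))
  rare_occ <- partition$rare$counts > 0
  common_occ <- partition$common$counts > 0
  n_samples <- ncol(rare_occ)
  if (n_samples < 2) stop("rarity types need a partition over >= 2 samples")
  n_rare <- rowSums(rare_occ)
  n_common <- rowSums(common_occ)
  detected <- (n_rare + n_common) > 0
  if (any(!detected)) {
    warning(sum(!detected), " never-detected ASV(s) excluded from typing")
  }
  n_rare <- n_rare[detected]
  n_common <- n_common[detected]
  type <- ifelse(n_common == n_samples, "permanently_common",
          ifelse(n_common >= 1, "conditionally_rare_common",
          ifelse(n_rare >= 2, "permanently_rare", "transiently_rare")))
  flagged <- n_common >= 1 & n_common < n_samples & n_rare == 0
  data.frame(
    asv = names(n_rare),
    type = factor(type, levels = c("permanently_rare", "transiently_rare",
                                   "conditionally_rare_common",
                                   "permanently_common")),
    n_rare = unname(n_rare), n_common = unname(n_common),
    flagged = unname(flagged),
    stringsAsFactors = FALSE, row.names = NULL)
}
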