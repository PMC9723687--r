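#' Construct a feature table
#'
#' A feature table is the ASV-by-sample count matrix at the centre of every
#' downstream analysis: rows are amplicon sequence variants (ASVs), columns
#' are samples, entries are non-negative integer read counts.
#'
#' @param counts numeric matrix of non-negative integer counts with ASV row
#'   names and sample column names.
#' @param is_rarefied logical; `TRUE` when every column has been subsampled to
#'   a common depth.
#' @param depth reads per sample when rarefied; checked against column sums.
#' @return an object of class `feature_table` with elements `counts`,
#'   `is_rarefied` and `depth`.
#' @export
#' @examples
#' m <- matrix(c(5L, 3L, 2L, 0L, 4L, 6L), nrow = 3,
#'             dimnames = list(paste0("ASV", 1:3), c("S1", "S2")))
#' feature_table(m)
feature_table <- function(counts, is_rarefied = FALSE, depth = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry ASV row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate ASV ids in feature table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in feature table")
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  cs <- colSums(counts)
  if (isTRUE(is_rarefied)) {
    depth <- depth %||% unname(cs[1])
    if (any(cs != depth))
      stop("is_rarefied = TRUE but column sums are not all equal to `depth`")
  } else {
    depth <- depth %||% NA_real_
  }
  structure(list(counts = counts, is_rarefied = isTRUE(is_rarefied),
                 depth = as.numeric(depth)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d ASVs x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (x$is_rarefied) sprintf(", rarefied to %g reads/sample", x$depth)
              else ""))
  invisible(x)
}

#' Coerce to a feature table
#'
#' @param x a `feature_table` or a count matrix (ASVs in rows).
#' @param ... passed to [feature_table()].
#' @return a `feature_table`.
#' @export
as_feature_table <- function(x, ...) {
  if (inherits(x, "feature_table")) x else feature_table(x, ...)
}

# internal: raw count matrix (taxa x samples)
ft_counts <- function(x) {
  if (inherits(x, "feature_table")) x$counts else as.matrix(x)
}

#' Per-sample relative abundances
#'
#' @param table a `feature_table` or count matrix.
#' @return matrix of the same shape whose columns sum to 1 (all-zero columns
#'   stay zero).
#' @export
relative_abundance <- function(table) {
  m <- ft_counts(table)
  cs <- colSums(m)
  cs[cs == 0] <- 1
  sweep(m, 2, cs, "/")
}

#' Read a feature table from TSV
#'
#' Accepts plain TSV with the ASV id in the first column, as well as the
#' BIOM-TSV dialect whose leading lines start with `#` (a final
#' `#OTU ID`-style line is treated as the header). When the first header
#' token names samples (e.g. `sample_id`), the table is assumed transposed
#' and is flipped so that rows are ASVs.
#'
#' @param path TSV file path.
#' @param orientation `"auto"` (detect from the header token), `"taxa_rows"`
#'   or `"samples_rows"`.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path,
                               orientation = c("auto", "taxa_rows",
                                               "samples_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("feature table file not found: ", path)
  lines <- readLines(path)
  hash <- startsWith(lines, "#")
  if (any(hash)) {
    # keep a trailing "#OTU ID"-style header line, drop pure comments
    first_data <- which(!hash)[1]
    if (is.na(first_data)) stop("no data lines in ", path)
    keep <- !hash
    if (first_data > 1 && grepl("\t", lines[first_data - 1])) {
      lines[first_data - 1] <- sub("^#", "", lines[first_data - 1])
      keep[first_data - 1] <- TRUE
    }
    lines <- lines[keep]
  }
  df <- read.delim(text = paste(lines, collapse = "\n"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs an id column plus data columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  first_tok <- tolower(gsub("[^a-z]", "", tolower(names(df)[1])))
  transposed <- switch(orientation,
    taxa_rows = FALSE,
    samples_rows = TRUE,
    auto = first_tok %in% c("sample", "sampleid", "samples"))
  if (transposed) {
    message("feature table read as samples-in-rows; transposing")
    m <- t(m)
  }
  feature_table(m)
}

#' Read a sample metadata table from TSV
#'
#' @param path TSV with columns `sample_id`, `stage`, `time`, `replicate`
#'   (extra columns preserved).
#' @return a data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "time", "replicate")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  md
}

#' Load and cross-validate a dataset
#'
#' Reads the three input artifacts and checks that sample ids match between
#' table and metadata and that every ASV used downstream has a tip in the
#' tree.
#'
#' @param feature_path,metadata_path,tree_path file paths (TSV, TSV, Newick).
#' @param missing_tip_policy what to do with ASVs absent from the tree:
#'   `"drop"` removes them with a warning, `"error"` aborts.
#' @return list with elements `table` (`feature_table`), `metadata`
#'   (data.frame), `tree` (`phylo`) and `dropped_asvs` (character).
#' @export
load_dataset <- function(feature_path, metadata_path, tree_path,
                         missing_tip_policy = c("drop", "error")) {
  missing_tip_policy <- match.arg(missing_tip_policy)
  table <- read_feature_table(feature_path)
  metadata <- read_sample_metadata(metadata_path)
  tree <- ape::read.tree(tree_path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")

  missing_md <- setdiff(colnames(table$counts), metadata$sample_id)
  if (length(missing_md))
    stop("sample(s) in feature table but not in metadata: ",
         paste(missing_md, collapse = ", "))
  metadata <- metadata[match(colnames(table$counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL

  absent <- setdiff(rownames(table$counts), tree$tip.label)
  if (length(absent)) {
    if (missing_tip_policy == "error")
      stop(length(absent), " ASV(s) missing from the tree, e.g. ", absent[1])
    warning(length(absent), " ASV(s) missing from the tree were dropped")
    keep <- setdiff(rownames(table$counts), absent)
    table <- feature_table(table$counts[keep, , drop = FALSE],
                           is_rarefied = FALSE)
  }
  list(table = table, metadata = metadata, tree = tree, dropped_asvs = absent)
}

#' Rarefy a feature table
#'
#' Subsamples each sample's reads without replacement to a common depth
#' (hypergeometric rarefaction, via [vegan::rrarefy()]). Samples with fewer
#' reads than `depth` are dropped with a warning; ASVs left with all-zero
#' rows are removed.
#'
#' @param table a `feature_table` or count matrix.
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed for reproducibility.
#' @param n_draws number of independent rarefaction draws; the default 1
#'   returns a single `feature_table`, larger values return a list of
#'   independent draws.
#' @return a rarefied `feature_table` (or list thereof when `n_draws > 1`).
#' @export
rarefy_table <- function(table, depth, seed = NULL, n_draws = 1) {
  m <- ft_counts(table)
  stopifnot(depth >= 1, n_draws >= 1)
  totals <- colSums(m)
  if (all(totals < depth))
    stop("rarefaction depth ", depth, " exceeds every sample total")
  drop <- names(totals)[totals < depth]
  if (length(drop))
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(drop, collapse = ", "))
  m <- m[, totals >= depth, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  one_draw <- function() {
    # rrarefy warns when the smallest positive count is large; irrelevant here
    sub <- withCallingHandlers(
      t(vegan::rrarefy(t(m), sample = depth)),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    feature_table(sub, is_rarefied = TRUE, depth = depth)
  }
  if (n_draws == 1) one_draw() else replicate(n_draws, one_draw(),
                                              simplify = FALSE)
}

#' Chao1 richness estimator
#'
#' Classic Chao1, `S_obs + F1^2 / (2 F2)`, from singleton (`F1`) and
#' doubleton (`F2`) counts; when no doubletons exist the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used. Always at least `S_obs`.
#'
#' @param sample_counts non-negative integer vector of per-taxon counts for
#'   one sample.
#' @return estimated richness (taxa); 0 for an all-zero vector.
#' @export
#' @examples
#' chao1(c(50, 20, 10, 5, 2, 2, 1, 1, 1, 1)) # 14
chao1 <- function(sample_counts) {
  x <- sample_counts
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  s_obs <- sum(x > 0)
  if (s_obs == 0) return(0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Cophenetic (patristic) distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the path between tips i and
#' j; this matrix carries the between-community nearest-taxon distances used
#' by [beta_mntd()].
#'
#' @param tree a rooted `phylo` object with branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(tree$tip.label) || anyNA(tree$tip.label) ||
      any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled tips")
  ape::cophenetic.phylo(tree)
}
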