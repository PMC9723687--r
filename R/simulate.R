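#' Simulate a phylogeny with a conserved niche trait
#'
#' Pure-birth tree plus a continuous niche trait evolved by Brownian motion.
#' The trait can be made more phylogenetically conserved than plain Brownian
#' motion via `conservatism`: node heights of the tree used for the trait
#' simulation are raised to this power (< 1 concentrates trait divergence on
#' the deep splits, so lineages carry near-constant niche values — the
#' clade-level niche conservatism that betaNTI-style inference assumes,
#' and a pattern typical of 16S phylogenies where ecological strategies are
#' conserved at coarse taxonomic levels). `conservatism = 1` is plain
#' Brownian motion on the tree itself.
#'
#' @param n_taxa number of tips (>= 3).
#' @param birth_rate speciation rate of the pure-birth process.
#' @param bm_rate Brownian-motion variance rate; 0 gives identical traits.
#' @param conservatism node-height power for the trait simulation tree
#'   (0 < conservatism <= 1).
#' @param seed integer seed.
#' @return list with `tree` (`phylo`, tips labelled `ASV0001`, ...) and
#'   `traits` (named numeric vector).
#' @export
simulate_tree_and_traits <- function(n_taxa, birth_rate = 1, bm_rate = 1,
                                     conservatism = 1, seed = NULL) {
  stopifnot(n_taxa >= 3, birth_rate > 0, bm_rate >= 0,
            conservatism > 0, conservatism <= 1)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("ASV%04d", seq_len(n_taxa))
  trait_tree <- if (conservatism < 1) depth_power_transform(tree, conservatism)
                else tree
  traits <- if (bm_rate == 0) setNames(numeric(n_taxa), tree$tip.label)
            else ape::rTraitCont(trait_tree, model = "BM",
                                 sigma = sqrt(bm_rate))
  list(tree = tree, traits = traits)
}

# Raise relative node heights of an ultrametric tree to a power, keeping tip
# height fixed. p < 1 pushes splits toward the tips (coalescent-like);
# p > 1 toward the root.
depth_power_transform <- function(tree, p) {
  n <- ape::Ntip(tree)
  d <- ape::node.depth.edgelength(tree)
  t_max <- max(d[seq_len(n)])
  d2 <- t_max * (d / t_max)^p
  d2[seq_len(n)] <- t_max
  tree$edge.length <- d2[tree$edge[, 2]] - d2[tree$edge[, 1]]
  tree$edge.length[tree$edge.length < 1e-9] <- 1e-9
  tree
}

#' Phylogenetic coherence of a taxon set
#'
#' Mean nearest-neighbour cophenetic distance within the set, relative to
#' the same quantity for random sets of equal size. Values well below 1
#' mean the set is clustered on the tree; the synthetic generator uses this
#' to verify that a niche band actually satisfies the niche-conservatism
#' premise of the selection scenarios.
#'
#' @param D cophenetic distance matrix.
#' @param band character vector of tip names (subset of `rownames(D)`).
#' @param n_random number of random reference sets.
#' @return coherence ratio (observed / random expectation).
#' @export
band_coherence <- function(D, band, n_random = 30) {
  sub <- D[band, band, drop = FALSE]
  diag(sub) <- Inf
  obs <- mean(apply(sub, 1, min))
  ref <- mean(replicate(n_random, {
    rs <- sample(rownames(D), length(band))
    s2 <- D[rs, rs, drop = FALSE]
    diag(s2) <- Inf
    mean(apply(s2, 1, min))
  }))
  obs / ref
}

#' Scenario configuration for the synthetic generator
#'
#' Defaults emulate the study design the pipeline targets: a successional
#' chronosequence sampled as 5 stages x 4 times x 3 replicates = 60
#' samples and a rarefaction depth of 31,500 reads per sample.
#'
#' @param scenario assembly regime: `"homogeneous_selection"`,
#'   `"variable_selection"`, `"neutral_drift"`, `"dispersal_limitation"` or
#'   `"mixed"`.
#' @param n_taxa number of taxa in the regional pool (the tree keeps all of
#'   them, observed or not — the tip-shuffling null needs the full pool).
#' @param design integer vector `c(stages, times, replicates)`.
#' @param depth reads per sample (multinomial total).
#' @param sigma_w Gaussian niche width in trait units; `NULL` uses
#'   `0.2 * sd(traits)`.
#' @param env_quantiles trait quantiles at which stage environments sit;
#'   `NULL` picks scenario defaults (see [simulate_dataset()]).
#' @param trait_conservatism node-height power for the niche trait (see
#'   [simulate_tree_and_traits()]); the selection scenarios assume strongly
#'   conserved niches.
#' @param colonization_prob per-taxon, per-sample colonization probability
#'   in the selection scenarios; drives taxon turnover among samples that
#'   share an environment.
#' @param band_coherence_max selection scenarios redraw the tree/trait pair
#'   (up to `max_tree_draws` times) until the taxa nearest each
#'   environmental optimum form a phylogenetically coherent set (see
#'   Details).
#' @param max_tree_draws cap on tree/trait redraws.
#' @param band_size number of taxa over which coherence is assessed.
#' @param birth_rate,bm_rate tree/trait parameters.
#' @param k_sdlog sdlog of the lognormal carrying capacities; `NULL` uses
#'   0.5 for the selection scenarios (niche filtering and the colonization
#'   lottery already skew abundances) and 1.5 otherwise (the long-tailed
#'   abundance distribution that guarantees a rare biosphere).
#' @param sample_noise_sdlog sdlog of per-taxon-per-sample lognormal noise.
#' @param n_pools regional pools for `dispersal_limitation`; defaults to
#'   the number of stages.
#' @param drift_generations multinomial resampling generations for
#'   `neutral_drift`.
#' @param seed integer seed.
#'
#' @details The selection scenarios exist to emulate niche-based assembly
#' under phylogenetically conserved traits. A Brownian trait draw in which
#' the taxa around an environmental optimum happen to be scattered across
#' the tree violates that premise, so the generator screens candidate
#' tree/trait pairs with [band_coherence()] and keeps the first draw whose
#' niche band is clustered (or the most clustered of `max_tree_draws`).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("homogeneous_selection",
                                         "variable_selection",
                                         "neutral_drift",
                                         "dispersal_limitation", "mixed"),
                            n_taxa = 1000,
                            design = c(stages = 5, times = 4,
                                       replicates = 3),
                            depth = 31500, sigma_w = NULL,
                            env_quantiles = NULL,
                            trait_conservatism = 0.05,
                            colonization_prob = 0.5,
                            band_coherence_max = 0.35,
                            max_tree_draws = 40, band_size = 30,
                            birth_rate = 1, bm_rate = 1, k_sdlog = NULL,
                            sample_noise_sdlog = 0.5,
                            n_pools = NULL, drift_generations = 3,
                            seed = 1) {
  scenario <- match.arg(scenario)
  design <- setNames(as.integer(design), c("stages", "times", "replicates"))
  stopifnot(all(design >= 1), n_taxa >= 3, depth >= 1,
            colonization_prob > 0, colonization_prob <= 1)
  selection <- scenario %in% c("homogeneous_selection",
                               "variable_selection", "mixed")
  structure(list(
    scenario = scenario, n_taxa = n_taxa, design = design, depth = depth,
    sigma_w = sigma_w, env_quantiles = env_quantiles,
    trait_conservatism = trait_conservatism,
    colonization_prob = colonization_prob,
    band_coherence_max = band_coherence_max,
    max_tree_draws = max_tree_draws, band_size = band_size,
    birth_rate = birth_rate, bm_rate = bm_rate,
    k_sdlog = k_sdlog %||% (if (selection) 0.5 else 1.5),
    sample_noise_sdlog = sample_noise_sdlog,
    n_pools = n_pools %||% unname(design["stages"]),
    drift_generations = drift_generations, seed = seed
  ), class = "scenario_config")
}

# Stage environments as trait quantiles, per scenario.
scenario_env_quantiles <- function(scenario, n_stages) {
  switch(scenario,
    homogeneous_selection = rep(0.9, n_stages),
    variable_selection = if (n_stages == 1) 0.9
      else seq(0.9, 0.1, length.out = n_stages),
    mixed = {
      shared <- ceiling(n_stages / 2)
      varying <- n_stages - shared
      c(rep(0.9, shared),
        if (varying > 0) seq(0.5, 0.1, length.out = varying))
    },
    NULL)
}

#' Simulate a dataset under a known assembly regime
#'
#' In the selection scenarios the expected relative abundance of taxon i in
#' sample s is proportional to
#' `K_i * exp(-(z_i - E_s)^2 / (2 sigma_w^2)) * B_is * noise_is`,
#' with `K_i` lognormal carrying capacities, `z_i` conserved Brownian niche
#' traits, `E_s` the environment of the sample's stage (a trait quantile),
#' `B_is` a Bernoulli colonization indicator (the lottery that makes
#' equally-fit taxa turn over among samples) and lognormal per-sample
#' noise; counts are one multinomial draw at `depth`. Scenario wiring:
#' homogeneous selection — every stage shares one optimum in the trait
#' tail; variable selection — stage optima at opposite ends of the trait
#' range (separation many times `sigma_w`); mixed — half the stages share
#' an optimum, the rest spread; neutral drift — flat fitness, each sample
#' an independent serial multinomial-resampling chain from one long-tailed
#' pool; dispersal limitation — taxa split at random (with respect to the
#' phylogeny) into disjoint regional pools, one per stage.
#'
#' The returned table keeps all `n_taxa` rows, including never-observed
#' pool taxa, so the tip-shuffling null of [beta_nti()] can randomize
#' across the full regional phylogeny.
#'
#' @param cfg a [scenario_config()] (or arguments forwarded to it via
#'   `...`).
#' @param ... used instead of `cfg` to build the configuration inline.
#' @return list of class `synthetic_dataset`: `table` (`feature_table` at
#'   uniform depth), `metadata`, `tree`, `traits`, `truth` (scenario,
#'   expected dominant process, environments, pool map) and `config`.
#' @export
simulate_dataset <- function(cfg = NULL, ...) {
  cfg <- cfg %||% scenario_config(...)
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  scen <- cfg$scenario
  selection <- scen %in% c("homogeneous_selection", "variable_selection",
                           "mixed")
  S <- unname(cfg$design["stages"])

  env_q <- cfg$env_quantiles %||% scenario_env_quantiles(scen, S)

  if (selection) {
    # screen tree/trait draws for niche-band coherence (see scenario_config)
    best_coh <- Inf
    for (draw in seq_len(cfg$max_tree_draws)) {
      cand <- simulate_tree_and_traits(cfg$n_taxa, cfg$birth_rate,
                                       cfg$bm_rate,
                                       conservatism = cfg$trait_conservatism)
      Dc <- ape::cophenetic.phylo(cand$tree)
      zc <- cand$traits
      bands <- lapply(unique(env_q), function(q) {
        E <- quantile(zc, q)
        names(sort(abs(zc - E)))[seq_len(min(cfg$band_size, cfg$n_taxa))]
      })
      coh <- mean(vapply(bands, band_coherence, numeric(1), D = Dc))
      if (coh < best_coh) {
        tt <- cand
        best_coh <- coh
      }
      if (coh <= cfg$band_coherence_max) break
    }
  } else {
    tt <- simulate_tree_and_traits(cfg$n_taxa, cfg$birth_rate, cfg$bm_rate,
                                   conservatism = cfg$trait_conservatism)
    best_coh <- NA_real_
  }
  z <- tt$traits

  Tm <- unname(cfg$design["times"]); R <- unname(cfg$design["replicates"])
  md <- expand.grid(replicate = seq_len(R), time = seq_len(Tm),
                    stage = seq_len(S))[, c("stage", "time", "replicate")]
  md$sample_id <- sprintf("S%d.T%d.R%d", md$stage, md$time, md$replicate)
  md <- md[, c("sample_id", "stage", "time", "replicate")]
  n_samples <- nrow(md)

  K <- rlnorm(cfg$n_taxa, 0, cfg$k_sdlog)
  names(K) <- names(z)
  sigma_w <- cfg$sigma_w %||% (0.2 * sd(z))
  if (sigma_w == 0 && length(unique(z)) > 1)
    stop("sigma_w = 0 with distinct traits is degenerate")
  env <- if (selection) setNames(as.numeric(quantile(z, env_q)), seq_len(S))

  pool_of <- NULL
  if (scen == "dispersal_limitation") {
    pool_of <- setNames(sample(rep_len(seq_len(cfg$n_pools), cfg$n_taxa)),
                        names(z))
  }
  pool_p <- K / sum(K)

  counts <- matrix(0, cfg$n_taxa, n_samples,
                   dimnames = list(names(z), md$sample_id))
  for (s in seq_len(n_samples)) {
    st <- md$stage[s]
    if (selection) {
      w <- K * exp(-(z - env[as.character(st)])^2 / (2 * sigma_w^2)) *
        rbinom(cfg$n_taxa, 1, cfg$colonization_prob) *
        rlnorm(cfg$n_taxa, 0, cfg$sample_noise_sdlog)
      if (all(w == 0)) w[which.max(K)] <- 1
    } else if (scen == "dispersal_limitation") {
      stage_pool <- 1 + (st - 1) %% cfg$n_pools
      w <- K * (pool_of == stage_pool) *
        rlnorm(cfg$n_taxa, 0, cfg$sample_noise_sdlog)
    } else { # neutral_drift: serial resampling chain from the common pool
      p <- pool_p
      for (g in seq_len(cfg$drift_generations))
        p <- as.vector(rmultinom(1, cfg$depth, p)) / cfg$depth
      w <- p
    }
    counts[, s] <- rmultinom(1, cfg$depth, w)
  }
  dominant <- switch(scen,
    homogeneous_selection = "homogeneous_selection",
    variable_selection = "variable_selection",
    neutral_drift = "undominated",
    dispersal_limitation = "dispersal_limitation",
    mixed = "mixed")
  structure(list(
    table = feature_table(counts, is_rarefied = TRUE, depth = cfg$depth),
    metadata = md, tree = tt$tree, traits = z,
    truth = list(scenario = scen, expected_dominant = dominant,
                 env = env, sigma_w = sigma_w, pool_of = pool_of,
                 band_coherence = best_coh),
    config = cfg
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: scenario %s, %d taxa x %d samples, depth %g\n",
              x$truth$scenario, nrow(x$table$counts), ncol(x$table$counts),
              x$config$depth))
  invisible(x)
}

#' Write a synthetic dataset to plain-text artifacts
#'
#' @param dataset a `synthetic_dataset`.
#' @param out_dir output directory; writes `table.tsv`, `metadata.tsv`,
#'   `tree.nwk` and `truth.json`.
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(asv_id = rownames(dataset$table$counts),
                    dataset$table$counts, check.names = FALSE)
  write.table(tab, file.path(out_dir, "table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$metadata, file.path(out_dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$tree, file.path(out_dir, "tree.nwk"))
  truth <- dataset$truth
  truth$pool_of <- as.list(truth$pool_of)
  truth$env <- as.list(truth$env)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Simulate occurrence data from the Sloan neutral model itself
#'
#' Draws per-sample local relative abundances from the model's
#' Beta(N*m*p, N*m*(1-p)) distribution and converts them to read counts as
#' `floor(p_local * N)`, so that detection at limit `d` corresponds exactly
#' to the model's threshold `p_local >= d/N` and detection frequencies
#' follow [predict_frequency()] by construction — the parameter-recovery
#' fixture for [fit_sloan()]. (Resampling reads binomially instead would
#' blur the detection limit for taxa with `N*m*p < 1` and bias the
#' migration estimate upward.)
#'
#' @param n_taxa,n_samples dimensions.
#' @param Ntm true composite parameter N*m.
#' @param N local community size in reads.
#' @param p_sdlog sdlog of the lognormal metacommunity abundance
#'   distribution.
#' @param seed integer seed.
#' @return list with `table` (count matrix; column sums vary, as only
#'   per-taxon detection matters — pass `N` to [fit_sloan()]), `p_true`
#'   and `Ntm`.
#' @export
simulate_sloan_dataset <- function(n_taxa = 300, n_samples = 50, Ntm = 100,
                                   N = 1000, p_sdlog = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- rlnorm(n_taxa, 0, p_sdlog)
  p <- p / sum(p)
  names(p) <- sprintf("ASV%04d", seq_len(n_taxa))
  counts <- matrix(0L, n_taxa, n_samples,
                   dimnames = list(names(p),
                                   sprintf("S%03d", seq_len(n_samples))))
  for (i in seq_len(n_taxa)) {
    p_local <- rbeta(n_samples, Ntm * p[i], Ntm * (1 - p[i]))
    counts[i, ] <- floor(p_local * N)
  }
  list(table = counts, p_true = p, Ntm = Ntm, N = N)
}
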