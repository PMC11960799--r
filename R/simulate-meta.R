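#' Configuration for the synthetic effect-size generator
#'
#' Generative mirror of the multilevel meta-analytic model: a true overall
#' effect (unitless SMD) plus moderator offsets plus random effects at the
#' study, effect-size, species-identity and species-phylogeny levels, the
#' last correlated by the correlation matrix of a simulated coalescent
#' tree. Group summaries (n, mean, SD per control/response group) are then
#' drawn by normal sampling so that each record's realized SMDH estimates
#' its true effect.
#'
#' @param mu true overall effect (unitless SMD).
#' @param sigma2 named variance components
#'   `c(study = , es = , species = , phylo = )`, each >= 0.
#' @param n_studies number of studies (>= 1).
#' @param es_per_study effect sizes per study (>= 1).
#' @param n_species number of species on the tree (>= 1; must be > 0
#'   whenever the phylogenetic variance is > 0).
#' @param n_range inclusive range of per-group sample sizes (each >= 2).
#' @param sd_range range of within-group population SDs (> 0).
#' @param moderators named list of moderator level offsets, e.g.
#'   `list(event_type = c(warming = 0, ros = 0))`; offsets add to the true
#'   effect. `event_type`, `study_type` and `author_group` are assigned per
#'   study, `response_category` per record, `phylum` per species.
#' @param seed integer seed (split into deterministic substreams).
#' @return A list of class `meta_sim_config`.
#' @export
meta_sim_config <- function(mu = -0.9,
                            sigma2 = c(study = 0.19, es = 0.98,
                                       species = 0, phylo = 0.04),
                            n_studies = 17, es_per_study = 11,
                            n_species = 49,
                            n_range = c(5, 30), sd_range = c(0.5, 2),
                            moderators = list(
                              event_type = c(warming = 0, ros = 0),
                              study_type = c(experimental = 0,
                                             observational = 0),
                              response_category = c(quantity = 0,
                                                    energetic = 0),
                              author_group = c(lead = 0, other = 0)),
                            seed = 1L) {
  sigma2 <- sigma2[c("study", "es", "species", "phylo")]
  if (anyNA(sigma2) || any(sigma2 < 0))
    stop("sigma2 must supply non-negative study/es/species/phylo components",
         call. = FALSE)
  if (n_studies < 1 || es_per_study < 1)
    stop("counts must be >= 1", call. = FALSE)
  if (n_species < 1 && sigma2["phylo"] > 0)
    stop("zero species with nonzero phylogenetic variance", call. = FALSE)
  if (n_range[1] < 2) stop("sample sizes must be >= 2 (SD must be computable)",
                           call. = FALSE)
  if (sd_range[1] <= 0) stop("SDs must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "meta_sim_config")
}

#' Simulate an effect-size dataset with known ground truth
#'
#' Draws a coalescent species tree, per-level random effects (phylogenetic
#' effects correlated by the tree's correlation matrix), composes the true
#' effect of every record, and emits raw control/response group summaries
#' consistent with those true effects under normal sampling (sample means
#' are normal, sample SDs follow the scaled-chi distribution). The truth is
#' returned alongside for recovery tests.
#'
#' @param config a [meta_sim_config].
#' @return A list: `records` (data frame with study, species, moderators,
#'   group summaries `n_c, mean_c, sd_c, n_r, mean_r, sd_r`, and the true
#'   per-record effect `delta`), `tree` (an `ape::phylo`), `A` (the tree's
#'   correlation matrix), and `truth` (`mu`, `sigma2`, moderator offsets).
#' @export
simulate_effect_sizes <- function(config) {
  stopifnot(inherits(config, "meta_sim_config"))
  ns <- config$n_studies; npr <- config$es_per_study
  k <- ns * npr; nsp <- config$n_species
  s2 <- config$sigma2

  # substream 1: tree and species assignment
  set.seed(config$seed)
  tree <- ape::rcoal(nsp,
                     tip.label = sprintf("species_%02d", seq_len(nsp)))
  A <- ape::vcv(tree, corr = TRUE)
  study <- rep(sprintf("study_%02d", seq_len(ns)), each = npr)
  species <- sample(tree$tip.label, k, replace = TRUE)

  # substream 2: random effects
  set.seed(config$seed + 1L)
  u_study <- stats::rnorm(ns, sd = sqrt(s2["study"]))
  u_species <- stats::rnorm(nsp, sd = sqrt(s2["species"]))
  u_phylo <- if (s2["phylo"] > 0)
    drop(MASS::mvrnorm(1, mu = rep(0, nsp), Sigma = s2["phylo"] * A))
  else rep(0, nsp)
  names(u_species) <- names(u_phylo) <- tree$tip.label
  u_es <- stats::rnorm(k, sd = sqrt(s2["es"]))

  # substream 3: moderators
  set.seed(config$seed + 2L)
  mods <- config$moderators
  md <- list()
  per_study <- c("event_type", "study_type", "author_group")
  for (nm in names(mods)) {
    lev <- names(mods[[nm]])
    md[[nm]] <- if (nm %in% per_study)
      rep(sample(lev, ns, replace = TRUE), each = npr)
    else if (nm == "phylum") {
      sp2ph <- sample(lev, nsp, replace = TRUE)
      names(sp2ph) <- tree$tip.label
      sp2ph[species]
    } else sample(lev, k, replace = TRUE)
  }
  offset <- rep(0, k)
  for (nm in names(mods)) offset <- offset + mods[[nm]][md[[nm]]]

  delta <- config$mu + offset + u_study[match(study, unique(study))] +
    u_species[species] + u_phylo[species] + u_es

  # substream 4: group summaries by normal sampling
  set.seed(config$seed + 3L)
  nvals <- config$n_range[1]:config$n_range[2]   # guard length-1 sample()
  n_c <- nvals[sample.int(length(nvals), k, replace = TRUE)]
  n_r <- nvals[sample.int(length(nvals), k, replace = TRUE)]
  sd_c <- stats::runif(k, config$sd_range[1], config$sd_range[2])
  sd_r <- stats::runif(k, config$sd_range[1], config$sd_range[2])
  spool <- sqrt((sd_c^2 + sd_r^2) / 2)
  mu_c <- rep(0, k)
  mu_r <- mu_c + delta * spool
  mean_c <- stats::rnorm(k, mu_c, sd_c / sqrt(n_c))
  mean_r <- stats::rnorm(k, mu_r, sd_r / sqrt(n_r))
  s_c <- sd_c * sqrt(stats::rchisq(k, n_c - 1) / (n_c - 1))
  s_r <- sd_r * sqrt(stats::rchisq(k, n_r - 1) / (n_r - 1))

  records <- data.frame(
    es_id = sprintf("es_%03d", seq_len(k)), study = study,
    species = species, stringsAsFactors = FALSE)
  for (nm in names(md)) records[[nm]] <- unname(md[[nm]])
  records$n_c <- n_c; records$mean_c <- mean_c; records$sd_c <- s_c
  records$n_r <- n_r; records$mean_r <- mean_r; records$sd_r <- s_r
  records$delta <- delta

  list(records = records, tree = tree, A = A,
       truth = list(mu = config$mu, sigma2 = s2,
                    moderators = config$moderators))
}
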