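# Genetic-algorithm training of surrogate model families.

#' Genetic-algorithm settings
#'
#' @param population population size (default 400).
#' @param generations maximum generations (default 300).
#' @param tournament tournament size for selection (default 4).
#' @param crossover per-mating uniform-crossover probability (default 0.8).
#' @param mutation per-gene mutation rate (default 0.02).
#' @param family_size members kept in the returned family (default 200,
#'   capped at the population size).
#' @param plateau stop after this many generations without fitness
#'   improvement (default 30).
#' @param lambda weight of the internal-q2 penalty in the fitness,
#'   fitness = -RMSE(train) - lambda * (1 - q2_internal).
#' @param elitism elites copied unchanged each generation (default 2).
#' @param induced_fit_penalty kcal/mol per A of envelope dilation.
#' @param base_energy scaffold reference energy (kcal/mol).
#' @return list of settings.
#' @export
gaConfig <- function(population = 400L, generations = 300L, tournament = 4L,
                     crossover = 0.8, mutation = 0.02, family_size = 200L,
                     plateau = 30L, lambda = 0.2, elitism = 2L,
                     induced_fit_penalty = 2.0, base_energy = -8.9) {
  list(population = as.integer(population),
       generations = as.integer(generations),
       tournament = as.integer(tournament), crossover = crossover,
       mutation = mutation, family_size = as.integer(family_size),
       plateau = as.integer(plateau), lambda = lambda,
       elitism = as.integer(elitism),
       induced_fit_penalty = induced_fit_penalty, base_energy = base_energy)
}

# Precompute a stacked feature cache over the training ligands: one
# (P*7) x total_poses matrix per induced-fit scenario, plus pose-level
# solvation proxies, Boltzmann weights and the pose -> ligand map.
.dataset_feature_cache <- function(ensembles, envelope, nb) {
  feats <- lapply(ensembles, .ensemble_features, envelope = envelope,
                  scenarios = 0:5, nb = nb)
  lig_of <- unlist(mapply(function(f, i) rep(i, f$n_poses), feats,
                          seq_along(feats), SIMPLIFY = FALSE))
  list(flat = lapply(1:6, function(s)
         do.call(cbind, lapply(feats, function(f) f$flat[[s]]))),
       solv = unlist(lapply(feats, function(f) f$solv)),
       weights = unlist(lapply(feats, function(f) f$weights)),
       lig_of = lig_of, n_lig = length(ensembles),
       P = nrow(envelope@positions))
}

# vectorised predictions of one genome over all cached ligands
.cache_predict <- function(cache, labels, s_if, s_solv, config, nb) {
  fidx <- (seq_len(cache$P) - 1L) * 7L + labels
  part <- colSums(cache$flat[[s_if + 1]][fidx, , drop = FALSE])
  pose_G <- config$base_energy + part +
    config$induced_fit_penalty * 0.1 * s_if +
    .SOLV_SCENARIO_SCALE[s_solv + 1L] * cache$solv
  rt <- nb@gas_constant * nb@temperature
  m <- stats::ave(pose_G, cache$lig_of, FUN = min)
  contrib <- cache$weights * exp(-(pose_G - m) / rt)
  S <- rowsum(contrib, cache$lig_of)[, 1]
  m_lig <- rowsum(m, cache$lig_of)[, 1] /
    tabulate(cache$lig_of, nbins = cache$n_lig)
  G <- m_lig - rt * log(S)
  -G / .pic50_slope(nb)
}

#' Train a surrogate model family with a genetic algorithm
#'
#' Evolves per-particle property assignments (plus the induced-fit and
#' solvation scenario of each member) by tournament selection, uniform
#' crossover and per-particle mutation.  Fitness is
#' -RMSE(train) - lambda * (1 - q2_internal), where q2_internal is the
#' training-set explained variance (genomes carry no refittable
#' parameters, so held-out prediction with a fixed genome equals its
#' training prediction).  Fully reproducible from `seed`.
#'
#' @param dataset a [QsarDataset-class]; its train split (>= 8 entries) is
#'   used.
#' @param envelope an [Envelope-class]; built from the training ensembles
#'   with default spacing when NULL.
#' @param config settings from [gaConfig()].
#' @param seed integer seed.
#' @param nb a [NonbondedModel-class].
#' @return A [ModelFamily-class] of the final population's top
#'   `family_size` members.
#' @export
gaTrain <- function(dataset, envelope = NULL, config = gaConfig(), seed = 1,
                    nb = nonbondedModel()) {
  tr <- which(dataset@split == "train")
  if (length(tr) < 8)
    .afp_stop("need at least 8 training entries", "afp_precondition")
  if (is.null(envelope))
    envelope <- buildEnvelope(dataset@ensembles[tr])
  cache <- .dataset_feature_cache(dataset@ensembles[tr], envelope, nb)
  y <- dataset@pic50[tr]
  ss_tot <- sum((y - mean(y))^2)
  P <- cache$P
  pop <- config$population

  fitness_of <- function(labels, s_if, s_solv) {
    pred <- .cache_predict(cache, labels, s_if, s_solv, config, nb)
    sse <- sum((pred - y)^2)
    rmse <- sqrt(sse / length(y))
    q2i <- if (ss_tot > 0) 1 - sse / ss_tot else 0
    -rmse - config$lambda * (1 - q2i)
  }

  .with_seed(seed, {
    L <- matrix(sample.int(7L, pop * P, replace = TRUE), nrow = pop)
    s_if <- sample(0:5, pop, replace = TRUE)
    s_solv <- sample(0:1, pop, replace = TRUE)
    fit <- vapply(seq_len(pop), function(g)
      fitness_of(L[g, ], s_if[g], s_solv[g]), numeric(1))

    best <- max(fit)
    stall <- 0L
    for (gen in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      nL <- L; ns_if <- s_if; ns_solv <- s_solv
      # elites
      el <- ord[seq_len(min(config$elitism, pop))]
      nL[seq_along(el), ] <- L[el, , drop = FALSE]
      ns_if[seq_along(el)] <- s_if[el]
      ns_solv[seq_along(el)] <- s_solv[el]
      # offspring
      for (g in (length(el) + 1L):pop) {
        pick <- function() {
          cand <- sample.int(pop, config$tournament, replace = TRUE)
          cand[which.max(fit[cand])]
        }
        p1 <- pick(); p2 <- pick()
        child <- L[p1, ]
        c_if <- s_if[p1]; c_solv <- s_solv[p1]
        if (stats::runif(1) < config$crossover) {
          mask <- stats::runif(P) < 0.5
          child[mask] <- L[p2, mask]
          if (stats::runif(1) < 0.5) c_if <- s_if[p2]
          if (stats::runif(1) < 0.5) c_solv <- s_solv[p2]
        }
        mut <- stats::runif(P) < config$mutation
        if (any(mut))
          child[mut] <- sample.int(7L, sum(mut), replace = TRUE)
        if (stats::runif(1) < config$mutation) c_if <- sample(0:5, 1)
        if (stats::runif(1) < config$mutation) c_solv <- sample(0:1, 1)
        nL[g, ] <- child; ns_if[g] <- c_if; ns_solv[g] <- c_solv
      }
      L <- nL; s_if <- ns_if; s_solv <- ns_solv
      fit <- vapply(seq_len(pop), function(g)
        fitness_of(L[g, ], s_if[g], s_solv[g]), numeric(1))
      if (max(fit) > best + 1e-9) {
        best <- max(fit)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$plateau) break
      }
    }

    keep <- order(fit, decreasing = TRUE)[seq_len(min(config$family_size, pop))]
    members <- lapply(keep, function(g)
      surrogateModel(envelope, L[g, ], s_if[g], s_solv[g],
                     induced_fit_penalty = config$induced_fit_penalty,
                     base_energy = config$base_energy))
    new("ModelFamily", envelope = envelope, members = members,
        config = config, seed = as.integer(seed))
  })
}
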