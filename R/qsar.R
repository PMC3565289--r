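# Surrogate-model prediction (4D/5D/6D), consensus, and validation metrics.

#' Boltzmann weights of a set of pose energies
#'
#' w_i = exp(-E_i/RT) / sum_j exp(-E_j/RT), computed with a max-shift for
#' numerical stability.
#'
#' @param energies kcal/mol.
#' @param model a [NonbondedModel-class] (houses R and T), or a numeric
#'   temperature in K.
#' @return positive weights summing to 1.
#' @export
boltzmannWeights <- function(energies, model = nonbondedModel()) {
  if (length(energies) == 0)
    .afp_stop("empty energy list", "afp_precondition")
  if (is.numeric(model)) model <- nonbondedModel(temperature = model)
  rt <- model@gas_constant * model@temperature
  e <- energies - min(energies)
  w <- exp(-e / rt)
  w / sum(w)
}

# collapse exact duplicate poses (same coordinates to 1e-6 and equal
# conformational energy): a duplicated pose is the same microstate and must
# not be double-counted in the partition sum.
.dedupe_ensemble <- function(ens) {
  sig <- vapply(seq_along(ens@poses), function(i)
    paste(signif(ens@conf_energies[i], 10),
          paste(round(coords(ens@poses[[i]]), 6), collapse = ","),
          sep = "|"), character(1))
  keep <- !duplicated(sig)
  if (all(keep)) return(ens)
  new("PoseEnsemble", ligand_id = ens@ligand_id, poses = ens@poses[keep],
      conf_energies = ens@conf_energies[keep])
}

# feature bundle for one ensemble: per-scenario flattened feature matrices
# ((P*7) x n_poses, row index (p-1)*7 + label), solvation proxies and
# Boltzmann weights over the deduplicated poses.
.ensemble_features <- function(ens, envelope, scenarios, nb) {
  ens <- .dedupe_ensemble(ens)
  P <- nrow(envelope@positions)
  flat <- vector("list", 6)
  for (s in scenarios) {
    cols <- lapply(ens@poses, function(p)
      as.vector(t(.pose_feature_matrix(p, envelope, s))))
    flat[[s + 1]] <- matrix(unlist(cols), nrow = P * 7)
  }
  list(flat = flat,
       solv = vapply(ens@poses, .pose_solv_proxy, numeric(1)),
       weights = boltzmannWeights(ens@conf_energies, nb),
       n_poses = length(ens@poses))
}

# Boltzmann-combine per-pose pseudo free energies
.combine_G <- function(pose_G, weights, rt) {
  m <- min(pose_G)
  m - rt * log(sum(weights * exp(-(pose_G - m) / rt)))
}

# predict from a precomputed feature bundle
.predict_from_features <- function(feat, labels, s_if, s_solv,
                                   induced_fit_penalty, base_energy, nb) {
  P <- length(labels)
  fidx <- (seq_len(P) - 1L) * 7L + labels
  part <- colSums(feat$flat[[s_if + 1]][fidx, , drop = FALSE])
  pose_G <- base_energy + part + induced_fit_penalty * 0.1 * s_if +
    .SOLV_SCENARIO_SCALE[s_solv + 1L] * feat$solv
  rt <- nb@gas_constant * nb@temperature
  G <- .combine_G(pose_G, feat$weights, rt)
  -G / .pic50_slope(nb)
}

#' Predict the pIC50 of a pose ensemble with one surrogate model
#'
#' Per-pose pseudo binding free energies from [scorePose()] are
#' Boltzmann-combined with the pose weights derived from the
#' conformational energies (exact duplicate poses are collapsed first),
#' then converted to pIC50 via -dG/(ln(10) R T).
#'
#' @param model a [SurrogateModel-class].
#' @param ensemble a [PoseEnsemble-class].
#' @param nb a [NonbondedModel-class].
#' @return predicted pIC50 (numeric scalar).
#' @export
modelPredict <- function(model, ensemble, nb = nonbondedModel()) {
  feat <- .ensemble_features(ensemble, model@envelope,
                             model@induced_fit_scenario, nb)
  .predict_from_features(feat, model@labels, model@induced_fit_scenario,
                         model@solvation_scenario,
                         model@induced_fit_penalty, model@base_energy, nb)
}

#' Consensus prediction of a model family
#'
#' Mean and population standard deviation of the member predictions.
#'
#' @param family a [ModelFamily-class].
#' @param ensemble a [PoseEnsemble-class].
#' @param nb a [NonbondedModel-class].
#' @return list with `mean` and `sd` (pIC50 units).
#' @export
familyPredict <- function(family, ensemble, nb = nonbondedModel()) {
  scen <- sort(unique(vapply(family@members,
                             function(m) m@induced_fit_scenario, integer(1))))
  feat <- .ensemble_features(ensemble, family@envelope, scen, nb)
  preds <- vapply(family@members, function(m)
    .predict_from_features(feat, m@labels, m@induced_fit_scenario,
                           m@solvation_scenario, m@induced_fit_penalty,
                           m@base_energy, nb), numeric(1))
  n <- length(preds)
  list(mean = mean(preds), sd = sqrt(sum((preds - mean(preds))^2) / n))
}

#' Predictive r2 on an external test set
#'
#' r2_pred = 1 - sum(pred-exp)^2 / sum(exp - train_mean)^2, plus the
#' fraction of compounds predicted within a factor of 10 in affinity
#' (|pred - exp| <= 1.0 pIC50 units, inclusive).
#'
#' @param pred_test predicted pIC50 values.
#' @param exp_test experimental pIC50 values.
#' @param train_mean mean experimental pIC50 of the training set.
#' @return list with `r2_pred` and `fraction_within_factor10`.
#' @export
predictiveR2 <- function(pred_test, exp_test, train_mean) {
  if (length(pred_test) == 0 || length(pred_test) != length(exp_test))
    .afp_stop("test vectors must be non-empty and of equal length",
              "afp_precondition")
  denom <- sum((exp_test - train_mean)^2)
  if (denom == 0)
    .afp_stop("predictive r2 undefined: zero test variance about the training mean",
              "afp_undefined_metric")
  list(r2_pred = 1 - sum((pred_test - exp_test)^2) / denom,
       fraction_within_factor10 =
         mean(abs(pred_test - exp_test) <= 1.0 + 1e-12))
}

#' Cross-validated r2 (q2) by fold retraining
#'
#' Training entries are split into `n_folds` folds stratified by affinity
#' (seeded shuffling within affinity strata); for each fold a family is
#' retrained on the remainder and the held-out entries predicted.
#' q2 = 1 - PRESS/SS_tot, SS_tot taken about the per-fold training means.
#'
#' @param dataset a [QsarDataset-class] (its train split is used).
#' @param envelope the shared [Envelope-class].
#' @param config GA settings from [gaConfig()].
#' @param n_folds number of folds (default 5; >= 2).
#' @param seed integer seed controlling fold assignment and retraining.
#' @param nb a [NonbondedModel-class].
#' @return list with `q2`, `press`, `ss_tot` and per-entry held-out
#'   predictions.
#' @export
crossValidatedR2 <- function(dataset, envelope, config = gaConfig(),
                             n_folds = 5, seed = 1, nb = nonbondedModel()) {
  if (n_folds < 2) .afp_stop("need at least 2 folds", "afp_precondition")
  tr <- which(dataset@split == "train")
  if (length(tr) < n_folds)
    .afp_stop("fewer training entries than folds", "afp_precondition")
  y <- dataset@pic50[tr]
  fold <- .with_seed(seed, {
    ord <- order(y + stats::runif(length(y), 0, 1e-9))  # seeded tie-break
    f <- integer(length(y))
    f[ord] <- rep_len(sample(n_folds), length(y))
    f
  })
  pred <- numeric(length(tr))
  ss <- numeric(length(tr))
  for (k in seq_len(n_folds)) {
    hold <- which(fold == k)
    sub <- .subset_dataset(dataset, tr[-hold], tr[hold])
    fam <- gaTrain(sub, envelope = envelope, config = config,
                   seed = seed + k, nb = nb)
    for (h in seq_along(hold)) {
      fp <- familyPredict(fam, dataset@ensembles[[tr[hold[h]]]], nb)
      pred[hold[h]] <- fp$mean
    }
    ss[hold] <- (y[hold] - mean(y[-hold]))^2
  }
  press <- sum((pred - y)^2)
  ss_tot <- sum(ss)
  list(q2 = 1 - press / ss_tot, press = press, ss_tot = ss_tot,
       predictions = stats::setNames(pred, dataset@ids[tr]))
}

# build a QsarDataset from index vectors (train/test reassignment)
.subset_dataset <- function(dataset, train_idx, test_idx = integer()) {
  idx <- c(train_idx, test_idx)
  qsarDataset(dataset@ids[idx], dataset@ensembles[idx], dataset@pic50[idx],
              rep(c("train", "test"), c(length(train_idx), length(test_idx))))
}

#' Y-scrambling control
#'
#' For each round the training labels are randomly permuted (seeded), a
#' family is retrained with a reduced GA budget, and the cross-validated
#' q2 recorded.  A predictive model's q2 should collapse under scrambling.
#'
#' @param dataset a [QsarDataset-class].
#' @param envelope the shared [Envelope-class].
#' @param config full-budget GA settings (reduced internally unless
#'   `scramble_config` is given).
#' @param n_rounds number of scrambling rounds (default 10).
#' @param seed integer seed.
#' @param scramble_config optional explicit reduced-budget [gaConfig()].
#' @param n_folds folds for the per-round q2 (default 5).
#' @param include_identity prepend a control round with the identity
#'   permutation (reproduces the unscrambled q2 at the reduced budget).
#' @param nb a [NonbondedModel-class].
#' @return list with `q2_values`, `mean_q2` and the reduced config used.
#' @export
yScramble <- function(dataset, envelope, config = gaConfig(), n_rounds = 10,
                      seed = 1, scramble_config = NULL, n_folds = 5,
                      include_identity = FALSE, nb = nonbondedModel()) {
  if (n_rounds < 1) .afp_stop("need at least one round", "afp_precondition")
  if (is.null(scramble_config)) {
    scramble_config <- config
    scramble_config$population <- max(40L, config$population %/% 2L)
    scramble_config$generations <- max(30L, config$generations %/% 3L)
  }
  tr <- which(dataset@split == "train")
  rounds <- if (include_identity) 0:n_rounds else seq_len(n_rounds)
  q2s <- vapply(rounds, function(r) {
    ds <- dataset
    if (r > 0) {
      perm <- .with_seed(seed * 1000L + r, sample(length(tr)))
      ds@pic50[tr] <- dataset@pic50[tr][perm]
    }
    crossValidatedR2(ds, envelope, scramble_config, n_folds = n_folds,
                     seed = seed + r, nb = nb)$q2
  }, numeric(1))
  names(q2s) <- ifelse(rounds == 0, "identity", paste0("round", rounds))
  list(q2_values = q2s, mean_q2 = mean(q2s[rounds > 0]),
       config = scramble_config)
}

#' Consensus-scoring flag
#'
#' Accept iff the direct force-field score is favourable (at most
#' `ff_threshold`) and the molecule's interaction energy in the binding
#' site does not exceed its energy in a pre-equilibrated water reference
#' (ties resolve toward binding).  Otherwise the prediction is flagged
#' with the failing criteria.
#'
#' @param quasar_pred surrogate-family pIC50 prediction (reported back
#'   unchanged; flags do not alter the value).
#' @param ff_score direct force-field score, kcal/mol.
#' @param e_site interaction energy in the binding site, kcal/mol.
#' @param e_water interaction energy in the water reference, kcal/mol.
#' @param ff_threshold acceptance threshold for `ff_score` (default 0).
#' @return list with `status` ("accept"/"flag"), `reasons`, `pic50`.
#' @export
consensusFlag <- function(quasar_pred, ff_score, e_site, e_water,
                          ff_threshold = 0) {
  stopifnot(is.finite(quasar_pred), is.finite(ff_score),
            is.finite(e_site), is.finite(e_water))
  reasons <- character()
  if (ff_score > ff_threshold)
    reasons <- c(reasons, "unfavourable force-field score")
  if (e_site > e_water) reasons <- c(reasons, "prefers water")
  list(status = if (length(reasons)) "flag" else "accept",
       reasons = reasons, pic50 = quasar_pred)
}

#' Validate a trained family on a dataset
#'
#' Computes the cross-validated q2 on the training split, the predictive
#' r2 and factor-of-10 fraction on the test split, and optionally a
#' Y-scrambling distribution.
#'
#' @param dataset a [QsarDataset-class].
#' @param envelope the shared [Envelope-class].
#' @param family a trained [ModelFamily-class] (used for the test-set
#'   predictions).
#' @param config GA settings for the fold retraining.
#' @param seed integer seed.
#' @param n_scramble Y-scrambling rounds (0 to skip).
#' @param nb a [NonbondedModel-class].
#' @return A [ValidationReport-class].
#' @export
validateFamily <- function(dataset, envelope, family, config = gaConfig(),
                           seed = 1, n_scramble = 0, nb = nonbondedModel()) {
  cv <- crossValidatedR2(dataset, envelope, config, seed = seed, nb = nb)
  te <- which(dataset@split == "test")
  tr <- which(dataset@split == "train")
  pred <- vapply(te, function(i)
    familyPredict(family, dataset@ensembles[[i]], nb)$mean, numeric(1))
  pr <- predictiveR2(pred, dataset@pic50[te], mean(dataset@pic50[tr]))
  ys <- if (n_scramble > 0)
    yScramble(dataset, envelope, config, n_rounds = n_scramble,
              seed = seed, nb = nb)$q2_values
  else numeric()
  new("ValidationReport", q2 = cv$q2, r2_pred = pr$r2_pred,
      fraction_within_factor10 = pr$fraction_within_factor10,
      yscramble_q2 = as.numeric(ys))
}
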