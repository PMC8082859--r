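#' Define a synthetic three-batch drift scenario
#'
#' Emulates three chronologically released batches of binary-labelled
#' feature vectors (train / test / score analogues) with Tox21-like class
#' imbalance and a controllable covariate drift: class-conditional
#' multivariate Gaussians with unit-variance noise, whose means in the two
#' later batches are translated by \code{drift_delta} noise standard
#' deviations along a fixed random direction. \code{drift_delta = 0} makes
#' all three batches exchangeable.
#'
#' @param n_train,n_test,n_score Batch sizes.
#' @param d Feature dimension (default 50).
#' @param active_fraction Expected fraction of actives (default 0.1).
#' @param drift_delta Mean shift of the test/score batches, in units of
#'   \code{noise_sd} (default 0 = no drift).
#' @param noise_sd Within-class noise standard deviation (default 1).
#' @param class_sep Distance between the class means, in units of
#'   \code{noise_sd} (default 2: overlapping but learnable classes).
#' @param drift_align Cosine between the drift direction and the
#'   class-separation axis (default 0.7). A drift orthogonal to the class
#'   axis leaves every margin-based nonconformity distribution unchanged and
#'   is therefore invisible to the calibration diagnostics; a fixed
#'   alignment makes \code{drift_delta} an actual dial on miscalibration.
#'   The remaining component lies along a seed-fixed random orthogonal
#'   direction.
#' @param drift_mode \code{"covariate"} (mean translation, the default) or
#'   \code{"label_flip"} (labels of the drifted batches flipped with
#'   probability \code{drift_delta / 10}) for robustness checks.
#' @param seed Integer seed; generation is bit-reproducible from it.
#' @return An object of class \code{drift_scenario}.
#' @export
drift_scenario <- function(n_train = 2000L, n_test = 2000L, n_score = 2000L,
                           d = 50L, active_fraction = 0.1, drift_delta = 0,
                           noise_sd = 1, class_sep = 2, drift_align = 0.7,
                           drift_mode = c("covariate", "label_flip"), seed = 1L) {
  drift_mode <- match.arg(drift_mode)
  stopifnot(active_fraction > 0, active_fraction < 1, drift_delta >= 0,
            noise_sd > 0, class_sep >= 0, d >= 1,
            drift_align >= -1, drift_align <= 1)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_score = as.integer(n_score), d = as.integer(d),
                 active_fraction = active_fraction, drift_delta = drift_delta,
                 noise_sd = noise_sd, class_sep = class_sep,
                 drift_align = drift_align, drift_mode = drift_mode,
                 seed = as.integer(seed)),
            class = "drift_scenario")
}

#' Generate the three labelled batches of a drift scenario
#'
#' @param scenario A \code{\link{drift_scenario}}.
#' @return A list with elements \code{train}, \code{test}, \code{score},
#'   each a list with feature matrix \code{x} (\code{n x d}) and 0/1 label
#'   vector \code{y}.
#' @export
generate_batches <- function(scenario) {
  stopifnot(inherits(scenario, "drift_scenario"))
  s <- scenario
  set.seed(s$seed)
  # fixed class-separation axis u and drift direction v with a fixed
  # cosine (drift_align) to u, the rest along a random orthogonal direction
  u <- stats::rnorm(s$d); u <- u / sqrt(sum(u^2))
  w <- stats::rnorm(s$d); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
  v <- s$drift_align * u + sqrt(1 - s$drift_align^2) * w
  mu0 <- rep(0, s$d)
  mu1 <- s$class_sep * s$noise_sd * u
  one_batch <- function(n, drifted) {
    y <- stats::rbinom(n, 1L, s$active_fraction)
    if (sum(y == 0L) < 2L || sum(y == 1L) < 2L)
      stop("batch too small to contain both classes; increase n or active_fraction")
    shift <- if (drifted && s$drift_mode == "covariate")
      s$drift_delta * s$noise_sd * v else rep(0, s$d)
    x <- matrix(stats::rnorm(n * s$d, sd = s$noise_sd), n, s$d)
    x <- x + outer(rep(1, n), mu0 + shift) + outer(y, mu1)
    if (drifted && s$drift_mode == "label_flip") {
      flip <- stats::rbinom(n, 1L, min(s$drift_delta / 10, 1)) == 1L
      y[flip] <- 1L - y[flip]
    }
    list(x = x, y = y)
  }
  list(train = one_batch(s$n_train, FALSE),
       test = one_batch(s$n_test, TRUE),
       score = one_batch(s$n_score, TRUE))
}

#' Sparse count-feature variant of the batch generator
#'
#' Real signature-descriptor matrices are sparse nonnegative counts; this
#' variant emits batches as sparse \code{Matrix::dgCMatrix} Poisson counts
#' whose class-conditional rates differ along the same fixed directions as
#' the dense generator, for integration tests with the descriptor-matrix
#' readers. Drift translates the log-rates of the later batches.
#'
#' @inheritParams generate_batches
#' @param base_rate Mean Poisson rate of the count features (default 0.3,
#'   i.e. mostly zeros).
#' @return As \code{\link{generate_batches}}, with sparse \code{x}.
#' @export
generate_sparse_batches <- function(scenario, base_rate = 0.3) {
  stopifnot(inherits(scenario, "drift_scenario"))
  s <- scenario
  set.seed(s$seed + 1L)
  u <- stats::rnorm(s$d); u <- u / sqrt(sum(u^2))
  w <- stats::rnorm(s$d); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
  v <- s$drift_align * u + sqrt(1 - s$drift_align^2) * w
  one_batch <- function(n, drifted) {
    y <- stats::rbinom(n, 1L, s$active_fraction)
    if (sum(y == 0L) < 2L || sum(y == 1L) < 2L)
      stop("batch too small to contain both classes")
    shift <- if (drifted) s$drift_delta * 0.5 * v else rep(0, s$d)
    lograte <- log(base_rate) + outer(y, 0.5 * s$class_sep * u) +
      outer(rep(1, n), shift)
    x <- matrix(stats::rpois(n * s$d, lambda = exp(lograte)), n, s$d)
    list(x = methods::as(x, "CsparseMatrix"), y = y)
  }
  list(train = one_batch(s$n_train, FALSE),
       test = one_batch(s$n_test, TRUE),
       score = one_batch(s$n_score, TRUE))
}

#' Fixed molecule fixtures for descriptor and preprocessing tests
#'
#' A frozen, versioned list of small molecules with 0/1 activity labels,
#' covering every preprocessing branch: a sodium salt, charged species,
#' an InChI-duplicate pair with conflicting labels, a duplicate pair with
#' agreeing labels, a three-heavy-atom molecule (too small), an inorganic
#' salt (non-organic), an unparseable entry, and benzene for the
#' symmetry-count property of the signature descriptor.
#'
#' @return A data frame with columns \code{source_id}, \code{smiles},
#'   \code{label}.
#' @export
molecule_fixtures <- function() {
  fx <- matrix(c(
    "mol01", "c1ccccc1",                 "0",  # benzene: 6 equivalent atoms
    "mol02", "CCC",                      "0",  # propane: 3 heavy atoms -> too_small
    "mol03", "CC(=O)[O-].[Na+]",         "1",  # sodium acetate: salt strip + neutralise
    "mol04", "[Na+].[Cl-]",              "0",  # no organic fragment -> non_organic
    "mol05", "CC(=O)Oc1ccccc1C(=O)O",    "0",  # aspirin
    "mol06", "OC(=O)c1ccccc1OC(C)=O",    "1",  # aspirin again, conflicting label
    "mol07", "CCO",                      "0",  # ethanol: 3 heavy atoms -> too_small
    "mol08", "c1ccc2ccccc2c1",           "0",  # naphthalene
    "mol09", "C[N+](C)(C)C",             "1",  # tetramethylammonium (quaternary, kept charged)
    "mol10", "CC(N)C(=O)O",              "0",  # alanine
    "mol11", "CC(N)C(=O)[O-]",           "0",  # alanine carboxylate: neutralises to mol10, agreeing
    "mol12", "not_a_smiles",             "0",  # unparseable
    "mol13", "Oc1ccccc1",                "1",  # phenol
    "mol14", "[O-]c1ccccc1",             "1",  # phenolate: neutralises to phenol, agreeing
    "mol15", "CCCCO",                    "0",  # n-butanol
    "mol16", "CC(C)O",                   "1",  # isopropanol
    "mol17", "CCN(CC)CC",                "0",  # triethylamine
    "mol18", "CC[NH+](CC)CC.[Cl-]",      "0",  # triethylammonium chloride: strips + neutralises to mol17
    "mol19", "Clc1ccccc1",               "0",  # chlorobenzene
    "mol20", "CC(=O)Nc1ccc(O)cc1",       "0",  # paracetamol
    "mol21", "CN1CCC[C@H]1c1cccnc1",     "1",  # nicotine
    "mol22", "O=[N+]([O-])c1ccccc1",     "1",  # nitrobenzene (charge-separated group kept)
    "mol23", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "0",  # ibuprofen
    "mol24", "NCCc1ccc(O)c(O)c1",        "1",  # dopamine
    "mol25", "CSC",                      "0",  # dimethyl sulfide: 3 heavy atoms -> too_small
    "mol26", "OCC(O)CO",                 "0",  # glycerol
    "mol27", "C1CCCCC1",                 "0",  # cyclohexane
    "mol28", "N#Cc1ccccc1",              "1",  # benzonitrile
    "mol29", "CC(=O)C",                  "0",  # acetone
    "mol30", "OS(=O)(=O)c1ccccc1",       "0"   # benzenesulfonic acid
  ), ncol = 3, byrow = TRUE)
  data.frame(source_id = fx[, 1], smiles = fx[, 2],
             label = as.integer(fx[, 3]))
}
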