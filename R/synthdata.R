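# Synthetic task generators: self-contained labeled molecule sets for
# end-to-end testing of the full pipeline, plus a controlled
# noisy-conformer multiple-instance task in which exactly one conformer
# per molecule carries the label-determining geometry.

# drug-like scaffold x substituent enumeration; "{R}" marks the
# substitution site
SCAFFOLDS <- c(
  "c1ccc({R})cc1",            # benzene
  "c1cc({R})ccn1",            # pyridine
  "c1cnc({R})nc1",            # pyrimidine
  "c1cc({R})co1",             # furan
  "c1cc({R})cs1",             # thiophene
  "c1cc({R})[nH]c1",          # pyrrole
  "c1ccc2c(c1)c({R})c[nH]2",  # 3-substituted indole
  "c1ccc2cc({R})ccc2c1",      # naphthalene
  "C1CCC({R})CC1",            # cyclohexane
  "C1CCC({R})NC1",            # piperidine
  "Nc1ccc({R})cc1",           # aniline
  "Oc1ccc({R})cc1",           # phenol
  "COc1ccc({R})cc1",          # anisole
  "Cc1ccc({R})cc1",           # toluene
  "NC(=O)c1ccc({R})cc1",      # benzamide
  "N#Cc1ccc({R})cc1",         # benzonitrile
  "CC(=O)c1ccc({R})cc1",      # acetophenone
  "c1ccc(-c2ccc({R})cc2)cc1"  # biphenyl
)

SUBSTITUENTS <- c(
  "", "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC", "F", "Cl",
  "Br", "C#N", "C=C", "CO", "C(=O)O", "C(=O)N", "C(=O)OC", "C(F)(F)F",
  "S(N)(=O)=O", "[N+](=O)[O-]"
)

CASE_SMILES <- "Nc1ccc(-c2cc(Nc3ccc(S(N)(=O)=O)cc3)[nH]n2)cc1"

#' Built-in drug-like SMILES library
#'
#' Deterministic enumeration of small drug-like molecules
#' (scaffold x substituent); the source pool for the synthetic task
#' generators.
#'
#' @return Character vector of SMILES strings.
#' @export
molecule_library <- function() {
  out <- unlist(lapply(SCAFFOLDS, function(sc) {
    vapply(SUBSTITUENTS, function(sub) {
      if (sub == "") {
        gsub("(\\(\\{R\\}\\))|(\\{R\\})", "", sc)
      } else {
        gsub("\\{R\\}", sub, sc, fixed = FALSE)
      }
    }, character(1))
  }))
  unique(unname(out))
}

#' Radius of gyration of a coordinate set
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @return Scalar radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(coords) {
  centered <- sweep(coords, 2, colMeans(coords))
  sqrt(mean(rowSums(centered^2)))
}

clip_logm <- function(x, lo = 0.1, hi = 21.8) pmin(pmax(x, lo), hi)

# standardized, deduplicated library sample of exactly n molecules;
# the standardized library is cached for the session
synthdata_env <- new.env(parent = emptyenv())

sample_library <- function(n, seed) {
  if (is.null(synthdata_env$std_lib)) {
    std <- suppressMessages(standardize_molecules(
      molecule_library(), canonical_tautomer = FALSE, on_error = "drop"
    ))
    synthdata_env$std_lib <-
      dplyr::distinct(std, .data$smiles_canonical, .keep_all = TRUE)
  }
  pool <- synthdata_env$std_lib
  if (n > nrow(pool)) {
    abort(sprintf("n = %d exceeds the %d enumerable unique molecules.",
                  n, nrow(pool)),
          class = "equivs_generation_error")
  }
  out <- pool[with_seed(seed, sample.int(nrow(pool), n)), ]
  out$molecule_id <- default_ids(n)
  out$smiles <- out$smiles_canonical
  out
}

#' Synthetic bioactivity regression task
#'
#' Samples `n` molecules from the built-in library, standardizes them, and
#' assigns labels as an affine function of two invariant molecular
#' statistics (heavy-atom count and ring count) plus Gaussian noise,
#' clipped to the plausible -logM range 0.1-21.8. Labels are exactly
#' reproducible from the seed.
#'
#' @param n Number of molecules (>= 10).
#' @param noise_sigma Gaussian label noise standard deviation (default
#'   0.1 -logM).
#' @param seed Integer seed.
#' @param coefs Affine coefficients `(intercept, per heavy atom,
#'   per ring)`.
#' @return A tibble with `molecule_id`, `smiles`, `smiles_canonical`,
#'   `n_heavy_atoms`, `n_rings`, `value_logM`, `target_id`,
#'   `activity_type`.
#' @export
make_regression_task <- function(n, noise_sigma = 0.1, seed = 1,
                                 coefs = c(1.0, 0.25, 0.8)) {
  stopifnot(n >= 10, noise_sigma >= 0, length(coefs) == 3)
  std <- sample_library(n, seed)
  noise <- with_seed(seed + 1L, rnorm(nrow(std), 0, noise_sigma))
  std$value_logM <- clip_logm(
    coefs[1] + coefs[2] * std$n_heavy_atoms + coefs[3] * std$n_rings +
      noise
  )
  std$target_id <- "SYNTH-T1"
  std$activity_type <- "IC50"
  std
}

#' Synthetic noisy-conformer multiple-instance task
#'
#' Emulates conformer-ensemble noise: each molecule gets a full prepared
#' ensemble (ETKDG + MMFF94 + alignment + H-stripping), then all but one
#' randomly designated *informative* conformer have their coordinates
#' corrupted by large i.i.d. Gaussian atomic displacements. The label is an
#' affine function of the informative conformer's radius of gyration (plus
#' Gaussian noise), so only the intact conformer carries the
#' label-determining geometry and attention must find it.
#'
#' @param n Number of molecules.
#' @param M Conformers per molecule (>= 1; with `M = 1` the task
#'   degenerates to single-conformer regression and no corruption is
#'   applied).
#' @param noise_sigma Label noise standard deviation (default 0.1).
#' @param perturb_sd Standard deviation (Angstrom) of the per-coordinate
#'   displacements corrupting the uninformative conformers (default 1.5,
#'   on the order of a covalent bond length: large enough to destroy the
#'   geometry while keeping squared-distance features on a well-conditioned
#'   scale).
#' @param seed Integer seed.
#' @param coefs Affine coefficients `(intercept, per Angstrom of radius
#'   of gyration)`.
#' @return A tibble with `molecule_id`, `smiles_canonical`, `ensemble`
#'   (corrupted), `informative_conformer`, `rg` (informative conformer's
#'   radius of gyration), `value_logM`.
#' @export
make_noisy_conformer_task <- function(n, M = 10, noise_sigma = 0.1,
                                      perturb_sd = 1.5, seed = 1,
                                      coefs = c(1.0, 1.5)) {
  stopifnot(n >= 3, M >= 1, length(coefs) == 2)
  data <- sample_library(n, seed) |>
    prepare_conformers(n_conformers = M, seed = seed,
                       standardize = FALSE)
  n_kept <- nrow(data)
  info <- with_seed(seed + 1L, sample.int(M, n_kept, replace = TRUE))
  rg <- vapply(seq_len(n_kept), function(i) {
    radius_of_gyration(data$ensemble[[i]]$coords[[info[i]]])
  }, numeric(1))
  # corrupt the uninformative conformers
  if (M > 1 && perturb_sd > 0) {
    data$ensemble <- with_seed(seed + 2L, {
      lapply(seq_len(n_kept), function(i) {
        e <- data$ensemble[[i]]
        for (m in setdiff(seq_len(M), info[i])) {
          e$coords[[m]] <- e$coords[[m]] +
            matrix(rnorm(length(e$coords[[m]]), 0, perturb_sd),
                   nrow(e$coords[[m]]), 3)
        }
        e
      })
    })
  }
  noise <- with_seed(seed + 3L, rnorm(n_kept, 0, noise_sigma))
  data$informative_conformer <- info
  data$rg <- rg
  data$value_logM <- clip_logm(coefs[1] + coefs[2] * rg + noise)
  data
}

#' Case-molecule fixture
#'
#' A single sulfonamide-bearing CDK2 inhibitor with a reported bioactivity
#' of 9.0 -logM, prepared with the default 10-conformer pipeline; used for
#' interpretation examples and tests.
#'
#' @param seed Integer seed for conformer embedding.
#' @param n_conformers Number of conformers (default 10).
#' @return A one-row tibble with `molecule_id`, `smiles`, `ensemble` and
#'   `value_logM = 9.0`.
#' @export
case_molecule_fixture <- function(seed = 42, n_conformers = 10) {
  data <- tibble(molecule_id = "case-cdk2", smiles = CASE_SMILES) |>
    prepare_conformers(n_conformers = n_conformers, seed = seed)
  data$value_logM <- 9.0
  data
}
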