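# Shared fixtures, memoised per test run (conformer generation and model
# training are the expensive steps; each is computed once and reused).

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, code) {
  if (is.null(fixture_env[[name]])) {
    fixture_env[[name]] <- force(code)
  }
  fixture_env[[name]]
}

# 12 small molecules, 3 conformers each: cheap general-purpose fixture
tiny_prep <- function() {
  fixture("tiny_prep", {
    make_regression_task(12, noise_sigma = 0.1, seed = 101) |>
      prepare_conformers(n_conformers = 3, seed = 101,
                         standardize = FALSE)
  })
}

tiny_graphs <- function() {
  fixture("tiny_graphs", build_graphs(tiny_prep()))
}

# one prepared molecule with the default 10 conformers
ten_conf_prep <- function() {
  fixture("ten_conf_prep", {
    make_regression_task(10, noise_sigma = 0, seed = 202)[1:3, ] |>
      prepare_conformers(n_conformers = 10, seed = 202,
                         standardize = FALSE)
  })
}

prep_smiles <- function(smiles, n_conformers = 3, seed = 7,
                        strip = TRUE) {
  tibble::tibble(molecule_id = "m1", smiles = smiles) |>
    standardize_molecules(canonical_tautomer = FALSE) |>
    generate_conformers(n_conformers = n_conformers, seed = seed) |>
    optimize_conformers() |>
    align_conformers(strip_h = strip)
}

# uniform random 3D rotation + translation
random_rigid_motion <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, 0, 5))
}

apply_rigid <- function(x, motion) {
  sweep(x %*% motion$R, 2, motion$t, `+`)
}

# rigidly move every conformer of a graph (same or different motions)
transform_graph_coords <- function(graph, seed, per_conformer = TRUE) {
  coords <- lapply(seq_len(graph$M), function(m) {
    motion <- random_rigid_motion(seed + if (per_conformer) m else 0)
    apply_rigid(graph$coords[[m]], motion)
  })
  graph$coords <- coords
  graph$HC <- do.call(cbind, coords)
  graph
}

# relabel atoms of an ensemble by a permutation (perm[i] = new index of
# old atom i) and rebuild; independent construction used for the
# permutation-invariance tests
permute_ensemble <- function(ens, perm) {
  inv <- order(perm)
  ens$elements <- ens$elements[inv]
  ens$coords <- lapply(ens$coords, function(x) x[inv, , drop = FALSE])
  ens$perception$atoms <- ens$perception$atoms[inv, ]
  b <- ens$perception$bonds
  b$begin <- perm[b$begin]
  b$end <- perm[b$end]
  ens$perception$bonds <- b
  ens
}

# dihedral angle (degrees) between atoms i-j-k-l
dihedral <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  (ang * 180 / pi) %% 360
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# noisy-conformer MIL experiment (full model vs no-attention ablation),
# memoised per seed; the scale (n = 100, M = 10, 40 epochs) keeps one run
# around a minute while leaving a wide margin between the two variants
mil_experiment <- function(seed) {
  fixture(paste0("mil_", seed), {
    task <- make_noisy_conformer_task(100, M = 10, seed = seed)
    data <- task |> build_graphs() |> split_dataset(seed = seed)
    test <- dplyr::filter(data, .split == "test")
    fit_full <- equivs_train(
      data, control = train_control(epochs = 40, seed = seed))
    fit_noaa <- equivs_train(
      data, config = equivs_config(variant = "no_aa"),
      control = train_control(epochs = 40, seed = seed))
    mse_of <- function(fit) {
      pr <- predict(fit, test, conformers = FALSE)
      mean((test$value_logM - pr$.pred)^2)
    }
    pr_full <- predict(fit_full, test)
    ranking <- rank_conformers(pr_full)
    top <- ranking |>
      dplyr::group_by(molecule_id) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::inner_join(
        dplyr::select(test, molecule_id, informative_conformer),
        by = "molecule_id")
    list(
      test = test,
      fit_full = fit_full,
      mse_full = mse_of(fit_full),
      mse_noaa = mse_of(fit_noaa),
      ranking = ranking,
      top_frac = mean(top$conformer == top$informative_conformer)
    )
  })
}
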