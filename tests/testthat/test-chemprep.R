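# Structure standardization and conformer preparation.

test_that("standardization canonicalizes, strips salts and neutralizes", {
  out <- standardize_molecules(c("CCO", "C(=O)[O-].[Na+]", "OCC"))
  expect_equal(out$smiles_canonical[1], "CCO")
  expect_equal(out$n_heavy_atoms[1], 3L)
  # ethanol written differently canonicalizes identically (round-trip form)
  expect_equal(out$smiles_canonical[3], out$smiles_canonical[1])
  # sodium carboxylate -> neutral parent acid, counter-ion removed
  expect_false(grepl("Na", out$smiles_canonical[2]))
  expect_false(grepl("\\.", out$smiles_canonical[2]))
  expect_false(grepl("-", out$smiles_canonical[2], fixed = TRUE))
  expect_setequal(out$std_flags[[2]], c("fragment_parent", "uncharge"))
})

test_that("unparseable SMILES are rejected or dropped", {
  expect_error(
    standardize_molecules("not_a_smiles", on_error = "error"),
    class = "equivs_parse_error"
  )
  expect_warning(
    out <- standardize_molecules(c("CCO", "not_a_smiles")),
    "dropped"
  )
  expect_equal(nrow(out), 1L)
  expect_error(standardize_molecules(""), class = "equivs_parse_error")
})

test_that("conformer generation honors count, seed determinism", {
  std <- standardize_molecules("CCO")
  ens10 <- generate_conformers(std, seed = 5)$ensemble[[1]]
  expect_equal(n_conformers(ens10), 10L)   # default conformer count
  ens1 <- generate_conformers(std, n_conformers = 1, seed = 5)$ensemble[[1]]
  expect_equal(n_conformers(ens1), 1L)
  ens10b <- generate_conformers(std, seed = 5)$ensemble[[1]]
  expect_identical(ens10$coords, ens10b$coords)  # bitwise reproducible
  ens_other <- generate_conformers(std, seed = 6)$ensemble[[1]]
  expect_false(identical(ens10$coords[[1]], ens_other$coords[[1]]))
})

test_that("MMFF94 optimization lowers energies and max_iters = 0 is a no-op", {
  std <- standardize_molecules("CCCO")
  raw <- generate_conformers(std, n_conformers = 4, seed = 3)
  pre <- raw$ensemble[[1]]$energies
  opt <- optimize_conformers(raw, max_iters = 200)
  post <- opt$ensemble[[1]]$energies
  expect_true(all(post <= pre + 1e-8))
  expect_type(opt$ensemble[[1]]$converged, "logical")
  frozen <- optimize_conformers(raw, max_iters = 0)
  expect_equal(frozen$ensemble[[1]]$coords, raw$ensemble[[1]]$coords,
               tolerance = 1e-12)
})

test_that("optimized ethane settles into staggered torsions", {
  std <- standardize_molecules("CC")
  opt <- tibble::tibble(molecule_id = "eth", smiles = "CC") |>
    standardize_molecules() |>
    generate_conformers(n_conformers = 2, seed = 11) |>
    optimize_conformers(max_iters = 500)
  e <- opt$ensemble[[1]]
  h_on_c1 <- which(e$elements == "H")[1]
  h_on_c2 <- which(e$elements == "H")[4]
  for (m in seq_along(e$coords)) {
    ang <- dihedral(e$coords[[m]], h_on_c1, 1, 2, h_on_c2)
    off <- min(abs(ang - c(60, 180, 300)))
    expect_lt(off, 8)
  }
})

test_that("alignment is idempotent, rigid-motion-proof, and strips H", {
  prep <- prep_smiles("CCCCO", n_conformers = 3, strip = FALSE)
  e <- prep$ensemble[[1]]
  expect_true(any(e$elements == "H"))
  stripped <- align_conformers(prep)$ensemble[[1]]
  expect_false(any(stripped$elements == "H"))
  expect_equal(nrow(stripped$coords[[1]]), stripped$perception$n_heavy)

  # idempotence
  twice <- align_conformers(align_conformers(prep))$ensemble[[1]]
  once <- align_conformers(prep)$ensemble[[1]]
  expect_equal(twice$coords, once$coords, tolerance = 1e-10)

  # applying a rigid motion to conformer 2 then re-aligning restores it
  aligned <- align_conformers(prep, strip_h = FALSE)$ensemble[[1]]
  rmsd_pre <- rmsd(aligned$coords[[2]], aligned$coords[[1]],
                   superpose = FALSE)
  moved <- aligned
  motion <- random_rigid_motion(99)
  moved$coords[[2]] <- apply_rigid(moved$coords[[2]], motion)
  realigned <- align_conformers(moved, strip_h = FALSE)
  expect_equal(rmsd(realigned$coords[[2]], realigned$coords[[1]],
                    superpose = FALSE),
               rmsd_pre, tolerance = 1e-6)
  expect_equal(realigned$coords[[2]], aligned$coords[[2]],
               tolerance = 1e-6)
})

test_that("kabsch superposition matches an independent Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(42)
  x <- matrix(rnorm(30), 10, 3)
  motion <- random_rigid_motion(7)
  y <- apply_rigid(x, motion) + matrix(rnorm(30, 0, 0.05), 10, 3)
  fit <- kabsch(y, x)
  ours <- sqrt(mean(rowSums((fit$transform(y) - x)^2)))
  proc <- vegan::procrustes(x, y, scale = FALSE, symmetric = FALSE)
  oracle <- sqrt(proc$ss / nrow(x))
  expect_equal(ours, oracle, tolerance = 1e-8)
})

test_that("SDF round-trip preserves conformer count and coordinates", {
  prep <- tiny_prep()[1:3, ]
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(prep, path)
  back <- read_sdf(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$molecule_id, prep$molecule_id)
  for (i in 1:3) {
    a <- prep$ensemble[[i]]
    b <- back$ensemble[[i]]
    expect_equal(n_conformers(b), n_conformers(a))
    for (m in seq_along(a$coords)) {
      expect_equal(b$coords[[m]], a$coords[[m]], tolerance = 1e-3)
    }
  }
  expect_equal(back$value_logM, prep$value_logM, tolerance = 1e-6)
})

test_that("a default-prepared molecule writes ten SDF records", {
  skip_if_not_installed("ChemmineR")
  prep <- ten_conf_prep()[1, ]
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(prep, path)
  # independent reader confirms the record count
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  expect_equal(length(sdfset), 10L)
})

test_that("malformed SDF input raises a format error", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(character(0), path)
  expect_error(read_sdf(path), class = "equivs_format_error")
  expect_error(read_sdf("does_not_exist.sdf"),
               class = "equivs_format_error")
})
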