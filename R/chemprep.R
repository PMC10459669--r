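# Structure standardization and conformer-ensemble preparation.
#
# Pipeline (in narrative order): standardize -> add hydrogens + ETKDG
# embedding (M conformers, seed + m per conformer) -> MMFF94 optimization ->
# rigid-body alignment to the first conformer -> hydrogen stripping.

# ---- conformer_ensemble class ----------------------------------------------

new_conformer_ensemble <- function(id, smiles, elements, coords, energies,
                                   perception, seed,
                                   converged = NULL,
                                   optimized = FALSE, aligned = FALSE,
                                   stripped = FALSE, label = NULL) {
  structure(
    list(
      id = id, smiles = smiles, elements = elements, coords = coords,
      energies = energies, converged = converged, perception = perception,
      seed = seed, optimized = optimized, aligned = aligned,
      stripped = stripped, label = label
    ),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformer_ensemble> %s: %d conformers, %d atoms (%d heavy)%s%s%s\n",
    x$id, length(x$coords), length(x$elements), x$perception$n_heavy,
    if (x$optimized) ", MMFF94-optimized" else "",
    if (x$aligned) ", aligned" else "",
    if (x$stripped) ", H-stripped" else ""
  ))
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param ens A `conformer_ensemble`.
#' @return Integer conformer count.
#' @export
n_conformers <- function(ens) {
  stopifnot(inherits(ens, "conformer_ensemble"))
  length(ens$coords)
}

perception_from_record <- function(rec) {
  atoms <- dplyr::bind_rows(lapply(rec$atoms, function(a) {
    tibble(
      symbol = a$symbol, degree = a$degree, implicit_h = a$implicit_h,
      formal_charge = a$formal_charge,
      radical_electrons = a$radical_electrons,
      hybridization = a$hybridization, aromatic = a$aromatic,
      total_h = a$total_h
    )
  }))
  bonds <- if (length(rec$bonds)) {
    dplyr::bind_rows(lapply(rec$bonds, function(b) {
      tibble(
        begin = b$begin + 1L, end = b$end + 1L, bond_type = b$bond_type,
        kekulized_order = b$kekulized_order, conjugated = b$conjugated,
        in_ring = b$in_ring, stereo = b$stereo
      )
    }))
  } else {
    tibble(begin = integer(), end = integer(), bond_type = character(),
           kekulized_order = integer(), conjugated = logical(),
           in_ring = logical(), stereo = character())
  }
  list(atoms = atoms, bonds = bonds, n_heavy = rec$n_heavy,
       n_rings = rec$n_rings)
}

coords_from_record <- function(coords_json) {
  lapply(coords_json, function(conf) {
    do.call(rbind, lapply(conf, function(p) as.numeric(unlist(p))))
  })
}

ensemble_from_embed <- function(rec, seed) {
  new_conformer_ensemble(
    id = rec$id,
    smiles = rec$smiles_canonical,
    elements = as.character(unlist(rec$elements)),
    coords = coords_from_record(rec$coords),
    energies = vapply(rec$energies %null% list(),
                      function(e) as.numeric(e %null% NA_real_),
                      numeric(1)),
    perception = perception_from_record(rec),
    seed = seed
  )
}

# resolve a data-frame-or-ensemble argument into a list of ensembles plus
# a reassembly closure, so verbs work on both representations
as_ensemble_list <- function(data) {
  if (inherits(data, "conformer_ensemble")) {
    list(ensembles = list(data),
         rebuild = function(ens_list) ens_list[[1]])
  } else if (is.data.frame(data)) {
    if (!"ensemble" %in% names(data)) {
      abort("`data` must contain an `ensemble` list-column; run generate_conformers() first.")
    }
    list(ensembles = data$ensemble,
         rebuild = function(ens_list) {
           out <- data
           out$ensemble <- ens_list
           out
         })
  } else {
    abort("`data` must be a data frame or a conformer_ensemble.")
  }
}

# ---- standardization -------------------------------------------------------

#' Standardize molecular structures
#'
#' Applies RDKit's structure-standardization pipeline (the MolVS lineage):
#' functional-group normalization, charge recombination, metal
#' disconnection, reionization, charge neutralization, salt/solvent removal
#' (largest-fragment parent) and canonical tautomer selection. Molecules
#' that cannot be parsed or standardized are dropped with a warning (or
#' raise an error when `on_error = "error"`).
#'
#' @param data A data frame with a SMILES column, or a character vector of
#'   SMILES.
#' @param smiles Column holding SMILES strings (tidy-eval; default
#'   `smiles`).
#' @param id Column holding molecule identifiers; generated when absent.
#' @param canonical_tautomer Canonicalize tautomers (slowest step; on by
#'   default).
#' @param on_error `"drop"` (default) removes failing molecules with a
#'   warning; `"error"` aborts on the first failure.
#' @return A tibble with columns `molecule_id`, `smiles`,
#'   `smiles_canonical`, `n_heavy_atoms` and list-column `std_flags`
#'   recording which standardization steps changed the structure.
#' @examples
#' \dontrun{
#' standardize_molecules(c("CCO", "C(=O)([O-])C.[Na+]"))
#' }
#' @export
standardize_molecules <- function(data, smiles = smiles, id = molecule_id,
                                  canonical_tautomer = TRUE,
                                  on_error = c("drop", "error")) {
  on_error <- match.arg(on_error)
  if (is.character(data)) {
    data <- tibble(molecule_id = default_ids(length(data)), smiles = data)
  }
  smiles_col <- rlang::enquo(smiles)
  id_col <- rlang::enquo(id)
  smi <- dplyr::pull(data, !!smiles_col)
  ids <- if (rlang::as_name(id_col) %in% names(data)) {
    as.character(dplyr::pull(data, !!id_col))
  } else {
    default_ids(nrow(data))
  }
  if (any(!nzchar(smi)) || anyNA(smi)) {
    abort("SMILES must be non-empty strings.", class = "equivs_parse_error")
  }
  res <- pychem_call("standardize", list(
    molecules = purrr::map2(ids, smi, ~ list(id = .x, smiles = .y)),
    canonical_tautomer = canonical_tautomer
  ))
  parts <- pychem_partition(res$results)
  if (length(parts$failed)) {
    msgs <- pychem_failure_messages(parts$failed)
    if (on_error == "error") {
      abort(paste0("standardization failed:\n",
                   paste(msgs, collapse = "\n")),
            class = "equivs_parse_error")
    }
    warn(paste0("dropped ", length(msgs), " molecule(s):\n",
                paste(msgs, collapse = "\n")))
  }
  kept <- vapply(parts$ok, function(r) r$id, character(1))
  out <- data
  out$molecule_id <- ids
  out <- dplyr::filter(out, .data$molecule_id %in% kept)
  ord <- match(out$molecule_id, kept)
  out$smiles_canonical <-
    vapply(parts$ok, function(r) r$smiles_canonical, character(1))[ord]
  out$n_heavy_atoms <-
    vapply(parts$ok, function(r) r$n_heavy_atoms, integer(1))[ord]
  out$n_rings <-
    vapply(parts$ok, function(r) r$n_rings, integer(1))[ord]
  out$std_flags <-
    lapply(parts$ok, function(r) as.character(unlist(r$flags)))[ord]
  as_tibble(out)
}

# ---- conformer generation --------------------------------------------------

#' Generate 3D conformers with ETKDG
#'
#' Adds hydrogens and embeds `n_conformers` 3D conformers per molecule with
#' the ETKDG distance-geometry method, using a different random
#' initialization (seed + m) for each conformer so that repeated calls with
#' the same seed are bitwise reproducible. Embedding retries up to five
#' times with incremented seeds, then falls back once to random-coordinate
#' embedding; molecules that still fail raise an embedding error.
#'
#' @param data A data frame with a `smiles_canonical` (preferred) or
#'   `smiles` column, e.g. the output of [standardize_molecules()].
#' @param n_conformers Number of conformers per molecule (default 10).
#' @param seed Integer seed for the embedding RNG.
#' @return `data` with an `ensemble` list-column of `conformer_ensemble`
#'   objects (hydrogens present, unoptimized; per-conformer MMFF94 energies
#'   of the raw embeddings are recorded when the force field applies).
#' @seealso [optimize_conformers()], [align_conformers()],
#'   [prepare_conformers()]
#' @export
generate_conformers <- function(data, n_conformers = 10, seed = 42) {
  stopifnot(is.data.frame(data), n_conformers >= 1)
  smi <- data[["smiles_canonical"]] %null% data[["smiles"]]
  if (is.null(smi)) {
    abort("`data` needs a `smiles_canonical` or `smiles` column.")
  }
  ids <- as.character(data[["molecule_id"]] %null% default_ids(nrow(data)))
  res <- pychem_call("embed", list(
    molecules = purrr::map2(ids, smi, ~ list(id = .x, smiles = .y)),
    n_conformers = n_conformers, seed = seed
  ))
  parts <- pychem_partition(res$results)
  if (length(parts$failed)) {
    abort(paste0("conformer embedding failed:\n",
                 paste(pychem_failure_messages(parts$failed),
                       collapse = "\n")),
          class = "equivs_embedding_error")
  }
  ens <- lapply(parts$ok, ensemble_from_embed, seed = seed)
  names(ens) <- vapply(parts$ok, function(r) r$id, character(1))
  out <- data
  out$molecule_id <- ids
  out$ensemble <- unname(ens[ids])
  as_tibble(out)
}

#' Optimize conformer geometries with the MMFF94 force field
#'
#' Relaxes every conformer of every ensemble with MMFF94. Energies never
#' increase relative to the unoptimized geometry; per-conformer convergence
#' status is recorded. `max_iters = 0` leaves coordinates untouched (only
#' energies are evaluated).
#'
#' @param data A data frame with an `ensemble` list-column, or a single
#'   `conformer_ensemble`.
#' @param max_iters Maximum force-field iterations per conformer
#'   (default 200).
#' @return Input with optimized coordinates, updated `energies` and a
#'   `converged` flag per conformer.
#' @export
optimize_conformers <- function(data, max_iters = 200) {
  stopifnot(max_iters >= 0)
  resolved <- as_ensemble_list(data)
  ens_list <- resolved$ensembles
  req <- list(
    molecules = lapply(ens_list, function(e) {
      if (e$stripped) {
        abort("cannot MMFF94-optimize a hydrogen-stripped ensemble.")
      }
      list(id = e$id, smiles = e$smiles,
           coords = lapply(e$coords, function(m) {
             lapply(seq_len(nrow(m)), function(r) as.numeric(m[r, ]))
           }))
    }),
    max_iters = max_iters
  )
  res <- pychem_call("optimize", req)
  parts <- pychem_partition(res$results)
  if (length(parts$failed)) {
    abort(paste0("force-field setup failed:\n",
                 paste(pychem_failure_messages(parts$failed),
                       collapse = "\n")),
          class = "equivs_forcefield_error")
  }
  by_id <- setNames(parts$ok, vapply(parts$ok, `[[`, character(1), "id"))
  out <- lapply(ens_list, function(e) {
    r <- by_id[[e$id]]
    e$coords <- coords_from_record(r$coords)
    e$energies <- as.numeric(unlist(r$energies))
    e$converged <- as.logical(unlist(r$converged))
    e$optimized <- max_iters > 0
    e
  })
  resolved$rebuild(out)
}

# ---- alignment and hydrogen stripping --------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Returns the rotation and translation that minimize the RMSD of `moving`
#' onto `ref` (rows are points). Reflections are excluded.
#'
#' @param moving,ref Numeric n x 3 matrices with matched rows.
#' @return List with rotation matrix `R`, translation `t` and a `transform`
#'   function applying `x %*% R + t`.
#' @export
kabsch <- function(moving, ref) {
  stopifnot(nrow(moving) == nrow(ref), ncol(moving) == 3, ncol(ref) == 3)
  cm <- colMeans(moving)
  cr <- colMeans(ref)
  mc <- sweep(moving, 2, cm)
  rc <- sweep(ref, 2, cr)
  k <- crossprod(mc, rc)
  sv <- svd(k)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- cr - as.numeric(cm %*% rot)
  list(
    R = rot, t = trans,
    transform = function(x) sweep(x %*% rot, 2, trans, `+`)
  )
}

#' Heavy-atom root-mean-square deviation after optimal superposition
#'
#' @param a,b Coordinate matrices with matched rows.
#' @param superpose Superpose `a` onto `b` first (default TRUE).
#' @return RMSD in the coordinate units (Angstrom throughout the package).
#' @export
rmsd <- function(a, b, superpose = TRUE) {
  if (superpose) a <- kabsch(a, b)$transform(a)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Align conformers to the first conformer and strip hydrogens
#'
#' Rigid-body aligns every conformer m > 1 onto conformer 1 using the
#' Kabsch superposition over heavy atoms, then (by default) removes
#' hydrogen atoms, preserving heavy-atom order. Alignment is idempotent.
#'
#' @param data A data frame with an `ensemble` list-column, or a single
#'   `conformer_ensemble`.
#' @param strip_h Remove hydrogens after alignment (default TRUE).
#' @return Input with aligned (and optionally hydrogen-free) ensembles.
#' @export
align_conformers <- function(data, strip_h = TRUE) {
  resolved <- as_ensemble_list(data)
  out <- lapply(resolved$ensembles, function(e) {
    heavy <- e$elements != "H"
    ref <- e$coords[[1]][heavy, , drop = FALSE]
    e$coords <- lapply(seq_along(e$coords), function(m) {
      x <- e$coords[[m]]
      if (m == 1L) return(x)
      fit <- kabsch(x[heavy, , drop = FALSE], ref)
      fit$transform(x)
    })
    e$aligned <- TRUE
    if (strip_h && any(!heavy)) {
      e$coords <- lapply(e$coords, function(x) x[heavy, , drop = FALSE])
      e$elements <- e$elements[heavy]
      e$stripped <- TRUE
    } else if (strip_h) {
      e$stripped <- TRUE
    }
    e
  })
  resolved$rebuild(out)
}

#' Full conformer-preparation pipeline
#'
#' Convenience composition of [standardize_molecules()],
#' [generate_conformers()], [optimize_conformers()] and
#' [align_conformers()] in that order (hydrogens are added before
#' embedding and removed after alignment).
#'
#' @inheritParams standardize_molecules
#' @inheritParams generate_conformers
#' @inheritParams optimize_conformers
#' @param standardize Standardize structures first (default TRUE; set to
#'   FALSE when `data` already carries `smiles_canonical`).
#' @return A tibble with standardization columns and an `ensemble`
#'   list-column of aligned, hydrogen-stripped, MMFF94-optimized ensembles.
#' @export
prepare_conformers <- function(data, n_conformers = 10, seed = 42,
                               max_iters = 200, standardize = TRUE,
                               canonical_tautomer = TRUE) {
  if (standardize && !("smiles_canonical" %in% names(data))) {
    data <- standardize_molecules(data,
                                  canonical_tautomer = canonical_tautomer)
  }
  data |>
    generate_conformers(n_conformers = n_conformers, seed = seed) |>
    optimize_conformers(max_iters = max_iters) |>
    align_conformers()
}

# ---- SDF I/O ---------------------------------------------------------------

#' Write conformer ensembles to a multi-record SDF file
#'
#' One V2000 record per conformer; records of the same molecule share the
#' molecule id as title and carry a `conformer_index` data field (1-based),
#' plus `value_logM` when a label is available.
#'
#' @param data A data frame with an `ensemble` list-column (optionally a
#'   `value_logM` column), or a single `conformer_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(data, path) {
  resolved <- as_ensemble_list(data)
  labels <- if (is.data.frame(data) && "value_logM" %in% names(data)) {
    data$value_logM
  } else {
    vapply(resolved$ensembles,
           function(e) (e$label %null% NA_real_), numeric(1))
  }
  req <- list(
    path = path,
    molecules = lapply(seq_along(resolved$ensembles), function(i) {
      e <- resolved$ensembles[[i]]
      list(
        id = e$id, smiles = e$smiles, with_h = !e$stripped,
        label = if (is.finite(labels[i])) labels[i] else NULL,
        coords = lapply(e$coords, function(m) {
          lapply(seq_len(nrow(m)), function(r) as.numeric(m[r, ]))
        })
      )
    })
  )
  res <- pychem_call("sdf_write", req)
  parts <- pychem_partition(res$results)
  if (length(parts$failed)) {
    abort(paste0("SDF writing failed:\n",
                 paste(pychem_failure_messages(parts$failed),
                       collapse = "\n")),
          class = "equivs_format_error")
  }
  invisible(path)
}

#' Read conformer ensembles from a multi-record SDF file
#'
#' Records sharing a title are collected into one ensemble; atom and bond
#' perception is re-derived from the first record of each molecule.
#'
#' @param path SDF file path.
#' @return A tibble with `molecule_id`, `smiles_canonical`, an `ensemble`
#'   list-column and `value_logM` (NA when absent from the file).
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "equivs_format_error")
  }
  res <- pychem_call("sdf_read", list(path = path))
  if (!is.null(res$error) || length(res$results) == 0L) {
    abort(sprintf("malformed or empty SDF file: %s", path),
          class = "equivs_format_error")
  }
  ens <- lapply(res$results, function(rec) {
    e <- new_conformer_ensemble(
      id = rec$id, smiles = rec$smiles_canonical,
      elements = as.character(unlist(rec$elements)),
      coords = coords_from_record(rec$coords),
      energies = rep(NA_real_, length(rec$coords)),
      perception = perception_from_record(rec),
      seed = NA_integer_,
      label = rec$label %null% NULL
    )
    e$stripped <- !any(e$elements == "H")
    e
  })
  tibble(
    molecule_id = vapply(ens, function(e) e$id, character(1)),
    smiles_canonical = vapply(ens, function(e) e$smiles, character(1)),
    ensemble = ens,
    value_logM = vapply(ens, function(e) e$label %null% NA_real_,
                        numeric(1))
  )
}
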