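# Molecular graph construction: adjacency, 74-dim atom features, 12-dim
# bond features, and concatenated per-conformer coordinate features (3M
# columns, i.e. 30 for the default 10 conformers).

# 43-symbol element vocabulary; out-of-vocabulary elements get an all-zero
# element block (with a warning).
ELEMENT_VOCAB <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb"
)
HYBRIDIZATION_LEVELS <- c("SP", "SP2", "SP3", "SP3D", "SP3D2")
BOND_TYPE_LEVELS <- c("SINGLE", "DOUBLE", "TRIPLE", "AROMATIC")
BOND_STEREO_LEVELS <- c("STEREONONE", "STEREOANY", "STEREOZ", "STEREOE",
                        "STEREOCIS", "STEREOTRANS")

#' Atom feature matrix (74 columns)
#'
#' Encodes each heavy atom as the concatenation of: element one-hot (43
#' symbols), degree one-hot (0-10), implicit-hydrogen one-hot (0-6), formal
#' charge (one numeric slot), radical-electron count (one numeric slot),
#' hybridization one-hot (SP, SP2, SP3, SP3D, SP3D2), aromaticity flag, and
#' total-hydrogen one-hot (0-4); 43+11+7+1+1+5+1+5 = 74 columns.
#'
#' @param atoms Atom perception tibble (columns `symbol`, `degree`,
#'   `implicit_h`, `formal_charge`, `radical_electrons`, `hybridization`,
#'   `aromatic`, `total_h`), e.g. `ensemble$perception$atoms`.
#' @return Numeric n x 74 matrix.
#' @export
atom_feature_matrix <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  oov <- setdiff(unique(atoms$symbol), ELEMENT_VOCAB)
  if (length(oov)) {
    warn(sprintf("element(s) outside the 43-symbol vocabulary (%s): %s",
                 "all-zero element block used",
                 paste(oov, collapse = ", ")))
  }
  m <- cbind(
    one_hot(atoms$symbol, ELEMENT_VOCAB),
    one_hot(atoms$degree, 0:10),
    one_hot(atoms$implicit_h, 0:6),
    as.numeric(atoms$formal_charge),
    as.numeric(atoms$radical_electrons),
    one_hot(atoms$hybridization, HYBRIDIZATION_LEVELS),
    as.numeric(atoms$aromatic),
    one_hot(atoms$total_h, 0:4)
  )
  stopifnot(ncol(m) == 74L)
  dimnames(m) <- NULL
  m
}

#' Bond feature matrix (12 columns)
#'
#' Encodes each bond as bond-type one-hot (single, double, triple,
#' aromatic), conjugation flag, ring-membership flag, and stereo one-hot
#' (none, any, Z, E, cis, trans); 4+1+1+6 = 12 columns.
#'
#' @param bonds Bond perception tibble (columns `bond_type`, `conjugated`,
#'   `in_ring`, `stereo`), e.g. `ensemble$perception$bonds`.
#' @return Numeric b x 12 matrix (zero rows for a bond-free molecule).
#' @export
bond_feature_matrix <- function(bonds) {
  stopifnot(is.data.frame(bonds))
  m <- cbind(
    one_hot(bonds$bond_type, BOND_TYPE_LEVELS),
    as.numeric(bonds$conjugated),
    as.numeric(bonds$in_ring),
    one_hot(bonds$stereo, BOND_STEREO_LEVELS)
  )
  if (nrow(bonds) == 0L) m <- matrix(0, 0, 12)
  stopifnot(ncol(m) == 12L)
  dimnames(m) <- NULL
  m
}

#' Binary adjacency matrix of the heavy-atom graph
#'
#' @param x A `conformer_ensemble`, or a bond tibble with `begin`/`end`
#'   columns (then `n` is required).
#' @param n Number of atoms (only when `x` is a bond table).
#' @return Symmetric n x n 0/1 matrix with zero diagonal.
#' @export
build_adjacency <- function(x, n = NULL) {
  if (inherits(x, "conformer_ensemble")) {
    bonds <- x$perception$bonds
    n <- x$perception$n_heavy
  } else {
    bonds <- x
    if (is.null(n)) abort("`n` is required when passing a bond table.")
  }
  a <- matrix(0L, n, n)
  if (nrow(bonds)) {
    a[cbind(bonds$begin, bonds$end)] <- 1L
    a[cbind(bonds$end, bonds$begin)] <- 1L
  }
  a
}

#' Assemble the graph representation of a conformer ensemble
#'
#' Produces the model input: adjacency `A`, node features `HV` (n x 74),
#' per-directed-edge bond features (2b x 12; both orientations carry the
#' bond's features), and the coordinate feature matrix `HC` (n x 3M) formed
#' by concatenating the M aligned heavy-atom conformer coordinate blocks
#' column-wise, so columns 3(m-1)+1..3m recover conformer m.
#'
#' @param ens An aligned, hydrogen-stripped `conformer_ensemble`.
#' @param label Optional bioactivity label in -logM.
#' @return A `molecular_graph` object.
#' @export
assemble_graph <- function(ens, label = NULL) {
  stopifnot(inherits(ens, "conformer_ensemble"))
  if (!ens$stripped) {
    abort("ensemble must be hydrogen-stripped before graph assembly (see align_conformers()).")
  }
  n <- ens$perception$n_heavy
  bad <- vapply(ens$coords, function(x) nrow(x) != n, logical(1))
  if (any(bad)) {
    abort("atom count mismatch between topology and conformer coordinates.",
          class = "equivs_consistency_error")
  }
  bonds <- ens$perception$bonds
  hv <- atom_feature_matrix(ens$perception$atoms)
  he_bond <- bond_feature_matrix(bonds)
  # directed edge list: both orientations, same bond features
  if (nrow(bonds)) {
    edge_index <- rbind(cbind(bonds$begin, bonds$end),
                        cbind(bonds$end, bonds$begin))
    edge_features <- rbind(he_bond, he_bond)
  } else {
    edge_index <- matrix(integer(), 0, 2)
    edge_features <- matrix(0, 0, 12)
  }
  hc <- do.call(cbind, ens$coords)
  structure(
    list(
      id = ens$id, smiles = ens$smiles,
      A = build_adjacency(bonds, n),
      node_features = hv,
      edge_index = edge_index,
      edge_features = edge_features,
      coords = ens$coords,
      HC = hc,
      label = label %null% ens$label,
      n = n, M = length(ens$coords)
    ),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf(
    "<molecular_graph> %s: %d atoms, %d directed edges, %d conformers (HC: %d x %d)%s\n",
    x$id, x$n, nrow(x$edge_index), x$M, nrow(x$HC), ncol(x$HC),
    if (!is.null(x$label)) sprintf(", label %.3g -logM", x$label) else ""
  ))
  invisible(x)
}

#' Extract one conformer's coordinates from the concatenated HC matrix
#'
#' @param graph A `molecular_graph`.
#' @param m Conformer index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
conformer_coords <- function(graph, m) {
  stopifnot(inherits(graph, "molecular_graph"), m >= 1, m <= graph$M)
  graph$HC[, (3 * (m - 1) + 1):(3 * m), drop = FALSE]
}

#' Build molecular graphs for a prepared table
#'
#' @param data A data frame with an `ensemble` list-column (from
#'   [prepare_conformers()] or [read_sdf()]).
#' @param label Column with bioactivity labels in -logM (tidy-eval;
#'   default `value_logM`; skipped when absent).
#' @return `data` with a `graph` list-column of `molecular_graph` objects.
#' @export
build_graphs <- function(data, label = value_logM) {
  stopifnot(is.data.frame(data))
  label_col <- rlang::enquo(label)
  labels <- if (rlang::as_name(label_col) %in% names(data)) {
    dplyr::pull(data, !!label_col)
  } else {
    rep(list(NULL), nrow(data))
  }
  data$graph <- purrr::map2(data$ensemble, seq_len(nrow(data)),
                            function(e, i) {
    lab <- if (is.list(labels)) labels[[i]] else labels[[i]]
    assemble_graph(e, label = lab)
  })
  as_tibble(data)
}
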