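# Multi-conformer structure geometry: PDB parsing, Kabsch superposition RMSD,
# Shrake-Rupley solvent-accessible surface area, exposure classes and dASA.

# van der Waals radii (Angstrom) for the heavy elements found in protein
# chains; anything else falls back to carbon.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Van der Waals radius lookup
#'
#' Returns the van der Waals radius (Angstrom) used for solvent-accessibility
#' calculations. Unknown elements fall back to the carbon radius.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- .vdw_radii[["C"]]
  unname(r)
}

.infer_element <- function(element_field, atom_name) {
  el <- toupper(trimws(element_field))
  bad <- el == "" | is.na(el)
  if (any(bad)) {
    # strip leading digits from the atom name, take the first letter
    nm <- gsub("^[0-9']+", "", trimws(atom_name[bad]))
    el[bad] <- toupper(substr(nm, 1L, 1L))
  }
  el
}

.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

# Parse ATOM records of one model's text into an atom data frame.
# `lines` carries the original file line numbers in `line_no`.
.parse_atom_lines <- function(lines, line_no, chain, path) {
  rec <- substr(lines, 1L, 6L)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  line_no <- line_no[keep]
  if (length(lines) == 0L) {
    stop("no ATOM records found in '", path, "'", call. = FALSE)
  }
  chains <- substr(lines, 22L, 22L)
  if (is.null(chain)) {
    uniq <- unique(chains[substr(lines, 1L, 4L) == "ATOM"])
    if (length(uniq) == 0L) uniq <- unique(chains)
    if (length(uniq) != 1L) {
      stop("file '", path, "' has chains {", paste(uniq, collapse = ", "),
           "}; pick one with `chain`", call. = FALSE)
    }
    chain <- uniq
  }
  sel <- chains == chain
  if (!any(sel)) {
    stop("chain '", chain, "' not found in '", path, "'; available chains: ",
         paste(sort(unique(chains)), collapse = ", "), call. = FALSE)
  }
  lines <- lines[sel]
  line_no <- line_no[sel]
  is_het <- substr(lines, 1L, 6L) == "HETATM"
  resname <- trimws(substr(lines, 18L, 20L))
  # heteroatoms (ligands, ions) and waters are excluded from the ASA atom set
  drop <- is_het | resname %in% .water_resnames
  lines <- lines[!drop]
  line_no <- line_no[!drop]
  if (length(lines) == 0L) {
    stop("chain '", chain, "' of '", path, "' has no polymer ATOM records",
         call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(substr(lines, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(lines, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(lines, 47L, 54L)))
  resseq <- suppressWarnings(as.integer(substr(lines, 23L, 26L)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resseq))
  if (length(bad) > 0L) {
    stop("malformed ATOM record at line ", line_no[bad[1L]], " of '", path,
         "'", call. = FALSE)
  }
  occ <- suppressWarnings(as.numeric(substr(lines, 55L, 60L)))
  occ[is.na(occ)] <- 1.0
  data.frame(
    atom_name = trimws(substr(lines, 13L, 16L)),
    altloc = substr(lines, 17L, 17L),
    residue_index = resseq,
    x = x, y = y, z = z,
    occupancy = occ,
    element = .infer_element(substr(lines, 77L, 78L), substr(lines, 13L, 16L)),
    line_no = line_no,
    stringsAsFactors = FALSE
  )
}

# Highest-occupancy alternate location wins; ties broken by the first altloc
# identifier in collation order.
.resolve_altlocs <- function(atoms) {
  key <- paste(atoms$residue_index, atoms$atom_name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

.finish_conformer <- function(atoms, conformer_id) {
  atoms <- .resolve_altlocs(atoms)
  # hydrogens are excluded (typical for X-ray structures and for ASA)
  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  atoms <- atoms[order(atoms$residue_index, atoms$line_no), , drop = FALSE]
  resolved <- sort(unique(atoms$residue_index[atoms$atom_name == "CA"]))
  if (length(resolved) == 0L) {
    stop("conformer '", conformer_id, "' has no C-alpha atoms", call. = FALSE)
  }
  atoms$vdw_radius <- vdw_radius(atoms$element)
  atoms$line_no <- NULL
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  structure(
    list(conformer_id = conformer_id, atoms = atoms,
         resolved_positions = resolved, bound = NA),
    class = "conformer"
  )
}

#' Parse one conformer from a PDB file
#'
#' Reads the ATOM records of one chain of one model. Heteroatoms and waters
#' are excluded (so is every hydrogen), alternate locations are resolved to
#' the highest-occupancy variant, and the ligand-bound flag is left unset.
#'
#' @param path Path to a PDB-format text file.
#' @param chain Chain identifier. May be omitted for single-chain files.
#' @param model Model number to read from multi-model files (default first).
#' @param conformer_id Identifier for the conformer; defaults to the file
#'   base name (plus the model number for multi-model files).
#' @return A `conformer` object: a list with `conformer_id`, an `atoms` data
#'   frame (atom_name, residue_index, x, y, z, occupancy, element,
#'   vdw_radius), the set of `resolved_positions` (residue indices with a
#'   C-alpha) and a `bound` flag (NA until supplied externally).
#' @seealso [parse_pdb_models()] for all models of a multi-model file.
#' @export
parse_pdb_conformer <- function(path, chain = NULL, model = 1L,
                                conformer_id = NULL) {
  models <- .split_models(path)
  if (model > length(models)) {
    stop("model ", model, " requested but '", path, "' has ",
         length(models), " model(s)", call. = FALSE)
  }
  blk <- models[[model]]
  if (is.null(conformer_id)) {
    conformer_id <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
    if (length(models) > 1L) conformer_id <- paste0(conformer_id, "_m", model)
  }
  atoms <- .parse_atom_lines(blk$lines, blk$line_no, chain, path)
  .finish_conformer(atoms, conformer_id)
}

#' Parse every model of a PDB file as a separate conformer
#'
#' Multi-model files (MODEL/ENDMDL) are treated as one conformer per model.
#'
#' @inheritParams parse_pdb_conformer
#' @param id_prefix Prefix for conformer ids; defaults to the file base name.
#' @return List of `conformer` objects.
#' @export
parse_pdb_models <- function(path, chain = NULL, id_prefix = NULL) {
  models <- .split_models(path)
  if (is.null(id_prefix)) {
    id_prefix <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  }
  lapply(seq_along(models), function(i) {
    id <- if (length(models) > 1L) paste0(id_prefix, "_m", i) else id_prefix
    atoms <- .parse_atom_lines(models[[i]]$lines, models[[i]]$line_no,
                               chain, path)
    .finish_conformer(atoms, id)
  })
}

.split_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  line_no <- seq_along(lines)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    return(list(list(lines = lines, line_no = line_no)))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i) {
    idx <- (starts[i] + 1L):(ends[i] - 1L)
    list(lines = lines[idx], line_no = line_no[idx])
  })
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> ", x$conformer_id, ": ", nrow(x$atoms), " atoms, ",
      length(x$resolved_positions), " resolved positions, bound = ",
      ifelse(is.na(x$bound), "unset", x$bound), "\n", sep = "")
  invisible(x)
}

#' Assemble a conformer ensemble
#'
#' Bundles the conformers of one protein. All conformers must share the same
#' residue numbering (identical sequence); conformer ids must be unique.
#'
#' @param protein_id Protein accession string.
#' @param conformers List of `conformer` objects, length >= 1.
#' @param sequence_length Optional protein length; defaults to the largest
#'   resolved residue index.
#' @return A `conformer_ensemble` object.
#' @export
conformer_ensemble <- function(protein_id, conformers, sequence_length = NULL) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            is.list(conformers), length(conformers) >= 1L)
  ids <- vapply(conformers, function(cf) cf$conformer_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate conformer ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(sequence_length)) {
    sequence_length <- max(unlist(lapply(conformers, `[[`,
                                         "resolved_positions")))
  }
  structure(list(protein_id = protein_id, conformers = conformers,
                 sequence_length = as.integer(sequence_length)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", x$protein_id, ": ",
      length(x$conformers), " conformer(s), sequence length ",
      x$sequence_length, "\n", sep = "")
  invisible(x)
}

# C-alpha coordinates keyed by residue index.
.ca_coords <- function(conformer) {
  ca <- conformer$atoms[conformer$atoms$atom_name == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$residue_index
  m
}

#' Minimal RMSD after optimal rigid-body superposition (Kabsch)
#'
#' Computes the root-mean-square deviation between two matched point sets
#' after removing the optimal rotation and translation (Kabsch algorithm via
#' singular value decomposition, with the reflection guard). Symmetric in its
#' arguments and invariant under any rigid motion applied to either set.
#'
#' @param coords_a,coords_b Numeric N x 3 matrices (Angstrom), N >= 3, with
#'   row i of `coords_a` matched to row i of `coords_b`.
#' @return Nonnegative RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (ncol(a) != 3L || ncol(b) != 3L) {
    stop("coordinate matrices must have 3 columns", call. = FALSE)
  }
  if (nrow(a) != nrow(b)) {
    stop("point counts differ: ", nrow(a), " vs ", nrow(b), call. = FALSE)
  }
  if (nrow(a) < 3L) stop("need at least 3 matched points", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- a %*% t(rot) - b
  sqrt(max(sum(diff * diff), 0) / nrow(a))
}

#' Pairwise and maximum C-alpha RMSD of an ensemble
#'
#' Each conformer pair is superposed on the intersection of its resolved
#' positions; RMSDmax is the maximum off-diagonal entry of the pairwise
#' matrix and summarizes the extent of conformational diversity.
#'
#' @param ensemble A `conformer_ensemble` with >= 2 conformers; every pair
#'   must share >= 3 commonly resolved C-alpha positions.
#' @return List with `rmsd_matrix` (symmetric, zero diagonal, conformer ids
#'   as dimnames) and `rmsd_max`.
#' @export
ensemble_rmsd <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  n <- length(ensemble$conformers)
  if (n < 2L) {
    stop("RMSDmax undefined for one conformer", call. = FALSE)
  }
  cas <- lapply(ensemble$conformers, .ca_coords)
  ids <- vapply(ensemble$conformers, `[[`, character(1), "conformer_id")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- intersect(rownames(cas[[i]]), rownames(cas[[j]]))
      if (length(shared) < 3L) {
        stop("conformers '", ids[i], "' and '", ids[j], "' share only ",
             length(shared), " resolved positions (need >= 3)", call. = FALSE)
      }
      m[i, j] <- m[j, i] <- kabsch_rmsd(cas[[i]][shared, , drop = FALSE],
                                        cas[[j]][shared, , drop = FALSE])
    }
  }
  list(rmsd_matrix = m, rmsd_max = max(m))
}

#' Deterministic unit-sphere point lattice (golden spiral)
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples each atom's solvent-expanded sphere (radius r + probe) with a
#' deterministic golden-spiral lattice; a sample point is accessible when it
#' lies outside every neighbouring atom's expanded sphere. Per-atom area is
#' (accessible points / total points) * 4 pi (r + probe)^2, summed over each
#' residue's atoms. Deterministic for a fixed point count.
#'
#' @param conformer A `conformer` object (hydrogens already excluded).
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_points Sample points per atom, >= 100 (default 960).
#' @return Named numeric vector: ASA in Angstrom^2 per residue index.
#' @export
shrake_rupley_asa <- function(conformer, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(conformer, "conformer"))
  if (probe_radius <= 0) stop("probe_radius must be positive", call. = FALSE)
  if (n_points < 100L) stop("n_points must be >= 100", call. = FALSE)
  atoms <- conformer$atoms
  if (any(!is.finite(atoms$vdw_radius)) || any(atoms$vdw_radius <= 0)) {
    stop("all atoms need a positive van der Waals radius", call. = FALSE)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rr <- atoms$vdw_radius + probe_radius
  n_atoms <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n_atoms)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n_atoms)) {
    nb <- which(d2[i, ] < (rr[i] + rr)^2)
    nb <- nb[nb != i]
    p <- pts * rr[i]
    p <- sweep(p, 2L, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dx <- p[, 1L] - xyz[j, 1L]
      dy <- p[, 2L] - xyz[j, 2L]
      dz <- p[, 3L] - xyz[j, 3L]
      acc <- acc & (dx * dx + dy * dy + dz * dz >= rr[j]^2)
      if (!any(acc)) break
    }
    area[i] <- sum(acc) / n_points * 4 * pi * rr[i]^2
  }
  asa <- tapply(area, atoms$residue_index, sum)
  out <- as.numeric(asa)
  names(out) <- names(asa)
  out[order(as.integer(names(out)))]
}

#' Buried/exposed classification of a residue from its ASA
#'
#' Residues with ASA below 20 Angstrom^2 are buried; the boundary value is
#' assigned to exposed.
#'
#' @param asa Numeric vector of nonnegative areas, Angstrom^2.
#' @param cutoff Classification cutoff (default 20).
#' @return Character vector of "buried"/"exposed".
#' @export
classify_exposure <- function(asa, cutoff = 20) {
  if (any(asa < 0, na.rm = TRUE)) {
    stop("ASA values must be nonnegative", call. = FALSE)
  }
  ifelse(asa < cutoff, "buried", "exposed")
}

#' Maximum ASA difference of a position across conformers
#'
#' @param ensemble_asa List of per-residue ASA vectors (one per conformer),
#'   as returned by [shrake_rupley_asa()].
#' @param position Residue index.
#' @return Max minus min ASA over the conformers in which the position is
#'   resolved, or `NA` (undefined, excluded from distributions) when it is
#'   resolved in fewer than two conformers.
#' @export
delta_asa_max <- function(ensemble_asa, position) {
  key <- as.character(position)
  vals <- unlist(lapply(ensemble_asa, function(a) a[key]), use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L) return(NA_real_)
  max(vals) - min(vals)
}

#' Per-position dASA table for an ensemble
#'
#' @inheritParams delta_asa_max
#' @param cutoff Exposure cutoff passed to [classify_exposure()].
#' @return Data frame with one row per residue position: number of conformers
#'   resolving it, `delta_asa_max` (NA when < 2), min/max ASA, and whether the
#'   buried/exposed call differs between conformers (`ambiguous_exposure`).
#' @export
delta_asa_table <- function(ensemble_asa, cutoff = 20) {
  positions <- sort(unique(as.integer(unlist(lapply(ensemble_asa, names)))))
  rows <- lapply(positions, function(p) {
    key <- as.character(p)
    vals <- unlist(lapply(ensemble_asa, function(a) a[key]), use.names = FALSE)
    vals <- vals[!is.na(vals)]
    data.frame(
      position = p,
      n_conformers = length(vals),
      delta_asa_max = if (length(vals) >= 2L) max(vals) - min(vals)
                      else NA_real_,
      asa_min = min(vals),
      asa_max = max(vals),
      ambiguous_exposure = length(unique(classify_exposure(vals,
                                                           cutoff))) > 1L
    )
  })
  do.call(rbind, rows)
}

#' Full geometry descriptor set for an ensemble
#'
#' Convenience wrapper computing the pairwise RMSD matrix with RMSDmax (when
#' >= 2 conformers), per-conformer per-residue ASA, and the per-position dASA
#' table.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param probe_radius,n_points Passed to [shrake_rupley_asa()].
#' @return An `ensemble_geometry` list: `protein_id`, `rmsd_matrix`,
#'   `rmsd_max` (NA for a single conformer), `asa` (named list of per-residue
#'   vectors) and `delta_asa` (data frame).
#' @export
ensemble_geometry <- function(ensemble, probe_radius = 1.4, n_points = 960L) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  asa <- lapply(ensemble$conformers, shrake_rupley_asa,
                probe_radius = probe_radius, n_points = n_points)
  names(asa) <- vapply(ensemble$conformers, `[[`, character(1),
                       "conformer_id")
  if (length(ensemble$conformers) >= 2L) {
    r <- ensemble_rmsd(ensemble)
    rmsd_matrix <- r$rmsd_matrix
    rmsd_max <- r$rmsd_max
  } else {
    rmsd_matrix <- NULL
    rmsd_max <- NA_real_
  }
  structure(
    list(protein_id = ensemble$protein_id, rmsd_matrix = rmsd_matrix,
         rmsd_max = rmsd_max, asa = asa, delta_asa = delta_asa_table(asa)),
    class = "ensemble_geometry"
  )
}
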