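# Synthetic dataset generator: conformer ensembles, SAS phenotype labels,
# per-(SAS, conformer) ddG matrices with conformer-level heterogeneity, bound
# flags, and toy multi-conformer structures with known RMSD.
#
# The stated world it emulates: ~119 proteins, 2-73 conformers per protein
# with mean ~8.6, ~803 substitutions of which ~60% are disease related, and
# class-conditional ddG such that the dataset means of the per-substitution
# minimum/maximum approximate 1.47/4.63 kcal/mol (disease) and 0.38/1.86
# kcal/mol (neutral).

# Conformer-level deviation scale: sd(cell | base) =
# conformer_sigma * (.conf_sd_base + .conf_sd_slope * |base|).
# Heteroscedasticity mirrors empirical stability estimates, whose conformer
# scatter grows with effect magnitude; the constants are frozen by the
# calibration against the class-conditional min/max targets.
.conf_sd_base <- 0.17
.conf_sd_slope <- 0.285

#' Generator configuration
#'
#' Defaults are calibrated to the stated world above; they are recorded in
#' the shipped config file `system.file("extdata", "generator-defaults.cfg",
#' package = "confdiv")`.
#'
#' @param n_proteins Number of proteins (default 119).
#' @param conformer_count_model Shifted negative binomial for conformers per
#'   protein, truncated to \[min, max\]: list(mu, size, min, max). The count
#'   is `min + NB(mu, size)` resampled into range; defaults target mean 8.6
#'   on \[2, 73\].
#' @param sas_per_protein_model Substitutions per protein:
#'   list(mu, size, min) for `min + NB(mu, size)`; defaults target a dataset
#'   total of ~803 at 119 proteins.
#' @param disease_fraction Probability a substitution is disease related
#'   (default 0.60).
#' @param disease_effect_model Substitution-level base ddG for the disease
#'   class: a right-skewed shifted gamma `shift + Gamma(shape, scale)` mixed
#'   with a minority stabilizing component `-(stab_shift +
#'   Gamma(stab_shape, stab_scale))` of weight `stab_weight`, so the
#'   two-sided prediction rule is exercised.
#' @param neutral_effect_model Same family for the neutral class, with a
#'   smaller and milder stabilizing minority.
#' @param difficulty_model Protein-level difficulty coupling: a substitution
#'   in a protein with `k` conformers draws its base effect from the
#'   opposite class's model with probability
#'   `max_flip * (k / 73)^exponent`. This emulates a documented feature of
#'   real ensembles — conformer-rich proteins show markedly poorer
#'   phenotype-stability correlation — and is what makes the cell-weighted
#'   global strategy the weakest, as observed.
#' @param conformer_sigma Scale multiplier of the conformer-level deviation
#'   (kcal/mol); 0 removes all conformer heterogeneity.
#' @param missing_rate Fraction of ddG cells masked as missing (each
#'   substitution always keeps at least one value). Default 0: the emulated
#'   pipeline computed every cell.
#' @param bound_prob Per-conformer probability of the ligand-bound flag.
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_proteins = 119L,
    conformer_count_model = list(mu = 6.6, size = 1.1, min = 2L, max = 73L),
    sas_per_protein_model = list(mu = 5.75, size = 1.5, min = 1L),
    disease_fraction = 0.60,
    disease_effect_model = list(shift = 0.93, shape = 1.2, scale = 2.64,
                                stab_weight = 0.12, stab_shift = 1.2,
                                stab_shape = 1.6, stab_scale = 1.1),
    neutral_effect_model = list(shift = -0.3, shape = 1.0, scale = 1.39,
                                stab_weight = 0.07, stab_shift = 0.3,
                                stab_shape = 1.2, stab_scale = 1.0),
    difficulty_model = list(max_flip = 0.5, exponent = 0.8),
    conformer_sigma = 1.0,
    missing_rate = 0.0,
    bound_prob = 0.5,
    seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              conformer_count_model = conformer_count_model,
              sas_per_protein_model = sas_per_protein_model,
              disease_fraction = disease_fraction,
              disease_effect_model = disease_effect_model,
              neutral_effect_model = neutral_effect_model,
              difficulty_model = difficulty_model,
              conformer_sigma = conformer_sigma,
              missing_rate = missing_rate,
              bound_prob = bound_prob,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1L) stop("n_proteins must be >= 1", call. = FALSE)
  if (cfg$disease_fraction < 0 || cfg$disease_fraction > 1) {
    stop("disease_fraction must be in [0, 1]", call. = FALSE)
  }
  if (cfg$conformer_sigma < 0) {
    stop("conformer_sigma must be >= 0", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$difficulty_model$max_flip < 0 ||
      cfg$difficulty_model$max_flip > 1) {
    stop("difficulty max_flip must be in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# truncated shifted negative binomial; resamples out-of-range draws
.rtrunc_nb <- function(n, mu, size, min, max = Inf) {
  out <- min + stats::rnbinom(n, mu = mu, size = size)
  while (any(bad <- out > max)) {
    out[bad] <- min + stats::rnbinom(sum(bad), mu = mu, size = size)
  }
  out
}

.draw_base_effect <- function(n, model) {
  b <- model$shift + stats::rgamma(n, shape = model$shape,
                                   scale = model$scale)
  w <- model$stab_weight %||% 0
  if (w > 0) {
    stab <- stats::runif(n) < w
    b[stab] <- -(model$stab_shift +
                   stats::rgamma(sum(stab), shape = model$stab_shape,
                                 scale = model$stab_scale))
  }
  b
}

#' Generate a synthetic ensemble/variant/ddG dataset
#'
#' Hierarchical model: each substitution draws a base effect `b` from its
#' phenotype-class model; each of its protein's conformers adds an
#' independent deviation `e ~ Normal(0, conformer_sigma * (0.2 +
#' 0.35 |b|))`; the cell value is `b + e`. Labels are Bernoulli with
#' `disease_fraction`, bound flags Bernoulli per conformer. Output is
#' byte-identical for a fixed seed.
#'
#' @param config A `generator_config`.
#' @return A `synthetic_dataset` list: `proteins` (protein_id, n_conformers,
#'   sequence_length), `conformers` (protein_id, conformer_id, bound),
#'   `sas` (a `sas_table`), `ddg` (a `ddg_matrix`) and the `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  np <- config$n_proteins
  ccm <- config$conformer_count_model
  spm <- config$sas_per_protein_model
  protein_id <- sprintf("SP%04d", seq_len(np))
  n_conf <- .rtrunc_nb(np, ccm$mu, ccm$size, ccm$min, ccm$max)
  seq_len_prot <- sample(120:500, np, replace = TRUE)
  n_sas <- pmin(.rtrunc_nb(np, spm$mu, spm$size, spm$min), seq_len_prot)

  conformers <- data.frame(
    protein_id = rep(protein_id, n_conf),
    conformer_id = unlist(lapply(seq_len(np), function(i) {
      sprintf("%s_c%02d", protein_id[i], seq_len(n_conf[i]))
    })),
    stringsAsFactors = FALSE
  )
  conformers$bound <- stats::runif(nrow(conformers)) < config$bound_prob

  sas_list <- lapply(seq_len(np), function(i) {
    pos <- sort(sample(seq_len(seq_len_prot[i]), n_sas[i]))
    aa <- t(vapply(seq_len(n_sas[i]),
                   function(j) sample(.aa_alphabet, 2L), character(2)))
    data.frame(protein_id = protein_id[i], position = pos,
               wt_aa = aa[, 1L], mut_aa = aa[, 2L],
               stringsAsFactors = FALSE)
  })
  sas <- do.call(rbind, sas_list)
  sas$label <- ifelse(stats::runif(nrow(sas)) < config$disease_fraction,
                      "disease", "neutral")
  sas <- .validate_sas(sas, source = "generated SAS table")
  class(sas) <- c("sas_table", "data.frame")

  k_per_sas <- n_conf[match(sas$protein_id, protein_id)]
  # protein-difficulty coupling: conformer-rich proteins discriminate worse
  dm <- config$difficulty_model
  flip <- stats::runif(nrow(sas)) <
    dm$max_flip * (k_per_sas / 73)^dm$exponent
  eff_disease <- xor(sas$label == "disease", flip)
  b <- numeric(nrow(sas))
  b[eff_disease] <- .draw_base_effect(sum(eff_disease),
                                      config$disease_effect_model)
  b[!eff_disease] <- .draw_base_effect(sum(!eff_disease),
                                       config$neutral_effect_model)
  sd_per_sas <- config$conformer_sigma *
    (.conf_sd_base + .conf_sd_slope * abs(b))
  n_cells <- sum(k_per_sas)
  dev <- stats::rnorm(n_cells, 0, rep(sd_per_sas, k_per_sas))
  cells <- data.frame(
    sas_id = rep(sas$sas_id, k_per_sas),
    conformer_id = unlist(lapply(seq_len(nrow(sas)), function(i) {
      sprintf("%s_c%02d", sas$protein_id[i],
              seq_len(k_per_sas[i]))
    })),
    ddg = rep(b, k_per_sas) + dev,
    stringsAsFactors = FALSE
  )
  if (config$missing_rate > 0) {
    mask <- stats::runif(n_cells) < config$missing_rate
    # every substitution keeps its first cell
    first <- !duplicated(cells$sas_id)
    mask[first] <- FALSE
    cells$ddg[mask] <- NA_real_
  }
  structure(list(
    proteins = data.frame(protein_id = protein_id, n_conformers = n_conf,
                          sequence_length = seq_len_prot,
                          stringsAsFactors = FALSE),
    conformers = conformers,
    sas = sas,
    ddg = ddg_matrix(sas[, c("sas_id", "protein_id", "position", "wt_aa",
                             "mut_aa")],
                     cells, conformers[, c("protein_id", "conformer_id")]),
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$proteins), " proteins, ",
      nrow(x$conformers), " conformers, ", nrow(x$sas),
      " substitutions (", sum(x$sas$label == "disease"), " disease / ",
      sum(x$sas$label == "neutral"), " neutral), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to TSV files
#'
#' Emits the same dialects the readers consume: `sas.tsv` (for
#' [read_sas_table()]), `ddg.tsv` (for [read_ddg_table()]) and
#' `conformers.tsv` with the bound flags.
#'
#' @param dataset A `synthetic_dataset`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(sas = file.path(out_dir, "sas.tsv"),
             ddg = file.path(out_dir, "ddg.tsv"),
             conformers = file.path(out_dir, "conformers.tsv"))
  sas <- dataset$sas[, c("protein_id", "position", "wt_aa", "mut_aa",
                         "label")]
  utils::write.table(sas, paths[["sas"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_ddg_table(dataset$ddg, paths[["ddg"]])
  utils::write.table(dataset$conformers, paths[["conformers"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

.toy_backbone <- function(n_residues) {
  offsets <- rbind(N = c(-1.45, 0.95, 0), CA = c(0, 0, 0),
                   C = c(1.51, 0.88, 0), O = c(1.85, 2.05, 0))
  elements <- c(N = "N", CA = "C", C = "C", O = "O")
  rows <- lapply(seq_len(n_residues), function(i) {
    ca <- c(3.8 * (i - 1L), 0, 0)
    data.frame(atom_name = rownames(offsets),
               residue_index = i,
               x = ca[1L] + offsets[, 1L], y = ca[2L] + offsets[, 2L],
               z = ca[3L] + offsets[, 3L],
               occupancy = 1.0,
               element = unname(elements),
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  atoms
}

#' Generate toy multi-conformer structures with known RMSD
#'
#' Builds a poly-alanine-like backbone (N, CA, C, O per residue on a
#' straight chain) and derives conformer `k` by displacing every atom of
#' residue `i` along z by `pattern[i] * (k - 1) * displacement`, where
#' `pattern` repeats (+1, -1, -1, +1). That block pattern has zero sum and
#' zero first moment along the chain, so the optimal superposition between
#' any two conformers is the identity and the pairwise C-alpha RMSD is
#' exactly `|k - l| * displacement` whenever `n_residues` is a multiple of
#' 4 (recorded in `expected_rmsd`). An optional random rigid motion per
#' conformer (rotation + translation) leaves all RMSDs unchanged.
#'
#' @param n_conformers Number of conformers (>= 1).
#' @param n_residues Number of residues (>= 3; use a multiple of 4 for the
#'   exact closed form).
#' @param displacement Per-step displacement amplitude in Angstrom (>= 0).
#' @param seed RNG seed for the rigid motions.
#' @param out_path Optional path; when given, the conformers are written as
#'   one multi-model PDB file.
#' @param rigid_motions Apply a random rigid motion to each conformer
#'   (default TRUE).
#' @return List: `conformers` (list of `conformer` objects),
#'   `expected_rmsd` (matrix, exact for `n_residues %% 4 == 0`),
#'   `displacement`, and `path` (or NULL).
#' @export
generate_toy_structures <- function(n_conformers, n_residues,
                                    displacement = 0, seed = 1L,
                                    out_path = NULL, rigid_motions = TRUE) {
  if (displacement < 0) stop("displacement must be >= 0", call. = FALSE)
  if (n_residues < 3L) stop("need at least 3 residues", call. = FALSE)
  if (n_conformers < 1L) stop("need at least 1 conformer", call. = FALSE)
  set.seed(seed)
  base <- .toy_backbone(n_residues)
  pattern <- rep_len(c(1, -1, -1, 1), n_residues)
  conformers <- lapply(seq_len(n_conformers), function(k) {
    atoms <- base
    atoms$z <- atoms$z + pattern[atoms$residue_index] *
      (k - 1L) * displacement
    if (rigid_motions) {
      rot <- .random_rotation()
      shift <- stats::runif(3L, -20, 20)
      xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
      atoms$x <- xyz[, 1L] + shift[1L]
      atoms$y <- xyz[, 2L] + shift[2L]
      atoms$z <- xyz[, 3L] + shift[3L]
    }
    atoms$vdw_radius <- vdw_radius(atoms$element)
    structure(list(conformer_id = sprintf("toy_c%02d", k), atoms = atoms,
                   resolved_positions = seq_len(n_residues), bound = NA),
              class = "conformer")
  })
  idx <- seq_len(n_conformers)
  expected <- abs(outer(idx, idx, `-`)) * displacement
  path <- NULL
  if (!is.null(out_path)) {
    write_pdb(conformers, out_path)
    path <- out_path
  }
  list(conformers = conformers, expected_rmsd = expected,
       displacement = displacement, path = path)
}

#' Write conformers as a (multi-model) PDB file
#'
#' @param conformers List of `conformer` objects (one MODEL each; a single
#'   conformer is written without MODEL records).
#' @param path Output file path.
#' @param chain Chain identifier (default "A").
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conformers, path, chain = "A") {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(conformers) > 1L
  for (k in seq_along(conformers)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    atoms <- conformers[[k]]$atoms
    lines <- sprintf(
      "ATOM  %5d %-4s ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(atoms)),
      ifelse(nchar(atoms$atom_name) < 4L,
             paste0(" ", atoms$atom_name), atoms$atom_name),
      chain, atoms$residue_index, atoms$x, atoms$y, atoms$z,
      atoms$occupancy, 0, atoms$element
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
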