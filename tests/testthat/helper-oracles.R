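# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written without calling the package
# functions it is used to check.

# ---- PDB fixture text -------------------------------------------------

pdb_atom_line <- function(serial, name, x, y, z, resseq = 1L, altloc = " ",
                          resname = "ALA", chain = "A", occ = 1.0,
                          element = NULL, het = FALSE) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1L, 1L)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          ifelse(nchar(name) < 4L, paste0(" ", name), name),
          altloc, resname, chain, resseq, x, y, z, occ, 0, element)
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# two-residue, nine-atom fixture (N CA C O + CB on residue 2)
two_residue_pdb <- function(chain = "A") {
  c(pdb_atom_line(1, "N", 0.0, 1.0, 0.0, 1, chain = chain),
    pdb_atom_line(2, "CA", 1.4, 0.0, 0.0, 1, chain = chain),
    pdb_atom_line(3, "C", 2.9, 0.4, 0.0, 1, chain = chain),
    pdb_atom_line(4, "O", 3.3, 1.5, 0.0, 1, chain = chain),
    pdb_atom_line(5, "N", 3.8, -0.6, 0.0, 2, chain = chain),
    pdb_atom_line(6, "CA", 5.2, -0.4, 0.0, 2, chain = chain),
    pdb_atom_line(7, "C", 6.0, -1.7, 0.0, 2, chain = chain),
    pdb_atom_line(8, "O", 5.5, -2.8, 0.0, 2, chain = chain),
    pdb_atom_line(9, "CB", 5.9, 0.5, 1.2, 2, chain = chain))
}

# single free-standing atom as a conformer object
atom_conformer <- function(xyz = c(0, 0, 0), element = "C", n = 1L,
                           spacing = 10) {
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(atom_name = "CA", residue_index = i,
               x = xyz[1] + (i - 1L) * spacing, y = xyz[2], z = xyz[3],
               occupancy = 1, element = element,
               vdw_radius = confdiv::vdw_radius(element),
               stringsAsFactors = FALSE)
  }))
  structure(list(conformer_id = "fix", atoms = atoms,
                 resolved_positions = seq_len(n), bound = NA),
            class = "conformer")
}

# ---- Kabsch brute-force oracle ---------------------------------------
# Rotational grid search over ZYZ Euler angles plus Nelder-Mead refinement
# of the best starting points; translation removed by centering.

.euler_rot <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  matrix(c(ca * cb * cc - sa * sc, -ca * cb * sc - sa * cc, ca * sb,
           sa * cb * cc + ca * sc, -sa * cb * sc + ca * cc, sa * sb,
           -sb * cc, sb * sc, cb), 3, 3, byrow = TRUE)
}

brute_rmsd <- function(A, B, n_refine = 3L) {
  A <- scale(as.matrix(A), scale = FALSE)
  B <- scale(as.matrix(B), scale = FALSE)
  obj <- function(ang) {
    D <- A %*% t(.euler_rot(ang[1], ang[2], ang[3])) - B
    sqrt(mean(rowSums(D * D)))
  }
  aa <- seq(0, 2 * pi, length.out = 11)[-11]
  bb <- seq(0, pi, length.out = 7)
  grid <- as.matrix(expand.grid(aa, bb, aa))
  vals <- apply(grid, 1, obj)
  starts <- grid[order(vals)[seq_len(n_refine)], , drop = FALSE]
  best <- min(vals)
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 1000))
    best <- min(best, fit$value)
  }
  best
}

random_rotation_fixture <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# ---- analytic two-sphere exposed areas -------------------------------
# Exposed area of each solvent-expanded sphere (radius r_i + probe) when two
# atoms sit distance d apart: full sphere minus the spherical cap cut off by
# the other expanded sphere.

cap_exposed_areas <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(4 * pi * R1^2 - 2 * pi * R1 * max(h1, 0),
    4 * pi * R2^2 - 2 * pi * R2 * max(h2, 0))
}

# ---- MCC via Pearson correlation of binary vectors -------------------

mcc_pearson <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  if (length(truth) < 2) return(0)
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0) return(0)
  stats::cor(truth, pred)
}

# ---- KS statistic by direct ECDF scan --------------------------------

ks_D_oracle <- function(x, y) {
  v <- sort(c(x, y))
  max(vapply(v, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# ---- strategy metrics by exhaustive enumeration ----------------------
# rows: named list of per-SAS ddG vectors; labels: character vector aligned
# with rows; returns mcc/accuracy/specificity/sensitivity computed from
# first principles.

enum_counts <- function(truth_pos, pred_pos) {
  c(tp = sum(truth_pos & pred_pos), tn = sum(!truth_pos & !pred_pos),
    fp = sum(!truth_pos & pred_pos), fn = sum(truth_pos & !pred_pos))
}

enum_metrics_from_counts <- function(ct) {
  den <- sqrt(prod(c(ct["tp"] + ct["fp"], ct["tp"] + ct["fn"],
                     ct["tn"] + ct["fp"], ct["tn"] + ct["fn"])))
  list(
    mcc = if (den == 0) 0 else
      unname((ct["tp"] * ct["tn"] - ct["fp"] * ct["fn"]) / den),
    accuracy = unname((ct["tp"] + ct["tn"]) / sum(ct)),
    specificity = unname(ct["tn"] / (ct["tn"] + ct["fp"])),
    sensitivity = unname(ct["tp"] / (ct["tp"] + ct["fn"]))
  )
}

enum_strategy_metrics <- function(rows, labels, tau, strategy) {
  rows <- lapply(rows, function(v) v[!is.na(v)])
  truth_pos <- labels == "disease"
  if (strategy == "global") {
    vals <- unlist(rows, use.names = FALSE)
    truth_pos <- rep(truth_pos, lengths(rows))
  } else {
    f <- switch(strategy, min = min, max = max, mean = mean)
    vals <- vapply(rows, f, numeric(1))
  }
  enum_metrics_from_counts(enum_counts(truth_pos, abs(vals) > tau))
}

# ---- brute-force ambiguity classifier --------------------------------

ambiguous_oracle <- function(v, tau) {
  v <- v[!is.na(v)]
  cls <- ifelse(v > tau, "d", ifelse(v < -tau, "s", "n"))
  length(unique(cls)) >= 2
}

# ---- tiny ddg_matrix builder -----------------------------------------
# values: matrix (n_sas x n_conformers) possibly with NA; one protein.

toy_ddg_matrix <- function(values, labels = NULL, protein_id = "P1") {
  n_sas <- nrow(values)
  n_conf <- ncol(values)
  sas <- data.frame(
    protein_id = protein_id, position = seq_len(n_sas),
    wt_aa = "A", mut_aa = "V", stringsAsFactors = FALSE)
  sas$sas_id <- confdiv::sas_id(sas$protein_id, sas$position, sas$wt_aa,
                                sas$mut_aa)
  conf <- data.frame(protein_id = protein_id,
                     conformer_id = sprintf("%s_c%02d", protein_id,
                                            seq_len(n_conf)),
                     stringsAsFactors = FALSE)
  cells <- data.frame(
    sas_id = rep(sas$sas_id, each = n_conf),
    conformer_id = rep(conf$conformer_id, n_sas),
    ddg = as.vector(t(values)), stringsAsFactors = FALSE)
  cells <- cells[!is.na(cells$ddg) | TRUE, ]  # keep NA cells explicitly
  m <- confdiv::ddg_matrix(sas[, c("sas_id", "protein_id", "position",
                                   "wt_aa", "mut_aa")], cells, conf)
  if (!is.null(labels)) {
    lab <- sas
    lab$label <- labels
    class(lab) <- c("sas_table", "data.frame")
    attr(m, "labels") <- lab
  }
  m
}

toy_labels <- function(m, labels) {
  lab <- m$sas
  lab$label <- labels
  class(lab) <- c("sas_table", "data.frame")
  lab
}
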