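# Per-substitution aggregation of conformer ddG values, stability classes,
# ensemble-ambiguity statistics and the binned dASA-vs-spread analysis.

#' Summarize the ddG values of one substitution across conformers
#'
#' @param ddg_row Numeric vector of per-conformer ddG values (kcal/mol);
#'   `NA` cells are dropped.
#' @return List with `ddg_min`, `ddg_max`, `ddg_mean`, `ddg_spread`
#'   (max - min), and `n_conformers_used`.
#' @export
summarize_sas <- function(ddg_row) {
  v <- ddg_row[!is.na(ddg_row)]
  if (length(v) == 0L) {
    stop("substitution has no ddG value in any conformer", call. = FALSE)
  }
  list(ddg_min = min(v), ddg_max = max(v), ddg_mean = mean(v),
       ddg_spread = max(v) - min(v), n_conformers_used = length(v))
}

#' Per-substitution summary table for a whole ddG matrix
#'
#' @param m A `ddg_matrix`.
#' @param labels Optional `sas_table`; when given, a `label` column is joined
#'   on `sas_id`.
#' @return Data frame with one row per substitution (index order preserved).
#' @export
summarize_sas_table <- function(m, labels = NULL) {
  rows <- ddg_rows(m)
  out <- do.call(rbind, lapply(rows, function(v) {
    as.data.frame(summarize_sas(v))
  }))
  out <- cbind(m$sas[, c("sas_id", "protein_id", "position", "wt_aa",
                         "mut_aa")], out)
  rownames(out) <- NULL
  if (!is.null(labels)) {
    out$label <- labels$label[match(out$sas_id, labels$sas_id)]
  }
  out
}

#' Three-way stability class of a ddG value
#'
#' Destabilizing when ddG > tau, stabilizing when ddG < -tau, neutral
#' otherwise; the boundary |ddG| = tau is assigned to neutral so the three
#' classes partition the line.
#'
#' @param ddg Numeric vector, kcal/mol (`NA` passes through).
#' @param tau Positive classification cutoff, kcal/mol (default 2; the
#'   common alternative is 1).
#' @return Character vector in {stabilizing, neutral, destabilizing}.
#' @export
classify_stability <- function(ddg, tau = 2) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (any(is.infinite(ddg))) stop("ddG must be finite", call. = FALSE)
  out <- rep(NA_character_, length(ddg))
  ok <- !is.na(ddg)
  out[ok] <- "neutral"
  out[ok & ddg > tau] <- "destabilizing"
  out[ok & ddg < -tau] <- "stabilizing"
  out
}

#' Is a substitution's stability call conformer-dependent?
#'
#' TRUE when the stability classes observed across conformers are not all
#' identical (e.g. neutral in one conformer, destabilizing in another).
#'
#' @inheritParams summarize_sas
#' @param tau Classification cutoff, kcal/mol.
#' @return Logical scalar.
#' @export
is_ambiguous <- function(ddg_row, tau = 2) {
  v <- ddg_row[!is.na(ddg_row)]
  if (length(v) == 0L) {
    stop("substitution has no ddG value in any conformer", call. = FALSE)
  }
  length(unique(classify_stability(v, tau))) >= 2L
}

#' Per-protein ambiguity statistics
#'
#' A protein is flagged when at least one of its substitutions changes
#' stability class between conformers. Reports the flagged fraction of
#' proteins, the label composition of the ambiguous substitutions, and (when
#' geometry is supplied) the mean RMSDmax split by flag.
#'
#' @param m A `ddg_matrix`.
#' @param labels Optional `sas_table` supplying phenotype labels.
#' @param tau Classification cutoff, kcal/mol.
#' @param geometry Optional data frame (`protein_id`, `rmsd_max`).
#' @return List: `per_protein` data frame, `fraction_ambiguous`,
#'   `ambiguous_sas_ids`, `composition` (per-label counts/fractions of the
#'   ambiguous substitutions, NULL without labels), `rmsd_split` (NULL
#'   without geometry).
#' @export
protein_ambiguity <- function(m, labels = NULL, tau = 2, geometry = NULL) {
  stopifnot(inherits(m, "ddg_matrix"))
  rows <- ddg_rows(m)
  amb <- vapply(rows, is_ambiguous, logical(1), tau = tau)
  prot <- m$sas$protein_id
  per_protein <- data.frame(
    protein_id = unique(prot),
    n_sas = as.integer(table(factor(prot, levels = unique(prot)))),
    n_ambiguous = as.integer(tapply(amb, factor(prot, levels = unique(prot)),
                                    sum)),
    stringsAsFactors = FALSE
  )
  per_protein$ambiguous <- per_protein$n_ambiguous > 0L
  composition <- NULL
  if (!is.null(labels)) {
    lab <- labels$label[match(m$sas$sas_id, labels$sas_id)]
    amb_lab <- lab[amb]
    tab <- table(factor(amb_lab, levels = c("disease", "neutral")))
    composition <- data.frame(label = names(tab), n = as.integer(tab),
                              fraction = if (sum(tab) > 0)
                                as.numeric(tab) / sum(tab) else
                                  rep(NA_real_, length(tab)),
                              stringsAsFactors = FALSE)
  }
  rmsd_split <- NULL
  if (!is.null(geometry)) {
    rm <- geometry$rmsd_max[match(per_protein$protein_id,
                                  geometry$protein_id)]
    rmsd_split <- c(
      ambiguous = mean(rm[per_protein$ambiguous], na.rm = TRUE),
      unambiguous = mean(rm[!per_protein$ambiguous], na.rm = TRUE)
    )
    per_protein$rmsd_max <- rm
  }
  list(per_protein = per_protein,
       fraction_ambiguous = mean(per_protein$ambiguous),
       ambiguous_sas_ids = m$sas$sas_id[amb],
       composition = composition,
       rmsd_split = rmsd_split)
}

#' Signed dASA for the conformer pair with the largest ddG difference
#'
#' For each substitution, the conformer pair attaining the maximal ddG
#' difference defines an orientation: dASA = ASA(position, high-ddG
#' conformer) - ASA(position, low-ddG conformer). Substitutions with fewer
#' than two usable conformers, or without ASA for both chosen conformers,
#' are dropped.
#'
#' @param m A `ddg_matrix`.
#' @param asa Data frame with `protein_id`, `conformer_id`, `position`,
#'   `asa` (Angstrom^2), e.g. a geometry report.
#' @return Data frame: `sas_id`, `delta_asa`, `ddg_spread`.
#' @export
signed_delta_asa <- function(m, asa) {
  stopifnot(inherits(m, "ddg_matrix"),
            all(c("protein_id", "conformer_id", "position", "asa")
                %in% names(asa)))
  akey <- paste(asa$conformer_id, asa$position, sep = "\r")
  rows <- ddg_rows(m, drop_missing = TRUE)
  out <- lapply(seq_along(rows), function(i) {
    v <- rows[[i]]
    if (length(v) < 2L) return(NULL)
    hi <- names(v)[which.max(v)]
    lo <- names(v)[which.min(v)]
    pos <- m$sas$position[i]
    a_hi <- asa$asa[match(paste(hi, pos, sep = "\r"), akey)]
    a_lo <- asa$asa[match(paste(lo, pos, sep = "\r"), akey)]
    if (is.na(a_hi) || is.na(a_lo)) return(NULL)
    data.frame(sas_id = m$sas$sas_id[i], delta_asa = a_hi - a_lo,
               ddg_spread = max(v) - min(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) {
    out <- data.frame(sas_id = character(0), delta_asa = numeric(0),
                      ddg_spread = numeric(0))
  }
  out
}

#' Binned dASA-vs-ddG-spread profile
#'
#' Bins the signed dASA axis into half-open intervals [k*w, (k+1)*w) of width
#' `bin_width` (lower edge inclusive) and reports the per-bin mean and
#' standard error of the ddG spread, with bin centers at k*w + w/2. Empty
#' bins are omitted.
#'
#' @param delta_asa Numeric vector of signed dASA values, Angstrom^2.
#' @param ddg_spread Numeric vector (same length) of ddG spreads, kcal/mol.
#' @param bin_width Bin width in Angstrom^2 (default 10).
#' @return Data frame: `center`, `n`, `mean`, `se` (0 for singleton bins),
#'   ordered by center.
#' @export
binned_dasa_ddg <- function(delta_asa, ddg_spread, bin_width = 10) {
  stopifnot(length(delta_asa) == length(ddg_spread), bin_width > 0)
  if (length(delta_asa) == 0L) {
    return(data.frame(center = numeric(0), n = integer(0),
                      mean = numeric(0), se = numeric(0)))
  }
  k <- floor(delta_asa / bin_width)
  f <- factor(k, levels = sort(unique(k)))
  n <- as.integer(table(f))
  mu <- as.numeric(tapply(ddg_spread, f, mean))
  se <- as.numeric(tapply(ddg_spread, f, function(v) {
    if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
  }))
  data.frame(center = sort(unique(k)) * bin_width + bin_width / 2,
             n = n, mean = mu, se = se)
}
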