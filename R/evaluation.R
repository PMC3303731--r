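# Disease-vs-neutral discrimination from ddG: contingency metrics (MCC,
# accuracy, specificity, sensitivity), conformer-selection strategies with a
# resampled random baseline, per-conformer metrics, perfect-conformer and
# bound-state statistics, and the two-sample Kolmogorov-Smirnov test.

.strategies <- c("global", "min", "max", "mean", "random")
.strategy_display <- c(global = "Global", min = "Minimum", max = "Maximum",
                       mean = "Average", random = "Random")

#' Contingency table for disease-vs-neutral prediction
#'
#' Positive class is `disease` (a perturbing prediction).
#'
#' @param tp,tn,fp,fn Nonnegative counts.
#' @return A `contingency_table` list.
#' @export
contingency_table <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(counts) < 1) stop("empty contingency table", call. = FALSE)
  structure(as.list(counts), class = "contingency_table")
}

#' Matthews correlation coefficient
#'
#' MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)); a zero
#' denominator (any empty margin) yields 0 by convention.
#'
#' @param table A `contingency_table`, or `tp` when the four counts are
#'   given separately.
#' @param tn,fp,fn Remaining counts when not passing a table.
#' @return Value in \[-1, 1\].
#' @export
mcc <- function(table, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(table, "contingency_table")) {
    tp <- table$tp; tn <- table$tn; fp <- table$fp; fn <- table$fn
  } else {
    tp <- table
  }
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  num <- tp * tn - fp * fn
  ifelse(den == 0, 0, num / den)
}

#' Metrics derived from a contingency table
#'
#' @param table A `contingency_table`.
#' @return An `eval_metrics` list: `mcc`, `accuracy`, `specificity`,
#'   `sensitivity` (the latter two are `NA` when their denominator is 0) and
#'   the `table` itself.
#' @export
eval_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  tp <- table$tp; tn <- table$tn; fp <- table$fp; fn <- table$fn
  total <- tp + tn + fp + fn
  structure(list(
    mcc = mcc(table),
    accuracy = (tp + tn) / total,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    table = table
  ), class = "eval_metrics")
}

.metrics_from_labels <- function(truth, pred) {
  t_pos <- truth == "disease"
  p_pos <- pred == "disease"
  eval_metrics(contingency_table(
    tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
    fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos)
  ))
}

#' Phenotype prediction from a ddG value
#'
#' Under the default two-sided rule a substitution is called `disease` when
#' |ddG| > tau — stabilizing and destabilizing changes both count as
#' perturbing. The `destabilizing` rule uses ddG > tau only.
#'
#' @param ddg Numeric vector, kcal/mol.
#' @param tau Positive cutoff, kcal/mol (default 2).
#' @param rule `"two_sided"` (default) or `"destabilizing"`.
#' @return Character vector in {disease, neutral}.
#' @export
predict_label <- function(ddg, tau = 2, rule = c("two_sided",
                                                 "destabilizing")) {
  rule <- match.arg(rule)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  score <- if (rule == "two_sided") abs(ddg) else ddg
  ifelse(is.na(ddg), NA_character_,
         ifelse(score > tau, "disease", "neutral"))
}

.match_labels <- function(m, labels) {
  lab <- labels$label[match(m$sas$sas_id, labels$sas_id)]
  if (anyNA(lab)) {
    stop("label table does not cover substitution(s): ",
         paste(utils::head(m$sas$sas_id[is.na(lab)], 3L), collapse = ", "),
         call. = FALSE)
  }
  lab
}

# Draw matrix of resampled ddG picks: one uniformly chosen non-missing
# conformer value per substitution per resample. Rows = substitutions.
.random_picks <- function(rows, n_resamples) {
  lens <- lengths(rows)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  flat <- unlist(rows, use.names = FALSE)
  n <- length(rows)
  idx <- floor(stats::runif(n * n_resamples) *
                 rep(lens, n_resamples)) + 1L
  matrix(flat[rep(offs, n_resamples) + idx], nrow = n)
}

.resample_metric_vectors <- function(rows, truth, tau, rule, n_resamples) {
  v <- .random_picks(rows, n_resamples)
  p_pos <- if (rule == "two_sided") abs(v) > tau else v > tau
  t_pos <- truth == "disease"
  tp <- colSums(p_pos & t_pos)
  fp <- colSums(p_pos & !t_pos)
  fn <- colSums(!p_pos & t_pos)
  tn <- colSums(!p_pos & !t_pos)
  list(
    mcc = mcc(tp, tn, fp, fn),
    accuracy = (tp + tn) / length(truth),
    specificity = tn / (tn + fp),
    sensitivity = tp / (tp + fn),
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

#' Evaluate one conformer-selection strategy
#'
#' Strategies: `global` treats every (substitution, conformer) cell as an
#' independent prediction paired with its substitution's label; `min`, `max`
#' and `mean` reduce each substitution's conformer values to one statistic
#' first; `random` draws, per resample, one uniformly chosen conformer value
#' per substitution, computes the metrics, and reports their means over
#' resamples.
#'
#' @param m A `ddg_matrix`.
#' @param labels A `sas_table` covering every substitution in `m`.
#' @param strategy One of `"global"`, `"min"`, `"max"`, `"mean"`,
#'   `"random"`.
#' @param tau Positive cutoff, kcal/mol.
#' @param rule Prediction rule, see [predict_label()].
#' @param seed RNG seed for the random strategy.
#' @param n_resamples Resample count for the random strategy (default 1000).
#' @return A `strategy_result` list: `strategy`, `metrics` (an
#'   `eval_metrics`; for random the metric fields are resample means and the
#'   table holds mean counts), `n` (predictions per replicate), and for
#'   random additionally `n_resamples`, `seed`, `resample_mcc`.
#' @export
evaluate_strategy <- function(m, labels, strategy = c("global", "min", "max",
                                                      "mean", "random"),
                              tau = 2, rule = c("two_sided",
                                                "destabilizing"),
                              seed = NULL, n_resamples = 1000L) {
  strategy <- match.arg(strategy)
  rule <- match.arg(rule)
  stopifnot(inherits(m, "ddg_matrix"))
  lab <- .match_labels(m, labels)
  rows <- ddg_rows(m, drop_missing = TRUE)
  if (strategy == "global") {
    truth <- rep(lab, lengths(rows))
    vals <- unlist(rows, use.names = FALSE)
    metrics <- .metrics_from_labels(truth, predict_label(vals, tau, rule))
    return(structure(list(strategy = strategy, metrics = metrics,
                          n = length(vals)), class = "strategy_result"))
  }
  if (strategy %in% c("min", "max", "mean")) {
    stat_fun <- switch(strategy, min = min, max = max, mean = mean)
    vals <- vapply(rows, stat_fun, numeric(1))
    metrics <- .metrics_from_labels(lab, predict_label(vals, tau, rule))
    return(structure(list(strategy = strategy, metrics = metrics,
                          n = length(vals)), class = "strategy_result"))
  }
  # random resampling baseline
  if (!is.null(seed)) set.seed(seed)
  res <- .resample_metric_vectors(rows, lab, tau, rule, n_resamples)
  tab <- contingency_table(mean(res$tp), mean(res$tn), mean(res$fp),
                           mean(res$fn))
  metrics <- structure(list(
    mcc = mean(res$mcc),
    accuracy = mean(res$accuracy),
    specificity = mean(res$specificity, na.rm = TRUE),
    sensitivity = mean(res$sensitivity, na.rm = TRUE),
    table = tab
  ), class = "eval_metrics")
  structure(list(strategy = strategy, metrics = metrics, n = length(rows),
                 n_resamples = n_resamples, seed = seed,
                 resample_mcc = res$mcc), class = "strategy_result")
}

#' Evaluate all five strategies as one report table
#'
#' @inheritParams evaluate_strategy
#' @return Data frame with rows Global, Minimum, Maximum, Average, Random and
#'   columns strategy, mcc, accuracy, specificity, sensitivity, n, seed,
#'   n_resamples.
#' @export
evaluate_all_strategies <- function(m, labels, tau = 2,
                                    rule = c("two_sided", "destabilizing"),
                                    seed = 1L, n_resamples = 1000L) {
  rule <- match.arg(rule)
  rows <- lapply(.strategies, function(s) {
    r <- evaluate_strategy(m, labels, s, tau = tau, rule = rule,
                           seed = seed, n_resamples = n_resamples)
    data.frame(
      strategy = .strategy_display[[s]],
      mcc = r$metrics$mcc, accuracy = r$metrics$accuracy,
      specificity = r$metrics$specificity,
      sensitivity = r$metrics$sensitivity, n = r$n,
      seed = if (s == "random") seed else NA_integer_,
      n_resamples = if (s == "random") n_resamples else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Empirical significance of a strategy against the random baseline
#'
#' One-sided resampling p-value with add-one smoothing:
#' p = (k + 1) / (n_resamples + 1), where k counts resampled-baseline MCC
#' values at least as large as the reference strategy's MCC.
#'
#' @inheritParams evaluate_strategy
#' @param reference Reference strategy (default `"max"`). When the reference
#'   is `"random"` its mean resample MCC (under `seed + 1`) is used.
#' @return List: `p_value`, `reference_mcc`, `resample_mcc`, `n_resamples`.
#' @export
random_significance <- function(m, labels, tau = 2,
                                rule = c("two_sided", "destabilizing"),
                                reference = "max", seed = 1L,
                                n_resamples = 1000L) {
  rule <- match.arg(rule)
  ref_seed <- if (identical(reference, "random")) seed + 1L else NULL
  ref <- evaluate_strategy(m, labels, reference, tau = tau, rule = rule,
                           seed = ref_seed, n_resamples = n_resamples)
  lab <- .match_labels(m, labels)
  rows <- ddg_rows(m, drop_missing = TRUE)
  set.seed(seed)
  res <- .resample_metric_vectors(rows, lab, tau, rule, n_resamples)
  k <- sum(res$mcc >= ref$metrics$mcc)
  list(p_value = (k + 1) / (n_resamples + 1),
       reference_mcc = ref$metrics$mcc,
       resample_mcc = res$mcc, n_resamples = n_resamples)
}

#' Per-conformer metrics for one protein
#'
#' Evaluates each conformer's ddG column in isolation against the phenotype
#' labels of that protein's substitutions, to find the conformer that best
#' tracks the disease/neutral phenotype.
#'
#' @inheritParams evaluate_strategy
#' @param protein_id Protein to analyse.
#' @return Data frame (one row per conformer: conformer_id, n, tp, tn, fp,
#'   fn, mcc, accuracy, specificity, sensitivity) with attribute
#'   `mcc_range = c(min, max)`. Conformer columns with no value are skipped
#'   with a warning.
#' @export
per_conformer_metrics <- function(m, labels, protein_id, tau = 2,
                                  rule = c("two_sided", "destabilizing")) {
  rule <- match.arg(rule)
  stopifnot(inherits(m, "ddg_matrix"))
  sel <- m$sas$protein_id == protein_id
  if (!any(sel)) stop("no substitutions for protein '", protein_id, "'",
                      call. = FALSE)
  ids <- m$sas$sas_id[sel]
  lab <- labels$label[match(ids, labels$sas_id)]
  conf <- m$conformers$conformer_id[m$conformers$protein_id == protein_id]
  if (length(conf) == 0L) conf <- unique(m$cells$conformer_id[
    m$cells$sas_id %in% ids])
  out <- lapply(conf, function(cid) {
    cc <- m$cells[m$cells$conformer_id == cid & m$cells$sas_id %in% ids, ,
                  drop = FALSE]
    cc <- cc[!is.na(cc$ddg), , drop = FALSE]
    if (nrow(cc) == 0L) {
      warning("conformer '", cid, "' has no ddG values; skipped",
              call. = FALSE)
      return(NULL)
    }
    truth <- lab[match(cc$sas_id, ids)]
    mt <- .metrics_from_labels(truth, predict_label(cc$ddg, tau, rule))
    data.frame(conformer_id = cid, n = nrow(cc),
               tp = mt$table$tp, tn = mt$table$tn, fp = mt$table$fp,
               fn = mt$table$fn, mcc = mt$mcc, accuracy = mt$accuracy,
               specificity = mt$specificity, sensitivity = mt$sensitivity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) stop("no usable conformer column for protein '",
                         protein_id, "'", call. = FALSE)
  attr(out, "mcc_range") <- range(out$mcc)
  out
}

#' Fraction of substitutions with a perfectly agreeing conformer
#'
#' A substitution counts when at least one of its conformers' ddG values
#' predicts its true phenotype label.
#'
#' @inheritParams evaluate_strategy
#' @return Fraction in \[0, 1\].
#' @export
perfect_conformer_fraction <- function(m, labels, tau = 2,
                                       rule = c("two_sided",
                                                "destabilizing")) {
  rule <- match.arg(rule)
  lab <- .match_labels(m, labels)
  rows <- ddg_rows(m, drop_missing = TRUE)
  hit <- vapply(seq_along(rows), function(i) {
    any(predict_label(rows[[i]], tau, rule) == lab[i])
  }, logical(1))
  mean(hit)
}

#' Bound-state enrichment of the maximum-ddG conformer
#'
#' For each protein with externally supplied ligand-bound flags, finds the
#' conformer attaining the maximum ddG over all that protein's cells; when
#' several conformers tie, the protein counts as bound if any tied conformer
#' is bound. Proteins whose flags are not fully specified are excluded.
#'
#' @param m A `ddg_matrix`.
#' @param bound_flags Data frame with `protein_id`, `conformer_id`, `bound`
#'   (logical).
#' @return List: `fraction_bound`, `n_proteins`, `per_protein` data frame.
#' @export
bound_state_enrichment <- function(m, bound_flags) {
  stopifnot(inherits(m, "ddg_matrix"),
            all(c("protein_id", "conformer_id", "bound")
                %in% names(bound_flags)))
  cells <- m$cells[!is.na(m$cells$ddg), , drop = FALSE]
  cells$protein_id <- m$sas$protein_id[match(cells$sas_id, m$sas$sas_id)]
  bkey <- stats::setNames(bound_flags$bound, bound_flags$conformer_id)
  prots <- unique(cells$protein_id)
  rows <- lapply(prots, function(p) {
    pc <- cells[cells$protein_id == p, , drop = FALSE]
    flags <- bkey[unique(pc$conformer_id)]
    if (length(flags) == 0L || anyNA(flags)) return(NULL)
    top <- pc$conformer_id[pc$ddg == max(pc$ddg)]
    data.frame(protein_id = p, max_ddg = max(pc$ddg),
               max_conformers = paste(unique(top), collapse = ","),
               bound = any(bkey[unique(top)]), stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(rows) || nrow(rows) == 0L) {
    stop("no protein has complete bound/unbound flags", call. = FALSE)
  }
  list(fraction_bound = mean(rows$bound), n_proteins = nrow(rows),
       per_protein = rows)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution with the effective sample
#' size n1*n2/(n1+n2) (appropriate at the sample sizes in scope, hundreds).
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return List with `statistic` (D in \[0, 1\]) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  d <- max(abs(fx - fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(ne) * d
  if (d == 0) {
    p <- 1
  } else {
    j <- 1:100
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(max(p, 0), 1)
  }
  list(statistic = d, p_value = p)
}
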