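# Readers/writers for SAS annotation tables and per-(SAS, conformer) ddG
# tables, plus the adapter contract for external stability engines.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.aa3to1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)

#' Identifier of one single amino acid substitution
#'
#' @param protein_id,position,wt_aa,mut_aa Vectors defining the substitution.
#' @return Character ids of the form `P05062:128A>D`.
#' @export
sas_id <- function(protein_id, position, wt_aa, mut_aa) {
  sprintf("%s:%d%s>%s", protein_id, as.integer(position), wt_aa, mut_aa)
}

.normalize_label <- function(label) {
  lab <- tolower(trimws(label))
  out <- rep(NA_character_, length(lab))
  out[lab %in% c("disease", "lp/p")] <- "disease"
  out[lab %in% c("neutral", "polymorphism", "lb/b")] <- "neutral"
  out
}

.validate_sas <- function(df, source = "SAS table") {
  if (any(df$position < 1L)) {
    stop(source, ": positions must be >= 1", call. = FALSE)
  }
  bad_aa <- !(df$wt_aa %in% .aa_alphabet) | !(df$mut_aa %in% .aa_alphabet)
  if (any(bad_aa)) {
    stop(source, ": unknown amino acid code in row(s) ",
         paste(which(bad_aa), collapse = ", "), call. = FALSE)
  }
  same <- df$wt_aa == df$mut_aa
  if (any(same)) {
    stop(source, ": wild-type equals substituted residue in row(s) ",
         paste(which(same), collapse = ", "), call. = FALSE)
  }
  id <- sas_id(df$protein_id, df$position, df$wt_aa, df$mut_aa)
  if (anyDuplicated(id)) {
    dup <- which(duplicated(id))
    stop(source, ": duplicate substitution '", id[dup[1L]], "' in row ",
         dup[1L], call. = FALSE)
  }
  df$sas_id <- id
  df
}

#' Read a SAS annotation table
#'
#' Reads a TSV with header columns `protein_id`, `position`, `wt_aa`,
#' `mut_aa`, `label`. Labels are normalized: "Disease" -> `disease`,
#' "Polymorphism" -> `neutral` (case-insensitive; `disease`/`neutral` pass
#' through). Any other label, a wild-type equal to the substituted residue,
#' or a duplicated (protein, position, wt, mut) row is an error.
#'
#' @param path TSV file path.
#' @return Data frame of validated records with an added `sas_id` column,
#'   class `sas_table`.
#' @export
read_sas_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  need <- c("protein_id", "position", "wt_aa", "mut_aa", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("SAS table '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lab <- .normalize_label(df$label)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1L]
    stop("unknown label '", df$label[bad], "' in row ", bad, " of '",
         path, "'", call. = FALSE)
  }
  out <- data.frame(protein_id = df$protein_id,
                    position = as.integer(df$position),
                    wt_aa = toupper(df$wt_aa), mut_aa = toupper(df$mut_aa),
                    label = lab, stringsAsFactors = FALSE)
  out <- .validate_sas(out, source = paste0("'", path, "'"))
  class(out) <- c("sas_table", "data.frame")
  out
}

#' Build a SAS table in code
#'
#' Programmatic counterpart of [read_sas_table()] with identical validation.
#'
#' @inheritParams sas_id
#' @param label Character vector of `disease`/`neutral` (dialect labels such
#'   as "Polymorphism" are normalized).
#' @return A `sas_table` data frame.
#' @export
sas_table <- function(protein_id, position, wt_aa, mut_aa, label) {
  lab <- .normalize_label(label)
  if (anyNA(lab)) {
    stop("unknown label '", label[which(is.na(lab))[1L]], "'", call. = FALSE)
  }
  out <- data.frame(protein_id = protein_id, position = as.integer(position),
                    wt_aa = toupper(wt_aa), mut_aa = toupper(mut_aa),
                    label = lab, stringsAsFactors = FALSE)
  out <- .validate_sas(out)
  class(out) <- c("sas_table", "data.frame")
  out
}

#' Import a humsavar-style fixed-width variant list
#'
#' Convenience reader for the UniProt human-variant dialect: whitespace
#' separated lines `gene accession FTId p.Xxx123Yyy category ...` where the
#' category is Disease/Polymorphism (old dialect) or LP/P, LB/B (new).
#' Unclassified/US rows are dropped with a message.
#'
#' @param path File path.
#' @return A `sas_table` data frame.
#' @export
read_humsavar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("p\\.[A-Z][a-z]{2}\\d+[A-Z][a-z]{2}", lines)]
  if (length(lines) == 0L) {
    stop("no variant lines found in '", path, "'", call. = FALSE)
  }
  tok <- strsplit(trimws(lines), "\\s+")
  parse_one <- function(fields) {
    chg <- grep("^p\\.[A-Z][a-z]{2}\\d+[A-Z][a-z]{2}$", fields, value = TRUE)
    if (length(chg) != 1L) return(NULL)
    m <- regmatches(chg, regexec("^p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$",
                                 chg))[[1L]]
    wt <- .aa3to1[m[2L]]
    mut <- .aa3to1[m[4L]]
    if (is.na(wt) || is.na(mut)) return(NULL)
    idx <- which(fields == chg)
    lab <- if (idx < length(fields)) {
      .normalize_label(fields[idx + 1L])
    } else NA_character_
    data.frame(protein_id = fields[2L], position = as.integer(m[3L]),
               wt_aa = unname(wt), mut_aa = unname(mut),
               label = lab, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, Filter(Negate(is.null), lapply(tok, parse_one)))
  n_drop <- sum(is.na(rows$label))
  if (n_drop > 0L) {
    message("dropping ", n_drop, " unclassified variant(s)")
    rows <- rows[!is.na(rows$label), , drop = FALSE]
  }
  rows <- rows[rows$wt_aa != rows$mut_aa, , drop = FALSE]
  rows <- rows[!duplicated(sas_id(rows$protein_id, rows$position,
                                  rows$wt_aa, rows$mut_aa)), , drop = FALSE]
  out <- .validate_sas(rows)
  class(out) <- c("sas_table", "data.frame")
  out
}

#' Construct a ddG matrix
#'
#' Container for free-energy changes (kcal/mol, positive = destabilizing)
#' indexed by (substitution, conformer). Cells may be missing (`NA`), but
#' every substitution must retain at least one finite value.
#'
#' @param sas Data frame with `sas_id`, `protein_id`, `position`, `wt_aa`,
#'   `mut_aa` (one row per substitution, order preserved).
#' @param cells Data frame with `sas_id`, `conformer_id`, `ddg`.
#' @param conformers Data frame with `protein_id`, `conformer_id` listing the
#'   ensemble membership of each conformer.
#' @return A `ddg_matrix` object.
#' @export
ddg_matrix <- function(sas, cells, conformers) {
  stopifnot(all(c("sas_id", "protein_id", "position", "wt_aa", "mut_aa")
                %in% names(sas)),
            all(c("sas_id", "conformer_id", "ddg") %in% names(cells)),
            all(c("protein_id", "conformer_id") %in% names(conformers)))
  if (anyDuplicated(sas$sas_id)) {
    stop("duplicate sas_id in SAS index", call. = FALSE)
  }
  key <- paste(cells$sas_id, cells$conformer_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (substitution, conformer) cell", call. = FALSE)
  }
  unknown <- setdiff(cells$sas_id, sas$sas_id)
  if (length(unknown) > 0L) {
    stop("cells reference unknown substitution(s): ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  if (any(is.infinite(cells$ddg))) {
    stop("ddG values must be finite or NA", call. = FALSE)
  }
  n_ok <- tapply(!is.na(cells$ddg), factor(cells$sas_id,
                                           levels = sas$sas_id), sum)
  n_ok[is.na(n_ok)] <- 0L
  if (any(n_ok == 0L)) {
    stop("substitution(s) with no ddG value: ",
         paste(utils::head(sas$sas_id[n_ok == 0L], 3L), collapse = ", "),
         call. = FALSE)
  }
  rownames(sas) <- NULL
  rownames(cells) <- NULL
  structure(list(sas = as.data.frame(sas), cells = as.data.frame(cells),
                 conformers = as.data.frame(conformers)),
            class = "ddg_matrix")
}

#' @export
print.ddg_matrix <- function(x, ...) {
  cat("<ddg_matrix> ", nrow(x$sas), " substitutions x ",
      nrow(x$conformers), " conformers (", length(unique(x$sas$protein_id)),
      " proteins); ", sum(is.na(x$cells$ddg)), " missing cell(s)\n", sep = "")
  invisible(x)
}

#' Per-substitution ddG rows
#'
#' @param m A `ddg_matrix`.
#' @param drop_missing Drop `NA` cells from each row (default FALSE).
#' @return Named list (by `sas_id`, in index order) of numeric vectors named
#'   by conformer id.
#' @export
ddg_rows <- function(m, drop_missing = FALSE) {
  stopifnot(inherits(m, "ddg_matrix"))
  f <- factor(m$cells$sas_id, levels = m$sas$sas_id)
  vals <- split(stats::setNames(m$cells$ddg, m$cells$conformer_id), f)
  if (drop_missing) vals <- lapply(vals, function(v) v[!is.na(v)])
  vals
}

#' Read a per-(SAS, conformer) ddG table
#'
#' TSV with header columns `protein_id`, `position`, `wt_aa`, `mut_aa`,
#' `conformer_id`, `ddg_kcal_mol`. The literal "NA" (or an empty field) marks
#' a missing cell; any other non-numeric value is an error. A substitution
#' with no finite value at all is an error. When ensemble membership is
#' supplied, rows citing unknown conformers are kept with a warning.
#'
#' @param path TSV file path.
#' @param conformers Optional data frame (`protein_id`, `conformer_id`) of
#'   the known ensembles.
#' @return A `ddg_matrix`.
#' @export
read_ddg_table <- function(path, conformers = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  need <- c("protein_id", "position", "wt_aa", "mut_aa", "conformer_id",
            "ddg_kcal_mol")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("ddG table '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw <- trimws(df$ddg_kcal_mol)
  is_na <- is.na(raw) | raw %in% c("NA", "")
  ddg <- suppressWarnings(as.numeric(raw))
  bad <- which(!is_na & is.na(ddg))
  if (length(bad) > 0L) {
    stop("non-numeric ddG value '", raw[bad[1L]], "' in row ", bad[1L],
         " of '", path, "'", call. = FALSE)
  }
  id <- sas_id(df$protein_id, as.integer(df$position), toupper(df$wt_aa),
               toupper(df$mut_aa))
  sas <- data.frame(sas_id = id, protein_id = df$protein_id,
                    position = as.integer(df$position),
                    wt_aa = toupper(df$wt_aa), mut_aa = toupper(df$mut_aa),
                    stringsAsFactors = FALSE)
  sas <- sas[!duplicated(sas$sas_id), , drop = FALSE]
  cells <- data.frame(sas_id = id, conformer_id = df$conformer_id,
                      ddg = ddg, stringsAsFactors = FALSE)
  if (!is.null(conformers)) {
    unknown <- setdiff(cells$conformer_id, conformers$conformer_id)
    if (length(unknown) > 0L) {
      warning("ddG table cites conformer(s) not in the ensemble: ",
              paste(utils::head(unknown, 3L), collapse = ", "),
              call. = FALSE)
    }
    conf <- conformers[, c("protein_id", "conformer_id")]
  } else {
    conf <- unique(data.frame(protein_id = df$protein_id,
                              conformer_id = df$conformer_id,
                              stringsAsFactors = FALSE))
  }
  ddg_matrix(sas, cells, conf)
}

#' Write a ddG matrix back to TSV
#'
#' Inverse of [read_ddg_table()]; finite values survive a round trip
#' bit-exactly (17 significant digits), missing cells are written as "NA".
#'
#' @param m A `ddg_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ddg_table <- function(m, path) {
  stopifnot(inherits(m, "ddg_matrix"))
  sas <- m$sas
  idx <- match(m$cells$sas_id, sas$sas_id)
  out <- data.frame(
    protein_id = sas$protein_id[idx], position = sas$position[idx],
    wt_aa = sas$wt_aa[idx], mut_aa = sas$mut_aa[idx],
    conformer_id = m$cells$conformer_id,
    ddg_kcal_mol = ifelse(is.na(m$cells$ddg), "NA",
                          sprintf("%.17g", m$cells$ddg)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run an external stability engine for one (structure, substitution) pair
#'
#' Adapter contract for engines such as FoldX: the user supplies a shell
#' command template with placeholders `{structure}`, `{position}`, `{wt}`,
#' `{mut}`; the command must print one numeric ddG (kcal/mol) on stdout. The
#' adapter captures the value unaltered; a nonzero exit status or unparsable
#' output yields a missing cell with a logged warning.
#'
#' @param command_template Shell command with placeholders.
#' @param structure Path to the conformer structure file.
#' @param sas One-row `sas_table` (or list with `position`, `wt_aa`,
#'   `mut_aa`).
#' @param engine_name Engine label recorded in provenance (default
#'   "external").
#' @return List with `ddg` (numeric or NA), `ok`, `command`, and `engine`.
#' @export
run_stability_engine <- function(command_template, structure, sas,
                                 engine_name = "external") {
  cmd <- command_template
  cmd <- gsub("{structure}", structure, cmd, fixed = TRUE)
  cmd <- gsub("{position}", as.character(sas$position), cmd, fixed = TRUE)
  cmd <- gsub("{wt}", sas$wt_aa, cmd, fixed = TRUE)
  cmd <- gsub("{mut}", sas$mut_aa, cmd, fixed = TRUE)
  out <- suppressWarnings(tryCatch(system(cmd, intern = TRUE),
                                   error = function(e) character(0)))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    warning("engine '", engine_name, "' exited with status ", status,
            " for command: ", cmd, call. = FALSE)
    return(list(ddg = NA_real_, ok = FALSE, command = cmd,
                engine = engine_name))
  }
  txt <- paste(out, collapse = " ")
  tok <- regmatches(txt, regexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                                 txt))
  val <- suppressWarnings(as.numeric(tok))
  if (length(val) != 1L || is.na(val)) {
    warning("engine '", engine_name, "' produced unparsable output '",
            txt, "'", call. = FALSE)
    return(list(ddg = NA_real_, ok = FALSE, command = cmd,
                engine = engine_name))
  }
  list(ddg = val, ok = TRUE, command = cmd, engine = engine_name)
}

#' Provenance record for an engine run
#'
#' @param engine_name Engine label.
#' @param command_template Template used.
#' @param n_cells,n_missing Cell counts.
#' @param timestamp Optional timestamp string; defaults to the current time.
#' @return List serializable with `jsonlite::write_json()`.
#' @export
engine_provenance <- function(engine_name, command_template, n_cells,
                              n_missing, timestamp = NULL) {
  list(engine = engine_name, command_template = command_template,
       n_cells = n_cells, n_missing = n_missing,
       timestamp = timestamp %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Apply an author-numbering to sequence-numbering map to a SAS table
#'
#' Positions are 1-based sequence indices; when the structure's author
#' numbering differs, a two-column TSV (`author_position`,
#' `sequence_position`) remaps it. Identity is assumed otherwise.
#'
#' @param sas A `sas_table`.
#' @param map_path Path to the two-column TSV.
#' @return The remapped `sas_table`.
#' @export
apply_position_map <- function(sas, map_path) {
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  stopifnot(all(c("author_position", "sequence_position") %in% names(map)))
  idx <- match(sas$position, map$author_position)
  if (anyNA(idx)) {
    stop("position(s) missing from map: ",
         paste(utils::head(sas$position[is.na(idx)], 3L), collapse = ", "),
         call. = FALSE)
  }
  sas$position <- as.integer(map$sequence_position[idx])
  sas$sas_id <- sas_id(sas$protein_id, sas$position, sas$wt_aa, sas$mut_aa)
  sas
}

`%||%` <- function(a, b) if (is.null(a)) b else a
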