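# Rule-based interpretation of bioactivity scores and ADMET predictions,
# plus summary analytics over docking-result tables. Thresholds live in a
# data-driven rulebook (JSON) so the shipped defaults can be swapped or
# extended without code changes.

BIOACTIVITY_CLASSES <- c("GPCR ligand", "ion channel modulator",
                         "nuclear receptor ligand", "kinase inhibitor",
                         "protease inhibitor", "enzyme inhibitor")

#' Classify a bioactivity score
#'
#' A total partition of the reals: \code{active} for score > 0,
#' \code{moderately_active} for scores in [-0.50, 0] (both bounds
#' inclusive), \code{inactive} below -0.50.
#'
#' @param score finite numeric score (vectorized).
#' @return character vector of class labels.
#' @export
classify_bioactivity <- function(score) {
  if (any(!is.finite(score))) stop("bioactivity scores must be finite")
  ifelse(score > 0, "active",
         ifelse(score >= -0.50, "moderately_active", "inactive"))
}

#' Read a bioactivity-score table
#'
#' Wide CSV: a \code{ligand_id} column plus one numeric column per target
#' class (GPCR ligand, ion channel modulator, nuclear receptor ligand,
#' kinase inhibitor, protease inhibitor, enzyme inhibitor).
#'
#' @param path CSV path.
#' @return data.frame, one row per ligand, all six class columns present.
#' @export
read_bioactivity_table <- function(path) {
  if (!file.exists(path)) stop("bioactivity table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("ligand_id", BIOACTIVITY_CLASSES)
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("bioactivity table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  for (cl in BIOACTIVITY_CLASSES)
    if (any(!is.finite(df[[cl]])))
      stop("non-finite score in column '", cl, "'")
  df
}

# ---- ADMET rulebook --------------------------------------------------------

#' The default ADMET rulebook
#'
#' Threshold rules: Caco-2 permeability high above 0.90; intestinal
#' absorption poor below 30 percent; skin permeability low for logKp above
#' -2.5; blood-brain barrier readily crossed above logBBB -0.3 and brain
#' distribution poor below logBBB -1; T. pyriformis toxicity above -0.5.
#' Boolean predictions (P-gp roles, CYP roles, OCT2, AMES, hERG I/II,
#' hepatotoxicity, skin sensitisation) pass through as flags. CNS
#' permeability is reported without a verdict: no published cutoff backs one.
#'
#' @return list of rule records (property, kind, comparator, threshold,
#'   verdict texts).
#' @export
default_admet_rulebook <- function() {
  path <- system.file("extdata", "admet_rules.json", package = "cdftscreen")
  read_admet_rulebook(path)
}

#' Read an ADMET rulebook from JSON
#' @param path JSON file: array of rule objects.
#' @export
read_admet_rulebook <- function(path) {
  if (!file.exists(path)) stop("rulebook not found: ", path)
  rules <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (r in rules) {
    if (is.null(r$property) || is.null(r$kind))
      stop("every rule needs 'property' and 'kind'")
    if (r$kind == "threshold" &&
        (is.null(r$comparator) || is.null(r$threshold)))
      stop("threshold rule for '", r$property, "' needs comparator and threshold")
  }
  rules
}

apply_one_rule <- function(rule, rec) {
  prop <- rule$property
  val <- rec[[prop]]
  mk <- function(verdict, note = "") {
    data.frame(property = prop, rule = rule$label,
               value = if (is.null(val) || is.na(val)) NA else as.character(val),
               verdict = verdict, note = note, stringsAsFactors = FALSE)
  }
  if (is.null(val) || (length(val) == 1L && is.na(val)))
    return(mk("not evaluated", "property missing from record"))
  if (rule$kind == "report") return(mk("reported (no cutoff)"))
  if (rule$kind == "flag") {
    if (!is.logical(val)) stop("flag property '", prop, "' must be logical")
    return(mk(if (val) rule$verdict_true else rule$verdict_false))
  }
  # threshold rule
  if (!is.numeric(val)) stop("threshold property '", prop, "' must be numeric")
  hit <- switch(rule$comparator,
                gt = val > rule$threshold, ge = val >= rule$threshold,
                lt = val < rule$threshold, le = val <= rule$threshold,
                stop("unknown comparator '", rule$comparator, "'"))
  note <- ""
  if (!is.null(rule$note_band) &&
      abs(val - rule$threshold) <= rule$note_band)
    note <- sprintf("within %.3g of the %.3g threshold", rule$note_band,
                    rule$threshold)
  mk(if (hit) rule$verdict_true else rule$verdict_false, note)
}

#' Interpret one ligand's ADMET record against a rulebook
#'
#' Emits exactly one finding per rule, ordered by property name then rule
#' label; properties missing from the record yield a finding marked
#' "not evaluated" rather than an error.
#'
#' @param rec named list or one-row data.frame of ADMET properties
#'   (numeric values and logical flags); must carry \code{ligand_id}.
#' @param rulebook list of rules, default \code{default_admet_rulebook()}.
#' @return data.frame of findings: ligand_id, property, rule, value,
#'   verdict, note.
#' @export
interpret_admet <- function(rec, rulebook = default_admet_rulebook()) {
  if (is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1L)
    rec <- as.list(rec)
  }
  if (is.null(rec$ligand_id)) stop("ADMET record needs a ligand_id")
  if (!is.null(rec$intestinal_absorption) &&
      !is.na(rec$intestinal_absorption) &&
      (rec$intestinal_absorption < 0 || rec$intestinal_absorption > 100))
    stop("intestinal_absorption must lie in [0, 100], got ",
         rec$intestinal_absorption)
  findings <- do.call(rbind, lapply(rulebook, apply_one_rule, rec = rec))
  findings <- findings[order(findings$property, findings$rule), , drop = FALSE]
  rownames(findings) <- NULL
  cbind(ligand_id = rec$ligand_id, findings, stringsAsFactors = FALSE)
}

#' Read an ADMET prediction table
#'
#' Wide CSV with \code{ligand_id} plus numeric property columns and yes/no
#' flag columns (converted to logical).
#'
#' @param path CSV path.
#' @param flag_cols columns to coerce from Yes/No to logical; defaults to
#'   every column whose values are all in \{Yes, No\}.
#' @return data.frame, one row per ligand.
#' @export
read_admet_table <- function(path, flag_cols = NULL) {
  if (!file.exists(path)) stop("ADMET table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"ligand_id" %in% names(df))
    stop("ADMET table schema error: missing column ligand_id")
  if (is.null(flag_cols))
    flag_cols <- names(df)[vapply(df, function(col)
      is.character(col) && all(col %in% c("Yes", "No")), logical(1))]
  for (cl in flag_cols) df[[cl]] <- df[[cl]] == "Yes"
  df
}

# ---- docking analytics -----------------------------------------------------

#' Read a docking-results table
#'
#' CSV with columns protein_id, ligand_id, affinity (kcal/mol, negative =
#' favorable), n_hbonds, residues (semicolon-separated labels).
#'
#' @param path CSV path.
#' @return data.frame of docking records.
#' @export
read_docking_table <- function(path) {
  if (!file.exists(path)) stop("docking table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("protein_id", "ligand_id", "affinity", "n_hbonds")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("docking table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(df$affinity))) stop("affinities must be finite")
  if (any(df$n_hbonds < 0)) stop("hydrogen-bond counts must be non-negative")
  df
}

#' Summary analytics over docking records
#'
#' @param records data.frame as returned by \code{read_docking_table}.
#' @return list: \code{n_complexes}; \code{global_best} and
#'   \code{global_worst} (affinity extremes with their complex labels);
#'   \code{best_per_protein} (most negative affinity; ties broken by more
#'   hydrogen bonds, then lexicographic ligand_id); \code{mean_per_ligand};
#'   \code{hbond_range}.
#' @export
docking_summary <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("docking_summary needs a non-empty record table")
  pick <- function(df) {
    ord <- order(df$affinity, -df$n_hbonds, df$ligand_id)
    df[ord[1], c("protein_id", "ligand_id", "affinity", "n_hbonds")]
  }
  best <- records[which.min(records$affinity), ]
  worst <- records[which.max(records$affinity), ]
  per_protein <- do.call(rbind, lapply(split(records, records$protein_id), pick))
  rownames(per_protein) <- NULL
  means <- vapply(split(records$affinity, records$ligand_id), mean, numeric(1))
  list(
    n_complexes = nrow(records),
    global_best = list(protein_id = best$protein_id, ligand_id = best$ligand_id,
                       affinity = best$affinity),
    global_worst = list(protein_id = worst$protein_id,
                        ligand_id = worst$ligand_id, affinity = worst$affinity),
    best_per_protein = per_protein,
    mean_per_ligand = means,
    hbond_range = range(records$n_hbonds))
}
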