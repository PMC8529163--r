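# Orchestration: one call chains global CDFT descriptors -> classification
# -> pharma rules -> docking analytics into a single serializable report.
# Stages whose inputs are absent are marked "skipped", never fabricated.

#' Assemble a pipeline configuration
#'
#' @param species path to a species table (required for the descriptor
#'   stage); NULL skips it.
#' @param units energy unit of the species table.
#' @param bioactivity,admet,docking optional table paths.
#' @param rulebook optional ADMET rulebook JSON path (default rulebook when
#'   NULL).
#' @param tce_homo nucleophilicity reference HOMO (eV).
#' @param kid_tol KID pass tolerance (eV).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(species = NULL, units = "ev", bioactivity = NULL,
                            admet = NULL, docking = NULL, rulebook = NULL,
                            tce_homo = DEFAULT_REF_HOMO_EV, kid_tol = 0.05) {
  stopifnot(kid_tol > 0)
  for (p in c(species, bioactivity, admet, docking, rulebook))
    if (!is.null(p) && !file.exists(p)) stop("configured input not found: ", p)
  structure(list(species = species, units = units, bioactivity = bioactivity,
                 admet = admet, docking = docking, rulebook = rulebook,
                 tce_homo = tce_homo, kid_tol = kid_tol),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full profiling pipeline
#'
#' @param config a \code{pipeline_config}.
#' @return list of class \code{profile_report}: \code{descriptors}
#'   (data.frame or "skipped"), \code{kid} (list of kid_reports or
#'   "skipped"), \code{bioactivity}, \code{admet_findings}, \code{docking}
#'   and a \code{provenance} block (package version, config hash).
#' @export
run_profile <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(descriptors = "skipped", kid = "skipped",
                 bioactivity = "skipped", admet_findings = "skipped",
                 docking = "skipped")

  if (!is.null(config$species)) {
    records <- read_species_table(config$species, units = config$units)
    charges <- vapply(records, function(r) r$charge, integer(1))
    neutrals <- records[charges == 0L]
    ia <- lapply(neutrals, vertical_ia_koopmans)
    names(ia) <- vapply(neutrals, function(r) r$ligand_id, character(1))
    report$descriptors <- descriptor_table(ia, ref_homo_ev = config$tce_homo)
    have_totals <- all(vapply(records, function(r) !is.na(r$e_total), logical(1)))
    if (any(charges != 0L) && have_totals) {
      triplets <- collate_triplets(records)
      report$kid <- lapply(triplets, kid_check, tol_ev = config$kid_tol)
    }
  }
  if (!is.null(config$bioactivity)) {
    tab <- read_bioactivity_table(config$bioactivity)
    long <- do.call(rbind, lapply(BIOACTIVITY_CLASSES, function(cl)
      data.frame(ligand_id = tab$ligand_id, target_class = cl,
                 score = tab[[cl]], verdict = classify_bioactivity(tab[[cl]]),
                 stringsAsFactors = FALSE)))
    report$bioactivity <- long[order(long$ligand_id, long$target_class), ]
    rownames(report$bioactivity) <- NULL
  }
  if (!is.null(config$admet)) {
    tab <- read_admet_table(config$admet)
    rb <- if (is.null(config$rulebook)) default_admet_rulebook()
          else read_admet_rulebook(config$rulebook)
    report$admet_findings <- do.call(rbind, lapply(seq_len(nrow(tab)),
      function(i) interpret_admet(tab[i, ], rulebook = rb)))
  }
  if (!is.null(config$docking))
    report$docking <- docking_summary(read_docking_table(config$docking))

  report$provenance <- list(
    package = "cdftscreen",
    version = as.character(utils::packageVersion("cdftscreen")),
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC"))
  structure(report, class = "profile_report")
}

#' Render a profile report as JSON or markdown
#'
#' @param report a \code{profile_report}.
#' @param format \code{"json"} or \code{"markdown"}.
#' @return a character scalar (the document).
#' @export
render_report <- function(report, format = "json") {
  stopifnot(inherits(report, "profile_report"))
  if (!format %in% c("json", "markdown"))
    stop("unknown format '", format, "'; supported: json, markdown")
  if (format == "json")
    return(jsonlite::toJSON(unclass(report), dataframe = "rows",
                            auto_unbox = TRUE, digits = NA, pretty = TRUE))
  md_table <- function(df) {
    if (!is.data.frame(df)) return("_skipped_")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.4f", x))
    paste(c(paste0("| ", paste(names(df), collapse = " | "), " |"),
            paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
            apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))),
          collapse = "\n")
  }
  kid_df <- if (is.list(report$kid) && !identical(report$kid, "skipped"))
    do.call(rbind, lapply(report$kid, function(k)
      data.frame(ligand_id = k$ligand_id, j_i = k$j_i, j_a = k$j_a,
                 j_hl = k$j_hl, passes = k$passes))) else "skipped"
  dock_md <- if (is.list(report$docking)) {
    s <- report$docking
    paste0("Complexes: ", s$n_complexes, "; strongest binder: ",
           s$global_best$ligand_id, " on ", s$global_best$protein_id,
           " (", s$global_best$affinity, " kcal/mol); weakest: ",
           s$global_worst$affinity, " kcal/mol.\n\n",
           md_table(s$best_per_protein))
  } else "_skipped_"
  paste(c("# Ligand profiling report",
          "", "## Global Reactivity Descriptors", "",
          md_table(report$descriptors),
          "", "## KID consistency", "",
          if (is.data.frame(kid_df)) md_table(kid_df) else "_skipped_",
          "", "## Bioactivity classification", "",
          md_table(report$bioactivity),
          "", "## ADMET findings", "",
          md_table(report$admet_findings),
          "", "## Docking summary", "", dock_md,
          "", sprintf("_%s %s, config %s_", report$provenance$package,
                      report$provenance$version,
                      report$provenance$config_hash)),
        collapse = "\n")
}

#' Parse a JSON-rendered report back into a profile_report
#'
#' @param json character scalar from \code{render_report(..., "json")}.
#' @export
parse_report_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  structure(x, class = "profile_report")
}
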