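# Orchestration: validate a configuration, run the selected stages, write
# the report bundle (TSV tables + JSON summary + manifest). Deterministic
# given config + seed.

#' Build and validate a pipeline configuration
#'
#' Any subset of stages can be configured; a stage runs when its inputs are
#' present. Referenced files must exist at validation time. Every defaulted
#' parameter is echoed into the run manifest.
#'
#' @param substrates Path to a substrate-definition JSON
#'   ([read_substrates_json()]).
#' @param ions Named list: substrate id -> ion-list TSV path.
#' @param parents Path to a parent FASTA; defaults to the packaged bovine
#'   hemoglobin chains when peptide mapping is requested without one.
#' @param peptides Path to a product-peptide TSV.
#' @param psscl Path to a PS-SCL rate TSV.
#' @param decay Path to an activity time-series TSV (inactivation fit).
#' @param ph_activity Path to a pH-activity TSV (columns `ph`, `value`).
#' @param mass_mode `"monoisotopic"` or `"average"`.
#' @param tolerance Ion-matching tolerance in Da.
#' @param max_cuts Maximum simultaneous cuts considered per substrate.
#' @param min_jaccard Hemocidin-annotation overlap threshold.
#' @param threshold Specificity-matrix threshold.
#' @param seed Integer seed recorded and used for any stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(substrates = NULL, ions = NULL, parents = NULL,
                            peptides = NULL, psscl = NULL, decay = NULL,
                            ph_activity = NULL,
                            mass_mode = "monoisotopic", tolerance = 0.5,
                            max_cuts = 2L, min_jaccard = 0.5,
                            threshold = 0.5, seed = 1L) {
  cfg <- list(substrates = substrates, ions = ions, parents = parents,
              peptides = peptides, psscl = psscl, decay = decay,
              ph_activity = ph_activity,
              mass_mode = match.arg(mass_mode, c("monoisotopic", "average")),
              tolerance = tolerance, max_cuts = as.integer(max_cuts),
              min_jaccard = min_jaccard, threshold = threshold,
              seed = as.integer(seed))
  paths <- c(cfg$substrates, unlist(cfg$ions), cfg$parents, cfg$peptides,
             cfg$psscl, cfg$decay, cfg$ph_activity)
  missing <- if (length(paths)) paths[!file.exists(paths)] else character()
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (cfg$tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the analysis pipeline
#'
#' Executes every stage whose inputs are configured and writes a report
#' bundle under `out_dir`: per-substrate site reports, degradome interval /
#' site / subsite tables with class percentages and hemocidin annotations,
#' the normalized PS-SCL profile and derived specificity matrix, kinetic
#' fits, a JSON summary, and a manifest echoing the full configuration
#' (with defaults), package version and a config hash.
#'
#' @param config A [pipeline_config()] (or a path to a JSON file of
#'   arguments for it).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with all stage results plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config))
    config <- do.call(pipeline_config, jsonlite::fromJSON(config))
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  # -- substrate mapping ----------------------------------------------------
  if (!is.null(config$substrates) && length(config$ions)) {
    subs <- read_substrates_json(config$substrates)
    site_rows <- list()
    for (id in names(config$ions)) {
      if (is.null(subs[[id]]))
        stop("ion list given for unknown substrate '", id, "'", call. = FALSE)
      obs <- read_ion_tsv(config$ions[[id]])$mz
      res <- match_ions(subs[[id]], obs, tolerance = config$tolerance,
                        max_cuts = config$max_cuts, mode = config$mass_mode)
      results$substrate[[id]] <- res
      site_rows[[id]] <- data.frame(
        substrate = id,
        site = if (length(res$sites)) res$sites else ".",
        stringsAsFactors = FALSE)
      write_tsv_canonical(res$matches[, c("observed_mz", "sequence", "mz",
                                          "mass_error", "sites")],
                          file.path(out_dir, paste0("matches_",
                                                    gsub("\\s+", "_", id),
                                                    ".tsv")))
    }
    write_tsv_canonical(do.call(rbind, site_rows),
                        file.path(out_dir, "cleavage_sites.tsv"))
  }

  # -- degradome profiling --------------------------------------------------
  if (!is.null(config$peptides)) {
    parents <- if (!is.null(config$parents))
      read_parent_fasta(config$parents) else bovine_hemoglobin()
    peps <- read_peptide_tsv(config$peptides)
    iv <- map_peptides(peps, parents)
    iv <- annotate_hemocidins(iv, hemocidin_reference(),
                              min_jaccard = config$min_jaccard)
    results$degradome$intervals <- iv
    write_tsv_canonical(iv, file.path(out_dir, "peptide_intervals.tsv"))
    if (nrow(iv)) {
      sites <- extract_sites(iv, parents)
      results$degradome$sites <- sites
      write_tsv_canonical(as.data.frame(sites),
                          file.path(out_dir, "degradome_sites.tsv"))
      if (nrow(sites)) {
        tab <- subsite_table(sites)
        summ <- classify_summary(tab)
        results$degradome$subsite_table <- tab
        results$degradome$summary <- summ
        out <- data.frame(subsite = rownames(tab),
                          as.data.frame(unclass(tab)), check.names = FALSE)
        write_tsv_canonical(out, file.path(out_dir, "subsite_table.tsv"))
        write_tsv_canonical(
          data.frame(subsite = rownames(summ$class_percent),
                     summ$class_percent),
          file.path(out_dir, "class_percent.tsv"))
      }
    } else {
      write_tsv_canonical(empty_sites(),
                          file.path(out_dir, "degradome_sites.tsv"))
    }
  }

  # -- PS-SCL profiling -----------------------------------------------------
  if (!is.null(config$psscl)) {
    prof <- normalize_psscl(read_psscl_tsv(config$psscl))
    mat <- build_matrix(prof, threshold = config$threshold)
    results$psscl <- list(profile = prof, matrix = mat)
    write_tsv_canonical(prof, file.path(out_dir, "psscl_normalized.tsv"))
    write_matrix_json(mat, file.path(out_dir, "specificity_matrix.json"))
  }

  # -- kinetics -------------------------------------------------------------
  kin <- list()
  if (!is.null(config$decay)) {
    d <- read_activity_tsv(config$decay)
    fit <- fit_inactivation(d$time_min, d$value)
    kin$inactivation <- fit[c("k1_per_min", "k1_per_sec", "half_life_min",
                              "r_squared", "n_points")]
  }
  if (!is.null(config$ph_activity)) {
    d <- read_tsv_checked(config$ph_activity, c("ph", "value"),
                          c("ph", "value"))
    prof <- ph_profile(d$ph, d$value)
    kin$ph_optimum <- prof$optimum
    write_tsv_canonical(prof$curve, file.path(out_dir, "ph_profile.tsv"))
  }
  if (length(kin)) results$kinetics <- kin

  # -- summary + manifest ---------------------------------------------------
  summary <- list(
    sites = lapply(results$substrate, `[[`, "sites"),
    n_peptides_mapped = if (!is.null(results$degradome))
      nrow(results$degradome$intervals) else NULL,
    kinetics = results$kinetics
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  cfg_plain <- unclass(config)
  cfg_file <- file.path(out_dir, "manifest.json")
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_plain, tmp, auto_unbox = TRUE, null = "null")
  manifest <- list(
    package = "scissile",
    version = as.character(utils::packageVersion("scissile")),
    config = cfg_plain,
    config_md5 = unname(tools::md5sum(tmp)),
    r_version = R.version.string
  )
  unlink(tmp)
  jsonlite::write_json(manifest, cfg_file, auto_unbox = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}
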