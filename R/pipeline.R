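#' @title Workflow runners (simulate / kinetics / geometry)
#'
#' @description The three runners tie the package stages into the full
#' study workflow and are the programmatic equivalent of a command-line
#' interface: each takes a validated config (YAML path or list), writes its
#' outputs and a reproducibility manifest (seed, parameters, input hashes,
#' package version) to an output directory, and returns its results
#' invisibly.  A thin Rscript wrapper over these functions ships in
#' \code{inst/scripts/slowbind}.
#'
#' @param config a YAML file path or a named list.
#' @name workflow
NULL

load_config <- function(config, allowed) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config
}

write_manifest <- function(out_dir, config, outputs) {
  files <- file.path(out_dir, outputs)
  files <- files[file.exists(files)]
  manifest <- list(
    package = "slowbind",
    version = as.character(utils::packageVersion("slowbind")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config,
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

scheme_from_config <- function(x) {
  kinetic_scheme(k3 = x$k3 %||% 1e9, k4 = x$k4, k5 = x$k5, k6 = x$k6)
}

#' @describeIn workflow Generate the synthetic inputs: simulated
#'   progress-curve CSV (k_obs mode), Henderson table CSV, and toy conformer
#'   PDB files.  Config keys: \code{seed}, \code{out_dir}, \code{scheme}
#'   (k3/k4/k5/k6), \code{mm} (kcat/Km), \code{design} (assay_design
#'   arguments), \code{henderson} (assay_design arguments or FALSE),
#'   \code{conformers} (list of \code{name}/\code{target_delta_ap}/
#'   \code{coord_noise} entries or FALSE).
#' @export
run_simulate <- function(config) {
  config <- load_config(config, c("seed", "out_dir", "scheme", "mm",
                                  "design", "henderson", "conformers"))
  if (is.null(config$scheme)) stop("config needs a 'scheme' entry")
  if (is.null(config$out_dir)) stop("config needs an 'out_dir' entry")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- scheme_from_config(config$scheme)
  mmc <- config$mm %||% list()
  mm <- michaelis_params(kcat = mmc$kcat %||% 37, Km = mmc$Km %||% 1e-3)
  dcfg <- config$design %||% list()
  if (!is.null(dcfg$inhibitor_grid) && any(unlist(dcfg$inhibitor_grid) < 0))
    stop("inhibitor_grid must be nonnegative")
  design <- do.call(assay_design,
                    c(list(mode = "kobs", seed = seed), dcfg))
  sim <- simulate_assay(scheme, mm, design)
  utils::write.csv(assay_curves(sim),
                   file.path(out_dir, "progress_curves.csv"),
                   row.names = FALSE)
  outputs <- "progress_curves.csv"
  if (!isFALSE(config$henderson)) {
    hcfg <- config$henderson %||% list()
    if (isTRUE(hcfg)) hcfg <- list()
    hdesign <- do.call(assay_design,
                       c(list(mode = "henderson", seed = seed), hcfg))
    tab <- generate_henderson_table(scheme, mm, hdesign)
    utils::write.csv(as.data.frame(tab),
                     file.path(out_dir, "henderson_table.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "henderson_table.csv")
  }
  if (!is.null(config$conformers) && !isFALSE(config$conformers)) {
    for (cc in config$conformers) {
      nm <- cc$name %||% sprintf("conformer_%0.0f", cc$target_delta_ap)
      model <- generate_conformer(
        target_delta_ap = cc$target_delta_ap,
        coord_noise = cc$coord_noise %||% 0, seed = seed)
      write_structure_pdb(model, file.path(out_dir, paste0(nm, ".pdb")))
      outputs <- c(outputs, paste0(nm, ".pdb"))
    }
  }
  write_manifest(out_dir, config, outputs)
  invisible(file.path(out_dir, outputs))
}

#' @describeIn workflow Run the staged kinetic inference on a progress-curve
#'   CSV and write a report of every fitted and derived parameter.  Config
#'   keys: \code{input} (CSV path), \code{out_dir}, \code{Km}, \code{k3},
#'   \code{alpha}, \code{henderson_input} (optional Henderson CSV).
#' @export
run_kinetics <- function(config) {
  config <- load_config(config, c("input", "out_dir", "Km", "k3", "alpha",
                                  "henderson_input", "seed"))
  if (is.null(config$input)) stop("config needs an 'input' CSV path")
  if (is.null(config$out_dir)) stop("config needs an 'out_dir' entry")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- read_progress_csv(config$input)
  fit <- fit_slow_binding(data, Km = config$Km,
                          k3 = config$k3 %||% 1e9,
                          alpha = config$alpha %||% 0.05)
  report <- list(
    n_curves = length(fit$progress_fits),
    kobs_series = fit$kobs_series,
    note = fit$note)
  if (!is.null(fit$saturation)) {
    report$saturation <- list(
      k5 = fit$saturation$k5, k6 = fit$saturation$k6,
      KI_app = fit$saturation$KI, se = as.list(fit$saturation$se),
      decreasing = fit$saturation$decreasing)
    report$mechanism <- list(label = fit$verdict$label,
                             tau = fit$verdict$tau,
                             p_trend = fit$verdict$p_trend,
                             reason = fit$verdict$reason)
  }
  if (!is.null(fit$report)) report$derived <- unclass(fit$report)
  if (!is.null(config$henderson_input)) {
    tab <- utils::read.csv(config$henderson_input)
    hf <- henderson_fit(tab, Km = config$Km %||% 1e-3)
    report$henderson <- list(KIstar = hf$KIstar, Et = hf$Et)
  }
  jsonlite::write_json(report, file.path(config$out_dir, "kinetics_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  write_manifest(config$out_dir, config, "kinetics_report.json")
  invisible(fit)
}

#' @describeIn workflow Run the conformer-geometry analysis on a set of PDB
#'   files against an open reference; writes a per-structure table of
#'   (delta_ap, rmsd, state).  A structure missing a marker is reported as a
#'   flagged row and the run continues.  Config keys: \code{reference}
#'   (PDB path), \code{structures} (PDB paths), \code{out_dir},
#'   \code{markers} (resno1/resno2/resno3/vertex), \code{zones}.
#' @export
run_geometry <- function(config) {
  config <- load_config(config, c("reference", "structures", "out_dir",
                                  "markers", "zones", "seed"))
  if (is.null(config$reference)) stop("config needs a 'reference' PDB path")
  if (is.null(config$out_dir)) stop("config needs an 'out_dir' entry")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mk <- config$markers %||% list()
  markers <- marker_triple(resno1 = mk$resno1 %||% 91,
                           resno2 = mk$resno2 %||% 137,
                           resno3 = mk$resno3 %||% 42,
                           vertex = mk$vertex %||% 2)
  zones <- if (is.null(config$zones)) default_state_zones()
  else state_zones(lapply(config$zones, unlist))
  reference <- read_structure(config$reference)
  rows <- lapply(config$structures, function(p) {
    res <- tryCatch({
      m <- read_structure(p)
      r <- aperture_result(m, reference, markers, zones)
      data.frame(structure = basename(p), delta_ap = r$delta_ap,
                 rmsd = r$rmsd, state = r$state, error = NA_character_)
    }, error = function(e) {
      data.frame(structure = basename(p), delta_ap = NA_real_,
                 rmsd = NA_real_, state = "error",
                 error = conditionMessage(e))
    })
    res
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(config$out_dir, "geometry_report.csv"),
                   row.names = FALSE)
  write_manifest(config$out_dir, config, "geometry_report.csv")
  invisible(tab)
}
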