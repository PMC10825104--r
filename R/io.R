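#' Read a table of time-activity curves
#'
#' Accepts delimited text (comma or tab, auto-detected) in either layout:
#' long, with columns `frame_start_s`, `frame_duration_s`,
#' `value_kBq_per_mL` and optionally `region`; or wide, with
#' `frame_start_s`, `frame_duration_s` and one column per region. Times are
#' stored in seconds on disk (PET convention) and converted to minutes
#' internally (model convention). Rows may arrive unsorted; overlapping
#' frames and non-numeric cells are rejected with the offending row.
#'
#' @param path file path.
#' @return A list: `grid` ([time_grid]) and `tacs` (named list of [tac]s).
#' @export
read_tac_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("frame_start_s", "frame_duration_s")
  if (!all(need %in% names(df)))
    stop("missing timing columns: ", paste(setdiff(need, names(df)),
                                           collapse = ", "))
  for (cn in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad))
      stop("non-numeric '", cn, "' at row ", bad[1L])
    df[[cn]] <- as.numeric(df[[cn]])
  }
  if ("value_kBq_per_mL" %in% names(df)) {
    if (is.null(df$region)) df$region <- "TAC"
    wide <- stats::reshape(
      df[c("frame_start_s", "frame_duration_s", "region", "value_kBq_per_mL")],
      idvar = need, timevar = "region", direction = "wide")
    names(wide) <- sub("^value_kBq_per_mL\\.", "", names(wide))
    df <- wide
  }
  ord <- order(df$frame_start_s)
  df <- df[ord, , drop = FALSE]
  grid <- tryCatch(time_grid(df$frame_start_s / 60, df$frame_duration_s / 60),
                   error = function(e)
                     stop("invalid frame schedule: ", conditionMessage(e)))
  regions <- setdiff(names(df), need)
  if (!length(regions)) stop("no region columns found")
  tacs <- lapply(regions, function(rn) {
    v <- suppressWarnings(as.numeric(df[[rn]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric value for region '", rn, "' at sorted row ", bad[1L])
    tac(grid, v, label = rn)
  })
  names(tacs) <- regions
  list(grid = grid, tacs = tacs)
}

#' Write TACs as a wide delimited table
#'
#' Inverse of [read_tac_table] (wide layout, comma-separated, seconds);
#' values round-trip exactly at full double precision.
#'
#' @param tacs a [tac] or list of [tac]s sharing one grid.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  g <- do.call(stop_if_grid_mismatch, tacs)
  df <- data.frame(frame_start_s = g$frame_start * 60,
                   frame_duration_s = g$frame_duration * 60)
  for (i in seq_along(tacs)) {
    nm <- tacs[[i]]$label
    if (!nzchar(nm)) nm <- paste0("TAC", i)
    df[[nm]] <- tacs[[i]]$values
  }
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read anchor blood samples
#'
#' Delimited text with columns `time_min` and `conc_kBq_per_mL` (optional
#' `weight`).
#'
#' @param path file path.
#' @return data.frame with columns `time_min`, `conc` (and `weight` if
#'   present).
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "conc_kBq_per_mL") %in% names(df)))
    stop("anchors file needs columns time_min, conc_kBq_per_mL")
  out <- data.frame(time_min = as.numeric(df$time_min),
                    conc = as.numeric(df$conc_kBq_per_mL))
  if (!is.null(df$weight)) out$weight <- as.numeric(df$weight)
  if (anyNA(out)) stop("non-numeric anchor entries")
  out
}

#' Analysis configuration
#'
#' Validated bag of the physical and procedural constants a run depends on.
#' Unknown keys are rejected rather than ignored, so typos cannot silently
#' fall back to defaults.
#'
#' @param R blood-to-plasma ratio (default 0.9, human).
#' @param brain_density brain density, g/mL (default 1.05; used for any
#'   mL-to-g tissue conversion).
#' @param lumped_constant FDG lumped constant (default 0.52).
#' @param plasma_glucose plasma glucose, µmol/mL (`NULL` disables CMRGlu).
#' @param t_star Patlak linear-phase start, minutes (default 20).
#' @param seed integer seed for all stochastic steps.
#' @param n_starts SIME multi-start count.
#' @param bounds optional named list overriding fitting boxes.
#' @return An object of class `run_config`.
#' @export
run_config <- function(R = 0.9, brain_density = 1.05, lumped_constant = 0.52,
                       plasma_glucose = NULL, t_star = 20, seed = 1L,
                       n_starts = 8, bounds = NULL) {
  for (nm in c("R", "brain_density", "lumped_constant", "t_star")) {
    v <- get(nm)
    if (!is.numeric(v) || !is.finite(v) || v <= 0)
      stop(nm, " must be a positive number")
  }
  if (!is.null(plasma_glucose) &&
      (!is.numeric(plasma_glucose) || plasma_glucose <= 0))
    stop("plasma_glucose must be a positive number")
  structure(list(R = R, brain_density = brain_density,
                 lumped_constant = lumped_constant,
                 plasma_glucose = plasma_glucose, t_star = t_star,
                 seed = as.integer(seed), n_starts = n_starts,
                 bounds = bounds),
            class = "run_config")
}

#' Load a configuration from YAML
#'
#' @param path YAML file; keys must be arguments of [run_config] (unknown
#'   keys are rejected).
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Read a dynamic PET volume with masks from NIfTI files
#'
#' @param pet_path 4D NIfTI volume.
#' @param timing either a delimited file with `frame_start_s`,
#'   `frame_duration_s` columns or a BIDS-style JSON with `FrameTimesStart`
#'   and `FrameDuration` (seconds).
#' @param mask_paths named character vector of 3D NIfTI mask files.
#' @return A [dynamic_image].
#' @export
read_dynamic_image <- function(pet_path, timing, mask_paths = c()) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the 'RNifti' package is required to read NIfTI volumes")
  vox <- RNifti::readNifti(pet_path)
  vs <- attr(RNifti::niftiHeader(pet_path), "pixdim")
  if (grepl("\\.json$", timing)) {
    j <- jsonlite::read_json(timing, simplifyVector = TRUE)
    grid <- time_grid(j$FrameTimesStart / 60, j$FrameDuration / 60)
  } else {
    df <- utils::read.csv(timing)
    grid <- time_grid(df$frame_start_s / 60, df$frame_duration_s / 60)
  }
  masks <- lapply(mask_paths, function(p) RNifti::readNifti(p) > 0)
  names(masks) <- names(mask_paths)
  dynamic_image(unclass(vox), grid,
                voxel_size = RNifti::pixdim(vox)[1:3], masks = masks)
}

#' Run the full simulation-to-quantification pipeline
#'
#' Executes simulate (or accept supplied curves) -> SIME -> standalone
#' refits -> Patlak/CMRGlu -> input-function comparison, and returns a
#' machine-readable report that records every constant, bound and seed the
#' run used. With `out_dir` set, writes `report.json`, a human-readable
#' `summary.txt` and per-region CSV tables.
#'
#' @param config a [run_config].
#' @param inputs `NULL` to run on [reference_simulation()] (with its own
#'   `R = 1`), or a list with `wb_tac`, `region_tacs`, `anchors` and
#'   optionally `true_aif`, `truth`.
#' @param mode SIME estimator, `"mdif"` (default) or `"idif"`.
#' @param out_dir optional output directory.
#' @param require_cmrglu fail up front (before any computation) when CMRGlu
#'   output is requested but the config carries no `plasma_glucose`.
#' @return The report, invisibly when written to disk.
#' @export
run_pipeline <- function(config = run_config(), inputs = NULL,
                         mode = "mdif", out_dir = NULL,
                         require_cmrglu = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (require_cmrglu && is.null(config$plasma_glucose))
    stop("CMRGlu requested but the config has no plasma_glucose")
  stage <- "simulate"
  report <- tryCatch({
    if (is.null(inputs)) {
      sim <- reference_simulation()
      inputs <- list(wb_tac = sim$wb_tac, region_tacs = sim$region_tacs,
                     anchors = sim$anchors, true_aif = sim$aif,
                     truth = sim$truth)
      R_used <- sim$R
    } else R_used <- config$R
    stage <- "sime"
    prob <- sime_problem(inputs$wb_tac, inputs$region_tacs, inputs$anchors,
                         R = R_used, mode = mode)
    fitter <- if (mode == "mdif") fit_sime_mdif else fit_sime_idif
    sres <- fitter(prob, n_starts = config$n_starts, seed = config$seed)
    stage <- "fit"
    w <- make_weights(inputs$wb_tac$grid, inputs$wb_tac)
    cp <- sres$input_function
    fits <- lapply(inputs$region_tacs, function(tc)
      fit_standalone(tc, cp, weights = w, R = R_used))
    stage <- "patlak"
    cfg_cmr <- if (!is.null(config$plasma_glucose))
      cmrglu_config(config$lumped_constant, config$plasma_glucose) else NULL
    pat <- lapply(inputs$region_tacs, function(tc)
      patlak(tc, cp, t_star = config$t_star, cmrglu = cfg_cmr))
    stage <- "compare"
    cmp <- if (!is.null(inputs$true_aif))
      compare_curves(cp, inputs$true_aif) else NULL
    regions <- data.frame(
      region = vapply(inputs$region_tacs, function(x) x$label, ""),
      K1 = vapply(fits, function(f) f$params$K1, 0),
      k2 = vapply(fits, function(f) f$params$k2, 0),
      k3 = vapply(fits, function(f) f$params$k3, 0),
      Vb = vapply(fits, function(f) f$params$Vb, 0),
      Ki_mL_100g_min = vapply(fits, function(f) 100 * f$params$Ki, 0),
      Ki_patlak = vapply(pat, function(p) p$Ki, 0),
      CMRGlu = vapply(pat, function(p) p$CMRGlu, 0),
      CV_Ki_pct = vapply(fits, function(f) f$cv_ki, 0),
      WRSS = vapply(fits, function(f) f$wrss, 0),
      WRSS_0_3min = vapply(fits, function(f) f$wrss_0_3min, 0))
    list(
      provenance = list(
        config = unclass(config),
        mode = mode, R_used = R_used,
        tissue_bounds = tissue_bounds(),
        standalone_bounds = std_bounds(),
        n_frames = length(inputs$wb_tac$grid),
        anchors = inputs$anchors,
        package_version = as.character(utils::packageVersion("mdifkit"))),
      sime = list(cost = sres$cost, converged = sres$converged,
                  n_parameters = sres$n_parameters,
                  anchor_pct_difference = sres$anchor_residuals,
                  wb_params = if (mode == "mdif")
                    unclass(sres$wb_params)[1:4] else NULL,
                  idif_params = if (mode == "idif")
                    unclass(sres$feng) else NULL),
      regions = regions,
      input_comparison = cmp)
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    utils::write.csv(report$regions, file.path(out_dir, "regions.csv"),
                     row.names = FALSE)
    writeLines(pipeline_summary(report), file.path(out_dir, "summary.txt"))
    return(invisible(report))
  }
  report
}

pipeline_summary <- function(report) {
  c(sprintf("mdifkit pipeline report (mode %s, R = %g, seed = %d)",
            report$provenance$mode, report$provenance$R_used,
            report$provenance$config$seed),
    sprintf("SIME: cost %.6g, %d parameters, converged %s",
            report$sime$cost, report$sime$n_parameters,
            report$sime$converged),
    sprintf("anchor %% difference: %s",
            paste(sprintf("%.2f", report$sime$anchor_pct_difference),
                  collapse = ", ")),
    "",
    utils::capture.output(print(report$regions, digits = 4)),
    if (!is.null(report$input_comparison))
      c("", sprintf("input-function AUC ratio (recovered/true): %.4f; %% difference %.2f",
                    report$input_comparison$overall_ratio,
                    report$input_comparison$percent_difference)))
}
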