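# Configuration loading/validation, result serialization and run
# provenance. Configs are YAML with explicit unit suffixes in key names to
# prevent unit drift; unknown keys are hard errors.

.CONFIG_SCHEMA <- list(
  kinetics = c("k_on_per_nM_h", "k_off_per_h", "k_int_per_h", "k_rel_per_h",
               "mu_dec_per_h", "provenance"),
  receptors = c("R_cell_nM", "provenance"),
  svalues = c("S_m_Gy_per_decay", "S_cs_Gy_per_decay", "S_cy_Gy_per_decay",
              "provenance"),
  radiobiology = c("k_ssb_per_Gy", "lambda_ssb_per_h", "k_dsb_per_Gy",
                   "lambda_f_per_h", "lambda_s_per_h", "lambda_m_per_h",
                   "p_c", "p_HR", "provenance"),
  survival = c("a_per_h", "b_per_h", "a0_per_h", "b0_per_h", "a1_per_h",
               "b1_per_h", "psi_per_dsb", "phi_per_dsb",
               "dsb_checkpoint_cap", "apop_phases", "mitot_phases",
               "provenance"),
  cellcycle = c("mu_gr_per_h", "proportions", "n_starts", "provenance"),
  protocol = c("A0_Bq", "molar_activity_Bq_per_mol", "volume_L", "n_seeded",
               "seeding_offset_h", "rpt_exposure_h", "parpi_exposure_h",
               "endpoint_h", "ebrt_dose_Gy"),
  parpi = c("mode", "mu_parpi", "lambda_ssb_override_per_h",
            "lambda_red_per_ssb", "decay_form", "provenance"),
  solver = c("method", "rtol", "atol", "dt_out_h"),
  options = c("receptor_literal", "s_induction_literal",
              "mitosis_halves_lesions", "eps_sprog"),
  seed = NULL)

.require_keys <- function(block, keys, block_name) {
  missing <- setdiff(keys, names(block))
  if (length(missing))
    stop("config: block '", block_name, "' is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown blocks or keys, fills
#' defaults (24 start points, 11:8:4:1 phase proportions, checkpoint cap
#' 20, lsoda with rtol 1e-8/atol 1e-10), and builds the model and protocol
#' objects, running every constructor-level invariant check. Each violation
#' names the offending key.
#'
#' @param path path to the YAML configuration file.
#' @return An object of class `rpt_run_config`: list with `model`
#'   ([rpt_model()]), `protocol` ([protocol()]), `seed`, and `raw` (the
#'   parsed YAML).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config: file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(.CONFIG_SCHEMA))
  if (length(unknown))
    stop("config: unknown block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (blk in setdiff(names(raw), "seed")) {
    bad <- setdiff(names(raw[[blk]]), .CONFIG_SCHEMA[[blk]])
    if (length(bad))
      stop("config: unknown key(s) in block '", blk, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  for (blk in c("kinetics", "receptors", "svalues", "radiobiology",
                "survival", "cellcycle", "protocol"))
    if (is.null(raw[[blk]]))
      stop("config: required block '", blk, "' is missing; expected keys: ",
           paste(setdiff(.CONFIG_SCHEMA[[blk]], "provenance"),
                 collapse = ", "), call. = FALSE)

  k <- raw$kinetics
  .require_keys(k, c("k_on_per_nM_h", "k_off_per_h", "k_int_per_h",
                     "k_rel_per_h", "mu_dec_per_h"), "kinetics")
  kin <- kinetic_params(k$k_on_per_nM_h, k$k_off_per_h, k$k_int_per_h,
                        k$k_rel_per_h, k$mu_dec_per_h)
  .require_keys(raw$receptors, "R_cell_nM", "receptors")
  rec <- receptor_model(raw$receptors$R_cell_nM)
  s <- raw$svalues
  .require_keys(s, c("S_m_Gy_per_decay", "S_cs_Gy_per_decay",
                     "S_cy_Gy_per_decay"), "svalues")
  sv <- svalue_set(s$S_m_Gy_per_decay, s$S_cs_Gy_per_decay,
                   s$S_cy_Gy_per_decay)
  r <- raw$radiobiology
  .require_keys(r, c("k_ssb_per_Gy", "lambda_ssb_per_h", "k_dsb_per_Gy",
                     "lambda_f_per_h", "lambda_s_per_h", "lambda_m_per_h",
                     "p_c"), "radiobiology")
  rep_par <- repair_params(r$k_ssb_per_Gy, r$lambda_ssb_per_h,
                           r$k_dsb_per_Gy, r$lambda_f_per_h,
                           r$lambda_s_per_h, r$lambda_m_per_h,
                           r$p_c, if (is.null(r$p_HR)) 1 else r$p_HR)
  su <- raw$survival
  .require_keys(su, c("a_per_h", "b_per_h", "psi_per_dsb", "phi_per_dsb"),
                "survival")
  coef_vec <- function(x) if (is.list(x)) unlist(x) else x
  sargs <- list(a = coef_vec(su$a_per_h), b = coef_vec(su$b_per_h),
                psi = su$psi_per_dsb, phi = su$phi_per_dsb)
  for (nm in c("a0", "b0", "a1", "b1"))
    if (!is.null(su[[paste0(nm, "_per_h")]]))
      sargs[[nm]] <- su[[paste0(nm, "_per_h")]]
  if (!is.null(su$dsb_checkpoint_cap))
    sargs$dsb_checkpoint_cap <- su$dsb_checkpoint_cap
  if (!is.null(su$apop_phases)) sargs$apop_phases <- su$apop_phases
  if (!is.null(su$mitot_phases)) sargs$mitot_phases <- su$mitot_phases
  spar <- do.call(survival_params, sargs)
  cc <- raw$cellcycle
  .require_keys(cc, "mu_gr_per_h", "cellcycle")
  ccfg <- cellcycle_config(
    cc$mu_gr_per_h,
    proportions = if (is.null(cc$proportions)) c(11, 8, 4, 1)
                  else unlist(cc$proportions),
    n_starts = if (is.null(cc$n_starts)) 24 else cc$n_starts)
  pp <- raw$parpi
  parpi <- if (is.null(pp)) parpi_model("none") else {
    args <- list(mode = if (is.null(pp$mode)) "none" else pp$mode)
    if (!is.null(pp$mu_parpi)) args$mu_parpi <- pp$mu_parpi
    if (!is.null(pp$lambda_ssb_override_per_h))
      args$lambda_ssb_override <- pp$lambda_ssb_override_per_h
    if (!is.null(pp$lambda_red_per_ssb))
      args$lambda_red <- pp$lambda_red_per_ssb
    if (!is.null(pp$decay_form)) args$decay_form <- pp$decay_form
    do.call(parpi_model, args)
  }
  pr <- raw$protocol
  .require_keys(pr, c("A0_Bq", "molar_activity_Bq_per_mol", "volume_L"),
                "protocol")
  pargs <- list(A0 = pr$A0_Bq,
                molar_activity = pr$molar_activity_Bq_per_mol,
                volume = pr$volume_L)
  map <- c(n_seeded = "n_seeded", seeding_offset = "seeding_offset_h",
           rpt_exposure = "rpt_exposure_h",
           parpi_exposure = "parpi_exposure_h", endpoint = "endpoint_h",
           ebrt_dose = "ebrt_dose_Gy")
  for (nm in names(map))
    if (!is.null(pr[[map[[nm]]]])) pargs[[nm]] <- pr[[map[[nm]]]]
  proto <- do.call(protocol, pargs)
  solver <- raw$solver
  if (!is.null(solver)) {
    names(solver)[names(solver) == "dt_out_h"] <- "dt_out"
  } else solver <- list()
  options <- if (is.null(raw$options)) list() else raw$options
  model <- rpt_model(kin, rec, sv, rep_par, spar, ccfg, parpi,
                     solver = solver, options = options)
  structure(list(model = model, protocol = proto,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 raw = raw, path = path),
            class = "rpt_run_config")
}

#' Dump a run configuration back to YAML
#'
#' Writes the parsed configuration back out; `load_config()` of the dump
#' reproduces the same model (round-trip idempotence).
#'
#' @param config an `rpt_run_config` from [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' Export simulation results with a run record
#'
#' Writes ensemble and/or trajectory tables as CSV plus a JSON run record
#' (configuration hash, seed, solver settings, package version, output
#' manifest). Identical configuration and seed reproduce the CSVs
#' bit-identically for deterministic operations.
#'
#' @param result an `rpt_ensemble` or `rpt_trajectory` object.
#' @param out_prefix path prefix for the output files.
#' @param config optional `rpt_run_config` recorded for provenance.
#' @param seed seed recorded for provenance.
#' @return Invisible list with `files` (manifest) and `record` (run
#'   record), also written to `<out_prefix>_run.json`.
#' @export
export_results <- function(result, out_prefix, config = NULL, seed = NULL) {
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fmt <- function(df) {
    names(df)[names(df) == "D"] <- "D_Gy"
    df
  }
  if (inherits(result, "rpt_ensemble")) {
    f <- paste0(out_prefix, "_ensemble.csv")
    utils::write.csv(fmt(result$grid), f, row.names = FALSE)
    files <- c(files, f)
    if (!is.null(result$trajectories)) {
      for (i in seq_along(result$trajectories)) {
        f <- sprintf("%s_traj_%02d.csv", out_prefix, i - 1L)
        utils::write.csv(fmt(as.data.frame(result$trajectories[[i]])), f,
                         row.names = FALSE)
        files <- c(files, f)
      }
    }
  } else if (inherits(result, "rpt_trajectory")) {
    f <- paste0(out_prefix, "_traj.csv")
    utils::write.csv(fmt(as.data.frame(result)), f, row.names = FALSE)
    files <- c(files, f)
  } else stop("export_results: unsupported result type", call. = FALSE)

  cfg_hash <- if (!is.null(config)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    yaml::write_yaml(config$raw, tmp)
    unname(tools::md5sum(tmp))
  } else NA_character_
  record <- list(
    package = "rptparpi",
    version = as.character(utils::packageVersion("rptparpi")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_hash = cfg_hash,
    solver = if (!is.null(config)) config$model$solver else NULL,
    files = basename(files))
  fjson <- paste0(out_prefix, "_run.json")
  jsonlite::write_json(record, fjson, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(files = c(files, fjson), record = record))
}
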