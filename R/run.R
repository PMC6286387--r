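## Subcommand dispatcher behind the command-line front end
## (inst/cli/dellakit).  Every subcommand returns a machine-readable
## run report; the CLI serializes it as JSON.

SUBCOMMANDS <- c("itc-simulate", "itc-fit", "saxs-simulate",
                 "saxs-guinier", "saxs-kratky", "saxs-pr",
                 "nmr-simulate", "nmr-css", "gf-calibrate",
                 "gf-estimate", "make-fixtures")

arg_num <- function(args, name, default = NULL) {
  if (is.null(args[[name]])) {
    if (is.null(default)) stop("missing required argument --", name)
    return(default)
  }
  v <- suppressWarnings(as.numeric(args[[name]]))
  if (is.na(v)) stop("argument --", name, " must be numeric")
  v
}

arg_chr <- function(args, name, default = NULL) {
  v <- args[[name]]
  if (is.null(v)) {
    if (is.null(default) && !is.null(names(default)))
      stop("missing required argument --", name)
    return(default)
  }
  as.character(v)
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (!length(paths)) return(list())
  md5 <- tools::md5sum(paths)
  mapply(function(p, h) list(path = p, md5 = unname(h)),
         paths, md5, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

new_report <- function(command, parameters, results, inputs = character(),
                       warnings = character()) {
  list(schema_version = 1,
       package = "dellakit",
       package_version = as.character(utils::packageVersion("dellakit")),
       command = command,
       parameters = parameters,
       inputs = file_digest(inputs),
       results = results,
       warnings = warnings)
}

design_from_args <- function(args, default_cell_um) {
  titration_design(
    cell_volume = arg_num(args, "cell-volume-ml", 1.4482) * 1e-3,
    injection_volumes = rep(arg_num(args, "injection-ul", 10) * 1e-6,
                            arg_num(args, "injections", 20)),
    syringe_conc = arg_num(args, "syringe-um", 400) * 1e-6,
    cell_conc = arg_num(args, "cell-um", default_cell_um) * 1e-6,
    temperature_c = arg_num(args, "temp-c", 30))
}

thermo_block <- function(th) {
  list(Kb_per_M = th$Kb, n = th$n, dH_kcal_mol = th$dH,
       dG_kcal_mol = th$dG, mTdS_kcal_mol = th$mTdS,
       temperature_K = th$T_k)
}

parse_segments_arg <- function(txt) {
  ## "39-44:3.5,50-69:3.5" -> data.frame(start, end, offset)
  parts <- strsplit(strsplit(txt, ",")[[1]], "[:\\-]")
  do.call(rbind, lapply(parts, function(p) {
    if (length(p) != 3) stop("bad --segments element; expected start-end:offset")
    data.frame(start = as.integer(p[1]), end = as.integer(p[2]),
               offset = as.numeric(p[3]))
  }))
}

parse_range_arg <- function(txt) {
  if (is.null(txt) || !nzchar(txt)) return(integer())
  p <- as.integer(strsplit(txt, "-")[[1]])
  p[1]:p[2]
}

#' Run an analysis subcommand
#'
#' Dispatcher behind the `dellakit` command line.  Subcommands:
#' `itc-simulate`, `itc-fit`, `saxs-simulate`, `saxs-guinier`,
#' `saxs-kratky`, `saxs-pr`, `nmr-simulate`, `nmr-css`, `gf-calibrate`,
#' `gf-estimate`, `make-fixtures`.  Given the same inputs and `--seed`,
#' output is deterministic.
#'
#' @param subcommand one of the subcommands above.
#' @param args named list of argument values, names as on the command
#'   line without the `--` prefix (e.g. `list(model = "one-site",
#'   kb = 2.9e7)`).
#' @return A run report: a named list with `schema_version`, `package`,
#'   `package_version`, `command`, `parameters`, `inputs` (file
#'   digests), `results` and `warnings`; serialize with
#'   [write_report()].
#' @export
run <- function(subcommand, args = list()) {
  if (!subcommand %in% SUBCOMMANDS)
    stop("unknown subcommand '", subcommand, "'; expected one of: ",
         paste(SUBCOMMANDS, collapse = ", "))
  if (!is.null(args$seed)) set.seed(as.integer(arg_num(args, "seed")))
  warn <- character()
  withCallingHandlers(
    switch(subcommand,
      "itc-simulate" = run_itc_simulate(args),
      "itc-fit" = run_itc_fit(args),
      "saxs-simulate" = run_saxs_simulate(args),
      "saxs-guinier" = run_saxs_guinier(args),
      "saxs-kratky" = run_saxs_kratky(args),
      "saxs-pr" = run_saxs_pr(args),
      "nmr-simulate" = run_nmr_simulate(args),
      "nmr-css" = run_nmr_css(args),
      "gf-calibrate" = run_gf_calibrate(args),
      "gf-estimate" = run_gf_estimate(args),
      "make-fixtures" = run_make_fixtures(args)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }) -> rep
  rep$warnings <- c(rep$warnings, warn)
  rep
}

run_itc_simulate <- function(args) {
  model <- match.arg(arg_chr(args, "model", "one-site"),
                     c("one-site", "dilution-dimer"))
  noise <- arg_num(args, "noise", 0)
  if (model == "one-site") {
    design <- design_from_args(args, default_cell_um = 50)
    tg <- simulate_one_site(design, Kb = arg_num(args, "kb"),
                            n = arg_num(args, "n", 1),
                            dH = arg_num(args, "dh"), noise_sd = noise)
    pars <- list(model = model, Kb = arg_num(args, "kb"),
                 n = arg_num(args, "n", 1), dH = arg_num(args, "dh"))
  } else {
    design <- design_from_args(args, default_cell_um = 0)
    tg <- simulate_dilution_dimer(design,
                                  K_dim = arg_num(args, "kdim") * 1e-3,
                                  dH_dim = arg_num(args, "dhdim"),
                                  noise_sd = noise)
    pars <- list(model = model, K_dim_mM = arg_num(args, "kdim"),
                 dH_dim = arg_num(args, "dhdim"))
  }
  out <- arg_chr(args, "out")
  if (!is.null(out)) write_itc_csv(tg, out)
  new_report("itc-simulate", c(pars, list(noise_ucal = noise)),
             list(n_injections = length(tg$heats_ucal),
                  heats_kcal_per_mol = tg$heats_norm,
                  out = out))
}

run_itc_fit <- function(args) {
  path <- arg_chr(args, "file")
  if (is.null(path)) stop("missing required argument --file")
  tg <- read_itc_csv(path)
  blank_path <- arg_chr(args, "blank")
  if (!is.null(blank_path))
    tg <- subtract_dilution(tg, read_itc_csv(blank_path))
  model <- arg_chr(args, "model",
                   if (tg$design$cell_conc > 0) "one-site"
                   else "dilution-dimer")
  if (model == "one-site") {
    fit <- fit_one_site(tg)
    res <- list(model = model, outcome = fit$outcome,
                residual_rms_kcal_mol = fit$residual_rms,
                c_value = fit$c_value)
    if (fit$outcome == "ok") res <- c(res, thermo_block(fit$thermo))
  } else {
    fit <- fit_dilution_dimer(tg)
    res <- list(model = model, outcome = fit$outcome,
                K_dim_mM = fit$K_dim * 1e3,
                dH_dim_kcal_mol_dimer = fit$dH_dim,
                residual_rms_kcal_mol = fit$residual_rms)
  }
  new_report("itc-fit", list(model = model, file = path),
             res, inputs = c(path, blank_path))
}

run_saxs_simulate <- function(args) {
  model <- match.arg(arg_chr(args, "model", "sphere"), c("sphere", "debye"))
  gen <- if (model == "sphere") synth_sphere else synth_debye_chain
  prof <- gen(Rg = arg_num(args, "rg"), I0 = arg_num(args, "i0", 1),
              noise = arg_num(args, "noise", 0))
  out <- arg_chr(args, "out")
  if (!is.null(out)) write_saxs_dat(prof, out)
  new_report("saxs-simulate",
             list(model = model, Rg = arg_num(args, "rg"),
                  noise = arg_num(args, "noise", 0)),
             list(n_points = length(prof$q), out = out))
}

run_saxs_guinier <- function(args) {
  path <- arg_chr(args, "file")
  if (is.null(path)) stop("missing required argument --file")
  g <- guinier_fit(read_saxs_dat(path),
                   qRg_max = arg_num(args, "qrg-max", 1.3))
  new_report("saxs-guinier",
             list(file = path, qRg_max = arg_num(args, "qrg-max", 1.3)),
             list(flag = g$flag, Rg_A = g$Rg, Rg_se_A = g$Rg_se,
                  I0 = g$I0, q_range = g$q_range_used,
                  linearity_r2 = g$linearity_r2, n_points = g$n_points),
             inputs = path)
}

run_saxs_kratky <- function(args) {
  path <- arg_chr(args, "file")
  if (is.null(path)) stop("missing required argument --file")
  prof <- read_saxs_dat(path)
  g <- guinier_fit(prof, qRg_max = arg_num(args, "qrg-max", 1.3))
  k <- kratky_classify(prof, g)
  new_report("saxs-kratky", list(file = path),
             list(shape_class = k$shape_class, q_peak_per_A = k$q_peak,
                  peak_height = k$peak_height,
                  peak_height_expected = k$peak_height_expected,
                  plateau_level = k$plateau_level,
                  Rg_from_peak_A = k$Rg_from_peak),
             inputs = path)
}

run_saxs_pr <- function(args) {
  path <- arg_chr(args, "file")
  if (is.null(path)) stop("missing required argument --file")
  pr <- pr_transform(read_saxs_dat(path), Dmax = arg_num(args, "dmax"))
  new_report("saxs-pr", list(file = path, Dmax_A = arg_num(args, "dmax")),
             list(Rg_from_pr_A = pr$Rg_from_pr, I0_from_pr = pr$I0_from_pr,
                  r_A = pr$r, p = pr$p, condition = pr$condition),
             inputs = path)
}

run_nmr_simulate <- function(args) {
  segs <- if (!is.null(args$segments)) parse_segments_arg(args$segments)
          else NULL
  obs <- simulate_shift_table(segments = segs,
                              noise_sd = arg_num(args, "noise", 0),
                              missing = parse_range_arg(args$missing))
  out <- arg_chr(args, "out")
  if (!is.null(out)) write_shift_tsv(obs, out)
  coil_out <- arg_chr(args, "out-coil")
  if (!is.null(coil_out))
    write_shift_tsv(simulate_shift_table(segments = NULL), coil_out)
  new_report("nmr-simulate",
             list(segments = arg_chr(args, "segments", ""),
                  noise_ppm = arg_num(args, "noise", 0),
                  missing = arg_chr(args, "missing", "")),
             list(n_observed = sum(obs$observed), out = out,
                  out_coil = coil_out))
}

run_nmr_css <- function(args) {
  obs_path <- arg_chr(args, "observed")
  coil_path <- arg_chr(args, "coil")
  if (is.null(obs_path) || is.null(coil_path))
    stop("nmr-css needs --observed and --coil shift tables")
  coil <- read_shift_tsv(coil_path)
  rng <- range(coil$residue_number)
  types <- stats::setNames(coil$residue_type,
                           coil$residue_number)
  obs <- read_shift_tsv(obs_path, full_range = rng[1]:rng[2],
                        residue_types = types)
  prof <- call_helices(secondary_shifts(obs, coil),
                       stable_threshold = arg_num(args, "stable", 3.0),
                       marginal_threshold = arg_num(args, "marginal", 2.0),
                       min_len = arg_num(args, "min-len", 4),
                       max_gap = arg_num(args, "max-gap", 1))
  segs <- helix_segments(prof)
  new_report("nmr-css",
             list(stable_ppm = arg_num(args, "stable", 3.0),
                  marginal_ppm = arg_num(args, "marginal", 2.0)),
             list(segments = segs,
                  state = classify_state(prof),
                  missing_residues = attr(prof, "missing_residues")),
             inputs = c(obs_path, coil_path))
}

run_gf_calibrate <- function(args) {
  path <- arg_chr(args, "standards")
  if (is.null(path)) stop("missing required argument --standards")
  df <- read_gf_csv(path)
  cal <- fit_calibration(data.frame(elution_volume = df$elution_volume_ml,
                                    mw = df$mw_kda))
  new_report("gf-calibrate", list(standards = path),
             list(slope_log10kDa_per_ml = cal$slope,
                  intercept_log10kDa = cal$intercept,
                  r_squared = cal$r_squared,
                  volume_range_ml = cal$volume_range),
             inputs = path)
}

run_gf_estimate <- function(args) {
  path <- arg_chr(args, "standards")
  if (is.null(path)) stop("missing required argument --standards")
  df <- read_gf_csv(path)
  cal <- fit_calibration(data.frame(elution_volume = df$elution_volume_ml,
                                    mw = df$mw_kda))
  expected <- if (!is.null(args[["expected-complex-kda"]]))
    arg_num(args, "expected-complex-kda") else NULL
  st <- estimate_state(arg_num(args, "volume"), cal,
                       theoretical_mw = arg_num(args, "theoretical-kda"),
                       expected_complex_mw = expected)
  new_report("gf-estimate",
             list(volume_ml = arg_num(args, "volume"),
                  theoretical_kDa = arg_num(args, "theoretical-kda"),
                  expected_complex_kDa = expected),
             list(apparent_mw_kDa = st$apparent_mw, ratio = st$ratio,
                  state_call = st$state_call, annotation = st$annotation,
                  complex_deviation = st$complex_deviation,
                  extrapolated = st$extrapolated),
             inputs = path)
}

run_make_fixtures <- function(args) {
  out <- arg_chr(args, "out")
  if (is.null(out)) stop("missing required argument --out")
  bundle <- match.arg(arg_chr(args, "bundle", "paper-defaults"),
                      "paper-defaults")
  res <- make_fixture_bundle(out, seed = arg_num(args, "seed", 1))
  new_report("make-fixtures", list(bundle = bundle, out = out),
             list(modalities = names(res),
                  files = unname(unlist(lapply(res, `[[`, "files")))))
}

#' Serialize a run report as JSON
#'
#' @param report a report from [run()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Parse a run report written by [write_report()]
#'
#' @param path JSON path.
#' @return The report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
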