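## Seeded scenario generator: writes standard-format fixture files plus
## a truth manifest for every modality, so the full pipeline runs with
## no instrument data.

MODALITIES <- c("itc-one-site", "itc-dilution", "saxs-sphere",
                "saxs-debye", "nmr-free", "nmr-bound", "gf")

## One pseudo-random stream per modality, derived from the master seed,
## so adding a modality never perturbs existing fixtures.
modality_seed <- function(seed, modality) {
  idx <- match(modality, MODALITIES)
  as.integer((as.numeric(seed) * 131 + idx * 9973) %% 2147483647)
}

#' Default ground-truth parameters per modality
#'
#' The headline study conditions: the tight-binder titration
#' (Kb = 2.9e7 M^-1, n = 1.06, dH = -6.9 kcal/mol at the standard
#' 20 x 10 ul design), the dimer dilution (K_dim = 1.6 mM,
#' dH_dim = -66 kcal/mol), globular and unfolded scatterers
#' (Rg = 31.3 and 30.4 A), bound- and free-state helix patterns, and a
#' log-linear SEC column.
#'
#' @param modality one of `r paste(MODALITIES, collapse=", ")`.
#' @return Named list of truth parameters.
#' @export
default_truth <- function(modality) {
  switch(modality,
    "itc-one-site" = list(Kb = 2.9e7, n = 1.06, dH = -6.9),
    "itc-dilution" = list(K_dim = 1.6e-3, dH_dim = -66),
    "saxs-sphere"  = list(Rg = 31.3, I0 = 1),
    "saxs-debye"   = list(Rg = 30.4, I0 = 1),
    "nmr-bound"    = list(segments = data.frame(
                            start = c(39, 50, 81, 99),
                            end = c(44, 69, 88, 109),
                            offset = 3.5),
                          missing = 92:95),
    "nmr-free"     = list(segments = data.frame(
                            start = c(39, 55), end = c(44, 62),
                            offset = 2.0),
                          missing = integer()),
    "gf"           = list(slope = -0.25, intercept = 4.951,
                          standards_mw = c(670, 158, 44, 17, 1.35),
                          sample_mw = c(60.0, 91.8),
                          sample_theoretical = c(29.3, 89.3)),
    stop("unknown modality: ", modality))
}

#' Scenario configuration
#'
#' @param seed master integer seed; the per-modality stream is derived
#'   from it.
#' @param modality one of the supported modalities (see
#'   [default_truth()]).
#' @param truth truth parameters; defaults per modality.
#' @param noise modality-appropriate noise level (ucal for ITC,
#'   relative for SAXS, ppm for NMR, ml for SEC volumes); 0 = noiseless.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(seed, modality, truth = default_truth(modality),
                            noise = 0) {
  modality <- match.arg(modality, MODALITIES)
  structure(list(seed = as.integer(seed), modality = modality,
                 truth = truth, noise = noise),
            class = "scenario_config")
}

#' Generate fixture files for a scenario
#'
#' Writes the modality's standard file format into `out_dir` plus a
#' `truth.json` manifest of the generating parameters.  Identical
#' configurations produce byte-identical output.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `files` (paths written) and `truth`.
#' @export
make_scenario <- function(config, out_dir) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(modality_seed(config$seed, config$modality))
  tr <- config$truth
  noise <- config$noise
  files <- character()
  pth <- function(f) file.path(out_dir, f)

  if (config$modality == "itc-one-site") {
    tg <- simulate_one_site(titration_design(), Kb = tr$Kb, n = tr$n,
                            dH = tr$dH, noise_sd = noise)
    files <- c(write_itc_csv(tg, pth("itc_one_site.csv")),
               design_sidecar(pth("itc_one_site.csv")))
  } else if (config$modality == "itc-dilution") {
    tg <- simulate_dilution_dimer(titration_design(cell_conc = 0),
                                  K_dim = tr$K_dim, dH_dim = tr$dH_dim,
                                  noise_sd = noise)
    files <- c(write_itc_csv(tg, pth("itc_dilution.csv")),
               design_sidecar(pth("itc_dilution.csv")))
  } else if (config$modality %in% c("saxs-sphere", "saxs-debye")) {
    gen <- if (config$modality == "saxs-sphere") synth_sphere
           else synth_debye_chain
    prof <- gen(Rg = tr$Rg, I0 = tr$I0, noise = noise)
    f <- pth(paste0(sub("saxs-", "", config$modality), ".dat"))
    files <- write_saxs_dat(prof, f)
  } else if (config$modality %in% c("nmr-free", "nmr-bound")) {
    obs <- simulate_shift_table(segments = tr$segments, noise_sd = noise,
                                missing = tr$missing)
    coil <- simulate_shift_table(segments = NULL)
    files <- c(write_shift_tsv(obs, pth("observed_ca.tsv")),
               write_shift_tsv(coil, pth("random_coil_ca.tsv")))
  } else if (config$modality == "gf") {
    vol_for <- function(mw) (log10(mw) - tr$intercept) / tr$slope
    std_v <- vol_for(tr$standards_mw)
    if (noise > 0) std_v <- std_v + stats::rnorm(length(std_v), sd = noise)
    standards <- data.frame(name = paste0("std", seq_along(tr$standards_mw)),
                            elution_volume_ml = std_v,
                            mw_kda = tr$standards_mw)
    samples <- data.frame(name = paste0("sample", seq_along(tr$sample_mw)),
                          elution_volume_ml = vol_for(tr$sample_mw),
                          mw_kda = tr$sample_theoretical)
    files <- c(write_gf_csv(standards, pth("gf_standards.csv")),
               write_gf_csv(samples, pth("gf_samples.csv")))
  }

  truth_out <- tr
  if (!is.null(truth_out$segments))
    truth_out$segments <- as.list(as.data.frame(truth_out$segments))
  manifest <- list(modality = config$modality, seed = config$seed,
                   noise = noise, truth = truth_out,
                   files = basename(files))
  jsonlite::write_json(manifest, pth("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(files = c(files, pth("truth.json")), truth = tr))
}

#' Generate the full default fixture bundle
#'
#' One subdirectory per modality under `out_dir`, each holding its
#' standard-format data plus `truth.json`; truths are the headline
#' study conditions of [default_truth()].
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param noise named numeric vector of per-modality noise levels;
#'   unnamed modalities are noiseless.
#' @return Invisibly, named list of per-modality [make_scenario()]
#'   results.
#' @export
make_fixture_bundle <- function(out_dir, seed = 1, noise = c()) {
  res <- lapply(MODALITIES, function(m) {
    nz <- if (m %in% names(noise)) noise[[m]] else 0
    make_scenario(scenario_config(seed, m, noise = nz),
                  file.path(out_dir, m))
  })
  names(res) <- MODALITIES
  invisible(res)
}
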