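# Pipeline orchestration and file I/O: ties simulation, inversion,
# regional summarization, screening and the two prediction models into a
# single seeded, reproducible run.

#' Invert one measurement bundle for composition
#'
#' The full per-site inversion chain: frequency-domain inversion at each
#' laser wavelength, power-law fit of the recovered scattering, broadband
#' absorption recovery from the CW spectrum anchored on the
#' frequency-domain absorption values, and non-negative spectral
#' decomposition into chromophores.
#'
#' @param fd an \code{fd_measurement}
#' @param cw a \code{cw_spectrum}
#' @param lib extinction library (must cover the CW grid)
#' @return list with \code{chromophores} (\code{chromophore_set}),
#'   \code{scatter} (\code{scatter_params}), \code{optical} (data.frame
#'   wavelength_nm, mua, mus_prime on the CW grid) and \code{anchors}
#'   (per-laser-wavelength inversion results)
#' @export
invert_measurement <- function(fd, cw, lib = nir_extinction_library()) {
  stopifnot(inherits(fd, "fd_measurement"), inherits(cw, "cw_spectrum"))
  inv <- lapply(fd$wavelengths_nm, function(wl) fd_invert(fd, wl))
  anchors <- data.frame(
    wavelength_nm = fd$wavelengths_nm,
    mua = vapply(inv, `[[`, numeric(1), "mua"),
    mus_prime = vapply(inv, `[[`, numeric(1), "mus_prime"))
  scatter <- fit_powerlaw(anchors$wavelength_nm, anchors$mus_prime)
  mua_bb <- broadband_mua(cw, scatter, anchors)
  chrom <- decompose_mua(as.numeric(mua_bb), lib, cw$wavelength_nm)
  list(chromophores = chrom, scatter = scatter,
       optical = data.frame(wavelength_nm = cw$wavelength_nm,
                            mua = as.numeric(mua_bb),
                            mus_prime = powerlaw_mus(scatter,
                                                     cw$wavelength_nm)),
       anchors = anchors)
}

#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed); \code{NULL} keeps
#'   everything in memory
#' @param n cohort size for the simulation stage
#' @param seed integer master seed, recorded in every output
#' @param split_fraction training fraction for the 80/20 split
#' @param n_tests Bonferroni family size for the screening stage
#' @param off_scale reporting scale for OFF/OLF
#' @param endmembers,noise,instrument generator settings
#' @param inputs optional list of pre-computed stage inputs
#'   (\code{sites}, \code{satt}, \code{dxa}); supplied stages skip the
#'   simulator
#' @return validated list of class \code{pipeline_config}
#' @export
pipeline_config <- function(out_dir = NULL, n = 99, seed = 20220608L,
                            split_fraction = 0.8, n_tests = 7,
                            off_scale = c("percent", "fraction"),
                            endmembers = endmember_pair(),
                            noise = cohort_noise(),
                            instrument = instrument_config(),
                            inputs = NULL) {
  off_scale <- match.arg(off_scale)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  structure(list(out_dir = out_dir, n = n, seed = as.integer(seed),
                 split_fraction = split_fraction, n_tests = n_tests,
                 off_scale = off_scale, endmembers = endmembers,
                 noise = noise, instrument = instrument, inputs = inputs),
            class = "pipeline_config")
}

# small stable polynomial hash of the deparsed configuration, for run logging
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[setdiff(names(config),
                                                  "out_dir")]),
                           collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or ingest pre-computed tables), summarize sites into
#' the four anatomical regions, screen the seven optical parameters
#' against SATT, fit and evaluate the exponential OFF-SATT model on an
#' 80/20 split, and fit and evaluate the whole-body fat\%/LST\% models.
#' Reference endmember OFF/OLF values are carried through as a worked
#' example. All randomness derives from \code{config$seed}; outputs are
#' reproducible byte-for-byte.
#'
#' @param config a \code{pipeline_config}
#' @return report list (also written as JSON/CSV under
#'   \code{config$out_dir} when set)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) message("[dosicomp] ", sprintf(...))
  log_msg("run: seed %d, config hash %s, version %s", config$seed,
          config_hash(config),
          as.character(utils::packageVersion("dosicomp")))

  inputs <- config$inputs
  if (is.null(inputs)) {
    cohort <- generate_cohort(config$n, seed = config$seed,
                              endmembers = config$endmembers,
                              noise = config$noise)
    inputs <- cohort[c("sites", "satt", "dxa")]
    log_msg("simulate: %d participants", config$n)
  } else {
    log_msg("simulate: skipped (pre-computed inputs)")
  }

  regions <- summarize_regions(inputs$sites)
  quad <- regions[regions$region == "quadriceps", , drop = FALSE]
  quad_satt <- stats::aggregate(inputs$satt["satt_cm"],
                                by = inputs$satt["participant_id"],
                                FUN = mean)
  quad$satt_cm <- quad_satt$satt_cm[match(quad$participant_id,
                                          quad_satt$participant_id)]
  log_msg("summarize: %d region rows", nrow(regions))

  screen <- screen_parameters(quad, target = "satt_cm",
                              n_tests = config$n_tests)
  log_msg("screen: retained %s",
          paste(screen$parameter[screen$retained], collapse = ", "))

  split <- split_cohort(quad$participant_id, config$split_fraction,
                        seed = config$seed)
  tr <- quad$participant_id %in% split$train
  satt_fit <- fit_satt(quad$off[tr] / 100, quad$satt_cm[tr])
  te <- !tr
  satt_ba <- bland_altman(predict_satt(satt_fit, quad$off[te] / 100),
                          quad$satt_cm[te])
  log_msg("fit-satt: a = %.4g, b = %.4g", satt_fit$a_satt, satt_fit$b_satt)

  models <- lapply(c("fat_pct", "lst_pct"), function(tgt) {
    m <- fit_bodycomp(regions, inputs$dxa, tgt, train_ids = split$train)
    list(model = m,
         evaluation = evaluate_bodycomp(m, regions, inputs$dxa,
                                        test_ids = split$test))
  })
  names(models) <- c("fat_pct", "lst_pct")
  log_msg("fit-bodycomp: fat%% bias %.3g, LST%% bias %.3g",
          models$fat_pct$evaluation$bias, models$lst_pct$evaluation$bias)

  em <- config$endmembers
  worked <- data.frame(
    endmember = c("lean", "fat"),
    off = c(compute_off(em$lean$chromophores),
            compute_off(em$fat$chromophores)),
    olf = c(compute_olf(em$lean$chromophores),
            compute_olf(em$fat$chromophores)))

  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("dosicomp")),
    endmember_worked_example = worked,
    screen = screen,
    satt = list(model = unclass(satt_fit)[c("a_satt", "b_satt", "n",
                                            "residual_norm")],
                bland_altman = ba_summary(satt_ba)),
    bodycomp = lapply(models, function(m) {
      list(intercept = m$model$intercept,
           coefficients = as.list(m$model$coefficients),
           n_train = m$model$n,
           bland_altman = ba_summary(m$evaluation))
    }),
    split = split[c("train", "test", "seed")]
  )

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    utils::write.csv(regions, file.path(od, "regions.csv"),
                     row.names = FALSE)
    utils::write.csv(screen, file.path(od, "screen.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg("report written to %s", od)
  }
  invisible(report)
}

ba_summary <- function(ba) {
  unclass(ba)[c("bias", "sd_diff", "loa_low", "loa_high", "n")]
}

#' Write / read the per-replicate site measurement table as CSV
#'
#' Comma-separated, UTF-8, header row, '.' decimal, empty cells for
#' missing values — the schema consumed by \code{summarize_regions}.
#'
#' @param sites site table (see \code{aggregate_region})
#' @param path file path
#' @return \code{read_cohort_csv} returns the validated data.frame
#' @export
write_cohort_csv <- function(sites, path) {
  check_site_table(sites)
  utils::write.csv(sites[site_table_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_site_table(df)
  df
}

#' Serialize fitted models as JSON
#'
#' @param model a \code{satt_model} or \code{bodycomp_model}
#' @param path file path
#' @return \code{read_model_json} returns the model object
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "satt_model")) {
    obj <- c(type = "satt_model",
             unclass(model)[c("a_satt", "b_satt", "n", "residual_norm")])
  } else if (inherits(model, "bodycomp_model")) {
    obj <- list(type = "bodycomp_model", target = model$target,
                predictor = model$predictor, intercept = model$intercept,
                coefficients = as.list(model$coefficients),
                train_ids = model$train_ids, n = model$n,
                sigma = model$sigma)
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "satt_model")) {
    satt_model(obj$a_satt, obj$b_satt,
               n = if (is.null(obj$n)) NA_integer_ else obj$n,
               residual_norm = if (is.null(obj$residual_norm)) NA_real_
                               else obj$residual_norm)
  } else if (identical(obj$type, "bodycomp_model")) {
    structure(list(target = obj$target, predictor = obj$predictor,
                   intercept = obj$intercept,
                   coefficients = unlist(obj$coefficients)[region_names],
                   train_ids = obj$train_ids, n = obj$n,
                   sigma = obj$sigma),
              class = "bodycomp_model")
  } else {
    stop("unrecognized model JSON", call. = FALSE)
  }
}
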