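## File formats: long-format time-series CSV, titration CSV, FASTA strand
## records, flat key = value run configuration, and JSON reports.

#' Default run configuration
#'
#' Flat named list of every tunable parameter with its module default:
#' energy-model terms (`energy.*`), kinetic parameters (`rate.*`), reaction
#' composition (`system.*`), observation noise (`noise.sigma_au`), the
#' initial-velocity window (`fit.window_s`), the master `seed` and the
#' `output_dir`.
#'
#' @return Named list of defaults.
#' @export
defaultRunConfig <- function() {
  em <- EnergyModel(); rp <- RateParams(); rs <- ReactionSystem()
  list(
    energy.dg_bp_rna_rna = em@dgBpRnaRna,
    energy.dg_bp_rna_dna = em@dgBpRnaDna,
    energy.dg_toehold_per_nt = em@dgToeholdPerNt,
    energy.ddg_mismatch = em@ddgMismatch,
    energy.temperature_K = em@temperatureK,
    rate.k_max = rp@kMax,
    rate.per_nt_factor = rp@perNtFactor,
    rate.n_sat_5p = rp@nSat5p,
    rate.dir_offset_3p = rp@dirOffset3p,
    rate.alpha_max = rp@alphaMax,
    rate.d_star = rp@dStar,
    rate.beta_max = rp@betaMax,
    rate.lambda_m = rp@lambdaM,
    rate.gamma_ds = rp@gammaDs,
    rate.k_rev_mode = rp@kRevMode,
    system.c_complex0 = rs@cComplex0,
    system.c_activator0 = rs@cActivator0,
    system.c_reporter0 = rs@cReporter0,
    system.e_background = rs@eBackground,
    system.k_cat = rs@kCat,
    system.k_m = rs@kM,
    system.era_ratio = rs@eraRatio,
    system.temperature_K = rs@temperatureK,
    noise.sigma_au = 0.18,
    fit.window_s = 600,
    seed = 1L,
    output_dir = "."
  )
}

#' Read a flat key = value run configuration
#'
#' One `key = value` pair per line; blank lines and `#` comments are ignored.
#' Unknown keys are rejected by name; keys absent from the file keep their
#' module default.
#'
#' @param path Path to the config file.
#' @return Named list: [defaultRunConfig()] overridden by the file.
#' @export
readRunConfig <- function(path) {
  defaults <- defaultRunConfig()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults))
      stop("unknown config key: '", key, "'")
    cfg[[key]] <- if (is.numeric(defaults[[key]])) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("config key '", key, "' expects a number, got '",
                           val, "'")
      num
    } else val
  }
  cfg
}

#' Build model objects from a run configuration
#'
#' @param cfg Named list as returned by [readRunConfig()].
#' @return [EnergyModel-class], [RateParams-class] or [ReactionSystem-class].
#' @name configObjects
NULL

#' @rdname configObjects
#' @export
configEnergyModel <- function(cfg) {
  EnergyModel(dgBpRnaRna = cfg$energy.dg_bp_rna_rna,
              dgBpRnaDna = cfg$energy.dg_bp_rna_dna,
              dgToeholdPerNt = cfg$energy.dg_toehold_per_nt,
              ddgMismatch = cfg$energy.ddg_mismatch,
              temperatureK = cfg$energy.temperature_K)
}

#' @rdname configObjects
#' @export
configRateParams <- function(cfg) {
  RateParams(kMax = cfg$rate.k_max, perNtFactor = cfg$rate.per_nt_factor,
             nSat5p = cfg$rate.n_sat_5p,
             dirOffset3p = cfg$rate.dir_offset_3p,
             alphaMax = cfg$rate.alpha_max, dStar = cfg$rate.d_star,
             betaMax = cfg$rate.beta_max, lambdaM = cfg$rate.lambda_m,
             gammaDs = cfg$rate.gamma_ds, kRevMode = cfg$rate.k_rev_mode)
}

#' @rdname configObjects
#' @export
configReactionSystem <- function(cfg) {
  ReactionSystem(cComplex0 = cfg$system.c_complex0,
                 cActivator0 = cfg$system.c_activator0,
                 cReporter0 = cfg$system.c_reporter0,
                 eBackground = cfg$system.e_background,
                 kCat = cfg$system.k_cat, kM = cfg$system.k_m,
                 eraRatio = cfg$system.era_ratio,
                 temperatureK = cfg$system.temperature_K)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Read/write long-format fluorescence time-series CSV
#'
#' The long format has required columns `time_s`, `sample_id`, `condition`,
#' `fluorescence_au` and optional `replicate` and `background_au`. Reading
#' groups rows by (`sample_id`, `condition`, `replicate`), sorts each group
#' by time, and returns one [FluorescenceSeries-class] per group with the
#' grouping labels in its metadata; duplicated time points within a group and
#' missing columns are errors. Writing is the exact inverse, so
#' write(read(x)) reproduces the file.
#'
#' @param path CSV path.
#' @return For the reader, a named list of [FluorescenceSeries-class].
#' @export
readTimeseriesCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "sample_id", "condition", "fluorescence_au")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("time-series CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (!"background_au" %in% names(df)) df$background_au <- 0
  key <- interaction(df$sample_id, df$condition, df$replicate, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$time_s), ]
    if (anyDuplicated(g$time_s))
      stop("duplicated (sample, time) row for sample '", g$sample_id[1],
           "' at t = ", g$time_s[anyDuplicated(g$time_s)])
    bg <- unique(g$background_au)
    FluorescenceSeries(g$time_s, g$fluorescence_au,
                       background = if (length(bg) == 1L) bg
                                    else g$background_au,
                       metadata = list(sample_id = g$sample_id[1],
                                       condition = g$condition[1],
                                       replicate = g$replicate[1]))
  })
  out[order(names(out))]
}

#' @rdname readTimeseriesCsv
#' @param seriesList Named or unnamed list of [FluorescenceSeries-class],
#'   each carrying `sample_id`, `condition`, `replicate` metadata.
#' @export
writeTimeseriesCsv <- function(seriesList, path) {
  if (is(seriesList, "FluorescenceSeries")) seriesList <- list(seriesList)
  rows <- lapply(seriesList, function(s) {
    md <- s@metadata
    bg <- if (length(s@background) == 1L)
      rep(s@background, length(s@times)) else s@background
    data.frame(time_s = .fmt(s@times),
               sample_id = md$sample_id %||% "sample",
               condition = md$condition %||% "NA",
               replicate = md$replicate %||% 1L,
               fluorescence_au = .fmt(s@values),
               background_au = .fmt(bg))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a titration CSV
#'
#' Columns `concentration_nM`, `fluorescence_au`, optional `replicate`.
#'
#' @param path CSV path.
#' @return data.frame suitable for [fitCalibration()].
#' @export
readTitrationCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration_nM", "fluorescence_au")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("titration CSV is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read/write FASTA strand records
#'
#' Thin wrappers over Biostrings with U/T normalization according to the
#' declared alphabet: RNA records have any `T` rewritten as `U` and vice
#' versa for DNA.
#'
#' @param path FASTA path.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return [Biostrings::RNAStringSet-class] or
#'   [Biostrings::DNAStringSet-class].
#' @export
readStrandFasta <- function(path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  raw <- Biostrings::readBStringSet(path)
  chr <- toupper(as.character(raw))
  if (alphabet == "RNA")
    Biostrings::RNAStringSet(stats::setNames(gsub("T", "U", chr), names(raw)))
  else
    Biostrings::DNAStringSet(stats::setNames(gsub("U", "T", chr), names(raw)))
}

#' @rdname readStrandFasta
#' @param x An XStringSet (or named character vector) to write.
#' @export
writeStrandFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' JSON reports
#'
#' Serializers for calibration models, Michaelis-Menten fits and duplex
#' layouts, plus the calibration reader used to rehydrate a stored model.
#'
#' @param calib,fit,layout Objects to serialize.
#' @param path JSON path.
#' @return The path, invisibly (readers return the rebuilt object).
#' @name jsonReports
NULL

#' @rdname jsonReports
#' @export
writeCalibrationJson <- function(calib, path) {
  stopifnot(is(calib, "CalibrationModel"))
  jsonlite::write_json(list(m_cl = calib@mCl, m_ucl = calib@mUcl,
                            background = calib@background,
                            r_squared_cl = calib@r2Cl,
                            r_squared_ucl = calib@r2Ucl),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname jsonReports
#' @export
readCalibrationJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  CalibrationModel(mCl = x$m_cl, mUcl = x$m_ucl, background = x$background,
                   r2Cl = x$r_squared_cl %||% NA_real_,
                   r2Ucl = x$r_squared_ucl %||% NA_real_)
}

#' @rdname jsonReports
#' @export
writeMmFitJson <- function(fit, path) {
  stopifnot(is(fit, "MMFit"))
  jsonlite::write_json(list(k_cat_per_s = fit@kCat, K_M_nM = fit@kM,
                            kcat_over_KM_per_M_s = fit@kcatOverKM,
                            E0_nM = fit@e0,
                            se = as.list(fit@se),
                            velocities = fit@velocities),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname jsonReports
#' @export
writeLayoutJson <- function(layout, path) {
  stopifnot(is(layout, "DuplexLayout"))
  jsonlite::write_json(list(
    toehold_direction = layout@toeholdDirection,
    toehold_length_f = layout@toeholdLengthF,
    toehold_length_r = layout@toeholdLengthR,
    bm_length = layout@bmLength,
    bm_start = layout@bmStart,
    spacer_length = layout@spacerLength,
    era_mismatch_distances = layout@eraMismatchDistances,
    activator_mismatch_distances = layout@activatorMismatchDistances,
    ds_activator = layout@dsActivator),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
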