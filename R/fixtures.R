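## Synthetic fixture study: a complete, deterministic bundle of the data
## types the analysis pipeline consumes, generated by the simulator.

.FIXTURE_SPACER <- "ACGUACGUACGUACGUACGUAC"          # 22-nt synthetic spacer
.FIXTURE_SPACER35 <- "ACGUACGUACGUACGUACGUACACGUACGUACGUA"  # 35-nt extension
.CAL_CONCS <- c(31.25, 62.5, 125, 250, 500, 1000, 2000)

#' Generate a synthetic fixture study
#'
#' Writes a deterministic bundle of synthetic data emulating the assay suite:
#' cleaved/uncleaved calibration titrations over the standard 31.25 nM - 2 uM
#' series, toehold-length panels (f = 1..10, both directions),
#' ERA-mismatch and activator-mismatch panels, toehold-exchange panels,
#' Michaelis-Menten titrations at E0 = 1 nM (plus 5 nM for a slow layout),
#' PM/MM/background replicate triplets for DF estimation, and one-pot
#' amplification scenarios. All randomness derives from `seed`, and the same
#' seed yields a byte-identical bundle. A `manifest.json` lists every file
#' with its generating parameters.
#'
#' @param seed Integer master seed.
#' @param dir Output directory (created if missing).
#' @param calib Ground-truth [CalibrationModel-class] used by the observer.
#' @param sigmaAu Observation noise SD, AU.
#' @return Invisibly, the manifest as a list.
#' @export
generateFixtureStudy <- function(seed, dir,
                                 calib = CalibrationModel(0.14466, 0.00007,
                                                          background = 1.0),
                                 sigmaAu = 0.18) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cr <- CrRNASpec(.FIXTURE_SPACER, name = "crRNA22_synthetic")
  cr35 <- CrRNASpec(.FIXTURE_SPACER35, name = "crRNA35_synthetic")
  rp <- RateParams()
  em <- EnergyModel()
  manifest <- list(seed = seed,
                   calibration_truth = list(m_cl = calib@mCl,
                                            m_ucl = calib@mUcl,
                                            background = calib@background,
                                            sigma_au = sigmaAu),
                   files = list())
  nextSeed <- local({i <- 0L; function() {i <<- i + 1L; seed * 1000L + i}})
  addFile <- function(name, params) {
    manifest$files[[name]] <<- params
  }

  ## --- calibration titrations -------------------------------------------
  titrate <- function(slope, label) {
    rows <- do.call(rbind, lapply(1:3, function(rep) {
      noise <- .withSeed(nextSeed(),
                         stats::rnorm(length(.CAL_CONCS), 0, sigmaAu))
      data.frame(concentration_nM = .fmt(.CAL_CONCS),
                 fluorescence_au = .fmt(slope * .CAL_CONCS +
                                          calib@background + noise),
                 replicate = rep)
    }))
    f <- file.path(dir, sprintf("calibration_%s.csv", label))
    utils::write.csv(rows, f, row.names = FALSE, quote = FALSE)
    addFile(basename(f), list(type = "titration", state = label,
                              slope_au_per_nM = if (label == "cleaved")
                                calib@mCl else calib@mUcl,
                              concentrations_nM = .CAL_CONCS,
                              replicates = 3, sigma_au = sigmaAu))
  }
  titrate(calib@mCl, "cleaved")
  titrate(calib@mUcl, "uncleaved")

  ## --- strand designs ----------------------------------------------------
  act <- designActivator(cr)
  eras <- list()
  strands <- c(crRNA22_synthetic = as.character(cr@spacer),
               crRNA35_synthetic = as.character(cr35@spacer),
               activator_PM = as.character(act@sequence))
  for (dirn in c("5prime", "3prime")) for (f in 1:10) {
    e <- designEra(cr, dirn, f)
    eras[[paste(dirn, f, sep = "_")]] <- e
    strands[[e@name]] <- as.character(e@sequence)
  }
  writeStrandFasta(strands, file.path(dir, "strands.fasta"))
  addFile("strands.fasta",
          list(type = "fasta", spacers = c(22, 35),
               era_toeholds = "1..10 both directions"))

  observeTo <- function(traj, condition, replicate = 1L) {
    observeFluorescence(traj, calib, sigmaAu, seed = nextSeed(),
                        metadata = list(sample_id = condition,
                                        condition = condition,
                                        replicate = replicate))
  }

  ## --- toehold-length panel ---------------------------------------------
  sys <- ReactionSystem()
  panel <- list()
  for (dirn in c("5prime", "3prime")) for (f in 1:10) {
    lay <- buildDuplexLayout(cr, eras[[paste(dirn, f, sep = "_")]], act)
    traj <- suppressMessages(
      simulateActivationCleavage(sys, lay, rp, em, tEnd = 1200))
    panel[[paste(dirn, f, sep = "_")]] <-
      observeTo(traj, sprintf("toehold_%s_f%d", dirn, f))
  }
  ctrl <- simulateActivationCleavage(sys, NULL, rp, em, tEnd = 1200)
  panel[["no_era"]] <- observeTo(ctrl, "no_ERA")
  writeTimeseriesCsv(panel, file.path(dir, "toehold_panel.csv"))
  addFile("toehold_panel.csv",
          list(type = "timeseries", t_end_s = 1200, dt_s = 20,
               toeholds = "f = 1..10, 5prime and 3prime, plus no-ERA control",
               system = "defaults"))

  ## --- mismatch panels ---------------------------------------------------
  mmPanel <- list()
  for (cfg in list(list(dirn = "3prime", f = 6), list(dirn = "5prime", f = 4))) {
    for (d in c(0L, 2L, 5L, 10L)) {
      span <- eras[[paste(cfg$dirn, cfg$f, sep = "_")]]@pairedSpan
      pos <- if (cfg$dirn == "5prime") span[1] + d else span[2] - d
      e <- designEra(cr, cfg$dirn, cfg$f, eraMismatches = pos)
      lay <- buildDuplexLayout(cr, e, act)
      traj <- simulateActivationCleavage(sys, lay, rp, em, tEnd = 1200)
      mmPanel[[paste(cfg$dirn, cfg$f, d, sep = "_")]] <-
        observeTo(traj, sprintf("era_mm_%s_f%d_d%d", cfg$dirn, cfg$f, d))
    }
  }
  for (d in c(1L, 5L, 9L, 14L)) {   # activator mismatches, 5' toehold-7
    e <- eras[["5prime_7"]]
    pos <- e@pairedSpan[1] + d
    actMm <- designActivator(cr, mismatchPositions = pos)
    lay <- buildDuplexLayout(cr, e, actMm)
    traj <- simulateActivationCleavage(sys, lay, rp, em, tEnd = 1200)
    mmPanel[[paste("act", d, sep = "_")]] <-
      observeTo(traj, sprintf("act_mm_5prime_f7_d%d", d))
  }
  writeTimeseriesCsv(mmPanel, file.path(dir, "mismatch_panel.csv"))
  addFile("mismatch_panel.csv",
          list(type = "timeseries", t_end_s = 1200,
               era_mismatch_distances = c(0, 2, 5, 10),
               activator_mismatch_distances = c(1, 5, 9, 14)))

  ## --- toehold-exchange panel -------------------------------------------
  tePanel <- list()
  teRp <- RateParams(kRevMode = "te_equilibrated")
  for (cfg in list(list(dirn = "3prime", f = 9, r = 4),
                   list(dirn = "5prime", f = 7, r = 4))) {
    te <- designTeEra(cr, cfg$dirn, cfg$f, cfg$r)
    lay <- buildDuplexLayout(cr, te$era, te$activator)
    traj <- simulateActivationCleavage(sys, lay, teRp, em, tEnd = 1200)
    tePanel[[paste(cfg$dirn, cfg$f, cfg$r, sep = "_")]] <-
      observeTo(traj, sprintf("te_%s_f%d_r%d", cfg$dirn, cfg$f, cfg$r))
  }
  writeTimeseriesCsv(tePanel, file.path(dir, "te_panel.csv"))
  addFile("te_panel.csv",
          list(type = "timeseries", k_rev_mode = "te_equilibrated",
               designs = "3prime f9/r4, 5prime f7/r4"))

  ## --- Michaelis-Menten titrations --------------------------------------
  mmRows <- list()
  for (e0 in c(1, 5)) {
    for (S in .CAL_CONCS) {
      msys <- ReactionSystem(cComplex0 = 0, cActivator0 = 0, cReporter0 = S,
                             eBackground = e0)
      traj <- simulateActivationCleavage(msys, NULL, rp, em, tEnd = 700)
      for (rep in 1:3) {
        mmRows[[sprintf("e%g_S%g_r%d", e0, S, rep)]] <-
          observeTo(traj, sprintf("mm_E%g_S%g", e0, S), replicate = rep)
      }
    }
  }
  writeTimeseriesCsv(mmRows, file.path(dir, "mm_titration.csv"))
  addFile("mm_titration.csv",
          list(type = "timeseries", E0_nM = c(1, 5),
               substrate_nM = .CAL_CONCS, replicates = 3, t_end_s = 700,
               k_cat_true = sys@kCat, K_M_true = sys@kM))

  ## --- DF replicate triplets --------------------------------------------
  dfRows <- list()
  eDf <- eras[["5prime_4"]]
  posMm <- eDf@pairedSpan[1] + 1L
  actMm <- designActivator(cr, mismatchPositions = posMm)
  layPm <- buildDuplexLayout(cr, eDf, act)
  layMm <- buildDuplexLayout(cr, eDf, actMm)
  trajPm <- simulateActivationCleavage(sys, layPm, rp, em, tEnd = 1200)
  trajMm <- simulateActivationCleavage(sys, layMm, rp, em, tEnd = 1200)
  bgSys <- ReactionSystem(cActivator0 = 0)
  trajBg <- simulateActivationCleavage(bgSys, layPm, rp, em, tEnd = 1200)
  for (rep in 1:3) {
    dfRows[[sprintf("pm_%d", rep)]] <- observeTo(trajPm, "PM", rep)
    dfRows[[sprintf("mm_%d", rep)]] <- observeTo(trajMm, "MM-1", rep)
    dfRows[[sprintf("bg_%d", rep)]] <- observeTo(trajBg, "background", rep)
  }
  writeTimeseriesCsv(dfRows, file.path(dir, "df_replicates.csv"))
  addFile("df_replicates.csv",
          list(type = "timeseries", layout = "5prime f4",
               activator_mismatch_distance = 1, replicates = 3,
               beta_penalty = betaFactor(1, rp)))

  ## --- one-pot scenarios -------------------------------------------------
  ## 37C one-pot conditions: slower turnover / tighter reporter binding
  ## (k_cat/K_M unchanged at 2e6 /M/s), reporter at the titration maximum
  opSys <- ReactionSystem(cActivator0 = 0, cReporter0 = 2000, kCat = 0.2,
                          kM = 100, temperatureK = 310.15)
  per <- list(kAmp = 3e-5, leakFrac = 0.05, template0 = 10, primer0 = 200)
  opRows <- list()
  eOp <- eras[["5prime_5"]]
  layOp <- buildDuplexLayout(cr, eOp, act)
  scenarios <- list(
    era_target = list(layout = layOp, target = TRUE, cleave = TRUE),
    era_notarget = list(layout = layOp, target = FALSE, cleave = TRUE),
    noera_target = list(layout = NULL, target = TRUE, cleave = TRUE),
    noera_notarget = list(layout = NULL, target = FALSE, cleave = TRUE),
    era_notarget_twostep = list(layout = layOp, target = FALSE,
                                cleave = FALSE))
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    traj <- simulateOnePot(opSys, c(per, list(targetPresent = sc$target)),
                           sc$layout, rp, em, tEnd = 14400,
                           templateCleavage = sc$cleave)
    opRows[[nm]] <- observeTo(traj, nm)
  }
  writeTimeseriesCsv(opRows, file.path(dir, "onepot.csv"))
  addFile("onepot.csv",
          list(type = "timeseries", t_end_s = 14400, k_cat = opSys@kCat,
               K_M = opSys@kM, per = per, era_layout = "5prime f5",
               scenarios = names(scenarios)))

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
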