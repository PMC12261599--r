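## End-to-end orchestration: each stage reads its inputs from the output
## directory, writes its artifacts, and records a manifest (stage, config
## hash, seed, inputs, outputs) so a run is reproducible from the config and
## seed alone.

#' Default run configuration
#'
#' A nested list with one block per stage: the acquisition protocol, the
#' phantom and cohort generator specs (as plain lists; see
#' \code{\link{PhantomSpec}} / \code{\link{CohortGenSpec}} for semantics),
#' fitting options (DESPOT2 path, whether/how to fit MWF), topography options
#' (percentile cuts) and model options (FDR level, centring flags). Any block
#' can be overridden before passing the config to \code{\link{runStage}}; the
#' whole list round-trips through YAML.
#'
#' @param seed master seed recorded in every stage manifest and used to seed
#'   each stochastic stage.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    protocol = protocolToList(AcquisitionProtocol()),
    phantom = list(grid_shape = c(24L, 24L, 40L), voxel_size = 0.5,
                   noise_sd = 0),
    cohort = list(n_participants = 120L),
    fitting = list(despot2_path = "joint", fit_mwf = FALSE,
                   mask_only = TRUE, bmc_samples = 20000L),
    topography = list(cut = 66, finer_cuts = c(44, 86)),
    models = list(fdr_q = 0.05, center_age = TRUE),
    sensitivity = list(dilate_voxels = 3L, shift_mm = 1.5))
}

.configHash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

.writeManifest <- function(outDir, stage, config, inputs, outputs) {
  manifest <- list(stage = stage, config_hash = .configHash(config),
                   seed = config$seed, inputs = inputs,
                   outputs = outputs)
  f <- file.path(outDir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  f
}

.needs <- function(outDir, path, producer) {
  full <- file.path(outDir, path)
  if (!file.exists(full))
    stop(sprintf("missing upstream artifact '%s'; run stage '%s' first",
                 path, producer), call. = FALSE)
  full
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate-phantom} (phantom volume, mask, ground-truth maps
#' and simulated signal stacks), \code{simulate-cohort} (cohort and visit
#' CSVs), \code{fit-maps} (B1 + DESPOT1/DESPOT2 maps from the stacks),
#' \code{extract-topography} (slice profile and subregion CSVs),
#' \code{prep-cognition} (domain z-scores), \code{fit-models} (age and
#' cognition models with FDR), \code{sensitivity} (shell and shifted-mask
#' summaries). Each stage writes its artifacts under \code{outDir} plus a
#' JSON manifest with the config hash and seed; deterministic stages are
#' bit-reproducible given the same config.
#'
#' @param stage stage name (see above).
#' @param config configuration list from \code{\link{defaultRunConfig}} (or a
#'   YAML file path).
#' @param outDir output directory.
#' @return list of artifact paths written, invisibly.
#' @export
runStage <- function(stage, config = defaultRunConfig(), outDir = "lcrelax-run") {
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- yaml::read_yaml(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  protocol <- protocolFromList(config$protocol)
  seed <- as.integer(config$seed)
  out <- switch(
    stage,
    "simulate-phantom" = {
      spec <- PhantomSpec(gridShape = config$phantom$grid_shape,
                          voxelSize = config$phantom$voxel_size, seed = seed)
      ph <- generatePhantom(spec)
      protocol@noiseSd <- as.numeric(config$phantom$noise_sd)
      stacks <- simulateAcquisition(ph$params, protocol, seed = seed,
                                    voxelSize = spec@voxelSize)
      truth <- asQmriMapSet(ph$params, spec@voxelSize)
      writeQmriMaps(truth, file.path(outDir, "truth"))
      writeLcMask(ph$mask, file.path(outDir, "lc_mask.nii.gz"))
      writeSignalStacks(stacks, file.path(outDir, "signals"))
      c("truth/", "lc_mask.nii.gz", "signals/")
    },
    "simulate-cohort" = {
      spec <- CohortGenSpec(nParticipants = config$cohort$n_participants,
                            seed = seed)
      cc <- generateCohort(spec, rawScores = TRUE)
      write.csv(cc$cohort, file.path(outDir, "cohort.csv"), row.names = FALSE)
      write.csv(cc$visits, file.path(outDir, "visits.csv"), row.names = FALSE)
      c("cohort.csv", "visits.csv")
    },
    "fit-maps" = {
      stacks <- readSignalStacks(.needs(outDir, "signals", "simulate-phantom"))
      mask <- readLcMask(.needs(outDir, "lc_mask.nii.gz", "simulate-phantom"))
      b1 <- fitDamB1Map(stacks)
      fitMask <- if (isTRUE(config$fitting$mask_only)) mask else NULL
      maps <- fitVolume(stacks, b1 = b1, mask = fitMask,
                        despot2Path = config$fitting$despot2_path,
                        estimateMwf = isTRUE(config$fitting$fit_mwf),
                        bmcConfig = BmcConfig(
                          nSamples = config$fitting$bmc_samples, seed = seed))
      writeQmriMaps(maps, file.path(outDir, "maps"))
      writeNiftiVolume(array(b1@kappa, b1@dim), voxelSize = b1@voxelSize,
                       file = file.path(outDir, "b1.nii.gz"))
      c("maps/", "b1.nii.gz")
    },
    "extract-topography" = {
      maps <- readQmriMaps(.needs(outDir, "maps", "fit-maps"))
      mask <- readLcMask(.needs(outDir, "lc_mask.nii.gz", "simulate-phantom"))
      prof <- sliceProfile(maps, mask)
      subs <- splitSubregions(prof, cut = config$topography$cut,
                              finerCuts = config$topography$finer_cuts)
      write.csv(prof@profile, file.path(outDir, "slice_profile.csv"),
                row.names = FALSE)
      write.csv(subs@summary, file.path(outDir, "subregions.csv"),
                row.names = FALSE)
      c("slice_profile.csv", "subregions.csv")
    },
    "prep-cognition" = {
      visits <- read.csv(.needs(outDir, "visits.csv", "simulate-cohort"))
      prepped <- prepCognition(visits)
      write.csv(prepped, file.path(outDir, "cognition_z.csv"),
                row.names = FALSE)
      "cognition_z.csv"
    },
    "fit-models" = {
      cohort <- read.csv(.needs(outDir, "cohort.csv", "simulate-cohort"),
                         stringsAsFactors = TRUE)
      visits <- read.csv(.needs(outDir, "cognition_z.csv", "prep-cognition"))
      metricCols <- setdiff(names(cohort),
                            c("pid", "age", "sex", "race", "edy"))
      ageTab <- do.call(rbind, lapply(metricCols, function(m) {
        lin <- fitLinearAge(cohort, m)
        quad <- fitQuadraticAge(cohort, m)
        data.frame(metric = m,
                   betaAge = lin@coefficients$estimate[
                     lin@coefficients$term == "age"],
                   pAge = lin@coefficients$p[lin@coefficients$term == "age"],
                   betaAge2 = quad@coefficients$estimate[
                     quad@coefficients$term == "I(ageC^2)"],
                   pAge2 = quad@coefficients$p[
                     quad@coefficients$term == "I(ageC^2)"])
      }))
      write.csv(ageTab, file.path(outDir, "age_models.csv"), row.names = FALSE)
      domains <- intersect(c("memory", "attention", "executive", "fluency",
                             "speed"), names(visits))
      cross <- coefficientTable(cohort, visits,
                                metrics = list(all = metricCols),
                                domains = domains, type = "cross_sectional",
                                q = config$models$fdr_q)
      write.csv(cross, file.path(outDir, "cross_sectional_models.csv"),
                row.names = FALSE)
      long <- coefficientTable(cohort, visits,
                               metrics = list(all = metricCols),
                               domains = domains, type = "longitudinal",
                               q = config$models$fdr_q)
      write.csv(long, file.path(outDir, "longitudinal_models.csv"),
                row.names = FALSE)
      c("age_models.csv", "cross_sectional_models.csv",
        "longitudinal_models.csv")
    },
    "sensitivity" = {
      maps <- readQmriMaps(.needs(outDir, "maps", "fit-maps"))
      truth <- readQmriMaps(.needs(outDir, "truth", "simulate-phantom"))
      mask <- readLcMask(.needs(outDir, "lc_mask.nii.gz", "simulate-phantom"))
      shell <- dilatedShellMask(mask, config$sensitivity$dilate_voxels)
      left <- shiftedMask(mask, -config$sensitivity$shift_mm)
      right <- shiftedMask(mask, config$sensitivity$shift_mm)
      rows <- lapply(list(lc = mask, shell = shell, leftShift = left,
                          rightShift = right), function(mk) {
        mm <- maskMeans(truth, mk)
        data.frame(r1 = mm["r1"], r2 = mm["r2"], mwf = mm["mwf"],
                   nOk = mm["nOk"])
      })
      tab <- do.call(rbind, rows)
      tab <- cbind(maskVariant = rownames(tab), tab)
      write.csv(tab, file.path(outDir, "sensitivity.csv"), row.names = FALSE)
      "sensitivity.csv"
    },
    stop(sprintf("unknown stage '%s'", stage), call. = FALSE))
  .writeManifest(outDir, stage, config,
                 inputs = character(), outputs = out)
  invisible(out)
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order:
#' simulate-phantom, simulate-cohort, fit-maps, extract-topography,
#' prep-cognition, fit-models, sensitivity.
#'
#' @inheritParams runStage
#' @return invisible list of per-stage outputs.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = "lcrelax-run") {
  stages <- c("simulate-phantom", "simulate-cohort", "fit-maps",
              "extract-topography", "prep-cognition", "fit-models",
              "sensitivity")
  res <- lapply(stages, runStage, config = config, outDir = outDir)
  names(res) <- stages
  invisible(res)
}
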