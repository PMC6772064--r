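#' @include io.R synthetic.R search.R
NULL

configError <- function(key, msg) {
  stop(structure(class = c("opmConfigError", "error", "condition"),
                 list(message = sprintf("config key `%s`: %s", key, msg),
                      call = NULL, key = key)))
}

numericalError <- function(stage, msg) {
  stop(structure(class = c("opmNumericalError", "error", "condition"),
                 list(message = sprintf("stage `%s`: %s", stage, msg),
                      call = NULL, stage = stage)))
}

.loadHead <- function(cfg, mesh) {
  kind <- cfg$head$kind %||% "sphere_global"
  if (kind == "single_shell") {
    if (is.null(mesh)) configError("head.shell_mesh", "required for single_shell")
    singleShellModel(mesh$vertices, mesh$faces, cfg$head$sh_order %||% 8)
  } else if (kind == "sphere_local") {
    if (is.null(mesh)) configError("head.shell_mesh", "required for sphere_local")
    tgt <- (cfg$head$target_mm %||% (defaultSourceLocation() * 1000)) / 1000
    fitSphere(mesh, region = localRegion(mesh, tgt,
                                         (cfg$head$region_mm %||% 40) / 1000))
  } else if (kind == "sphere_global") {
    if (is.null(mesh)) configError("head.shell_mesh", "required for sphere_global")
    fitSphere(mesh)
  } else configError("head.kind", paste("unknown kind", kind))
}

.loadInputs <- function(cfg, outDir) {
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    spec <- simulationSpec(
      nChannels = sim$n_channels %||% 13,
      sourceLocation = if (!is.null(sim$source_location_mm))
        sim$source_location_mm / 1000 else defaultSourceLocation(),
      sourceFreq = sim$source_freq_hz %||% 10,
      dipoleMoment = sim$dipole_moment_nAm %||% 10 * 1e-9,
      noiseRms = (sim$noise_rms_fT %||% 100) * 1e-15,
      duration = sim$duration_s %||% 1, sampleRate = sim$sample_rate_hz %||% 200,
      nTrials = sim$n_trials %||% 1, seed = cfg$seed %||% 0)
    hd <- makeHead(radius = (sim$head_radius_mm %||% 80) / 1000,
                   nVertices = sim$n_vertices %||% 642)
    arr <- makeArray(hd, nSensors = spec@nChannels)
    head <- .loadHead(cfg, hd$mesh)
    rec <- simulateRecording(spec, arr, hd$sources, head)
    list(data = rec$data, array = arr, sources = hd$sources, head = head,
         mesh = hd$mesh, truth = rec$truth, spec = spec)
  } else {
    for (k in c("array", "mesh", "data"))
      if (is.null(cfg[[k]])) configError(k, "path required when no simulation block")
    arr <- readSensorArray(cfg$array)
    mesh <- readSurface(cfg$mesh)
    data <- readDataMatrix(cfg$data)
    src <- makeSourcesFromMesh(mesh, (cfg$source_depth_mm %||% 10) / 1000)
    list(data = data, array = arr, sources = src, head = .loadHead(cfg, mesh),
         mesh = mesh, truth = NULL, spec = NULL)
  }
}

#' Source space from an inner-skull mesh
#'
#' Vertices moved `depth` inward along the outward vertex normal, with the
#' normal as the orientation constraint.
#' @param mesh list with vertices/faces.
#' @param depth metres.
#' @export
makeSourcesFromMesh <- function(mesh, depth = 0.01) {
  fcn <- faceCentresNormals(mesh$vertices, mesh$faces)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (k in seq_len(nrow(mesh$faces)))
    for (j in 1:3) vn[mesh$faces[k, j], ] <- vn[mesh$faces[k, j], ] + fcn$normals[k, ]
  vn <- normalizeRows(vn)
  sourceSpace(mesh$vertices - depth * vn, vn)
}

#' Run a configured experiment
#'
#' Executes one pipeline stage — `simulate`, `score`, `curve`, `search` or
#' `bma` — from a YAML/list configuration, writing its artifacts (with a
#' config echo, input hashes and the seed) into the output directory. This is
#' the programmatic core of the command-line front end.
#'
#' @param config a named list, or path to a YAML file.
#' @param overrides named list merged over the file configuration.
#' @return (invisibly) a list of the stage outputs and written paths.
#' @export
runExperiment <- function(config, overrides = list()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- modifyList(cfg, overrides)
  task <- cfg$task %||% configError("task", "missing")
  if (!task %in% c("simulate", "score", "curve", "search", "bma"))
    configError("task", paste("unknown task", task))
  if (is.null(cfg$simulation) && is.null(cfg$data))
    configError("data", "exactly one data source (file or simulation) required")
  if (!is.null(cfg$simulation) && !is.null(cfg$data))
    configError("data", "exactly one data source (file or simulation) required")
  cfg$seed <- cfg$seed %||% 0
  outDir <- cfg$out %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inp <- .loadInputs(cfg, outDir)
  invCfg <- cfg$inversion %||% list()
  prov <- list(seed = cfg$seed, config = cfg,
               input_hashes = if (!is.null(cfg$data))
                 as.list(tools::md5sum(c(cfg$array, cfg$mesh, cfg$data)))
               else list(simulation = "synthetic"))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  out <- list()
  wrap <- function(stage, expr) tryCatch(expr, error = function(e) {
    if (inherits(e, "opmConfigError")) stop(e)
    numericalError(stage, conditionMessage(e))
  })
  if (task == "simulate") {
    writeSensorArray(inp$array, file.path(outDir, "array.json"))
    writeSurface(inp$mesh, file.path(outDir, "mesh.obj"))
    writeDataMatrix(inp$data, file.path(outDir, "data.tsv"))
    jsonlite::write_json(list(source_index = inp$truth$sourceIndex,
                              seed = cfg$seed),
                         file.path(outDir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
    out <- inp
  } else if (task == "score") {
    ev <- wrap("score", scoreGeometry(inp$data, inp$array, inp$sources,
                                      inp$head, invCfg))
    jsonlite::write_json(list(F = ev@F, accuracy = ev@accuracy,
                              complexity = ev@complexity,
                              lambda = as.list(ev@lambdaHat),
                              converged = ev@converged, seed = cfg$seed),
                         file.path(outDir, "score.json"), auto_unbox = TRUE,
                         digits = NA)
    out$evidence <- ev
  } else if (task == "curve") {
    cc <- cfg$curve %||% list()
    crv <- wrap("curve", perturbationCurve(
      inp$data, inp$array, inp$sources, inp$head,
      kind = cc$kind %||% "orientation",
      offsets = cc$offsets %||% seq(-20, 20, by = 2.5),
      nRepeats = cc$n_repeats %||% 30, seed = cfg$seed,
      gainError = cc$gain_error %||% 0, config = invCfg))
    writeCurve(crv, file.path(outDir, "curve.tsv"))
    out$curve <- crv
  } else if (task == "search") {
    sc <- cfg$search %||% list()
    prior <- if ((sc$prior %||% "box") == "box")
      list(kind = "box", halfWidth = (sc$half_width_mm %||% 20) / 1000)
    else list(kind = "arc", range = sc$range_mm %||% c(-20, 20))
    samp <- wrap("search", metropolisPoseSearch(
      inp$data, inp$array, inp$sources, inp$head, prior = prior,
      nChains = sc$n_chains %||% 4, nIter = sc$n_iter %||% 600,
      seed = cfg$seed, config = invCfg))
    utils::write.table(samp, file.path(outDir, "chains.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out$samples <- samp
  } else if (task == "bma") {
    sc <- cfg$search %||% list()
    prior <- list(kind = "box", halfWidth = (sc$half_width_mm %||% 20) / 1000)
    samp <- wrap("search", metropolisPoseSearch(
      inp$data, inp$array, inp$sources, inp$head, prior = prior,
      nChains = sc$n_chains %||% 4, nIter = sc$n_iter %||% 600,
      seed = cfg$seed, config = invCfg))
    bb <- cfg$bma %||% list()
    res <- wrap("bma", bmaSources(samp, inp$data, inp$array, inp$sources,
                                  inp$head, nModels = bb$n_models %||% 30,
                                  seed = cfg$seed, config = invCfg))
    post <- res$posterior
    jsonlite::write_json(list(
      mean_translation_mm = post@meanPose@translation * 1000,
      ellipsoid_centre_mm = post@ellipsoidCentre * 1000,
      ellipsoid_cov_mm2 = post@ellipsoidCov * 1e6,
      volume_cm3 = post@volumeCm3, level = post@level, seed = cfg$seed),
      file.path(outDir, "posterior.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    out <- res
  }
  invisible(out)
}
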