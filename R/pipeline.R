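#' @include AllClasses.R io.R
NULL

.stage_names <- c("simulate", "screen", "signature", "linkage", "fourc",
                  "prot", "ifquant")

#' Assemble a run configuration
#'
#' A validated configuration for \code{\link{runStage}}: stage name,
#' input paths, parameter overrides, seed and output directory. Unknown
#' parameter keys are rejected so that typos fail loudly rather than
#' silently falling back to defaults.
#'
#' @param stage one of \code{simulate}, \code{screen}, \code{signature},
#'   \code{linkage}, \code{fourc}, \code{prot}, \code{ifquant}.
#' @param inputs named list of input file paths.
#' @param params named list of stage parameter overrides.
#' @param seed integer seed recorded in the manifest and used for every
#'   stochastic step of the stage.
#' @param outdir output directory (created if absent).
#' @return a \code{runConfig} list.
#' @export
runConfig <- function(stage, inputs = list(), params = list(), seed = 1L,
                      outdir = tempfile("run")) {
  stage <- match.arg(stage, .stage_names)
  allowed <- .stage_params(stage)
  unknown <- setdiff(names(params), allowed)
  if (length(unknown))
    stop("unknown parameter key(s) for stage '", stage, "': ",
         paste(unknown, collapse = ", "))
  structure(list(stage = stage, inputs = inputs, params = params,
                 seed = as.integer(seed), outdir = outdir),
            class = "runConfig")
}

.stage_params <- function(stage) {
  switch(stage,
    simulate = c("n_compounds", "n_samples", "n_fragments", "n_proteins",
                 "n_nuclei", "interaction_set", "linkage_effect", "gate",
                 "effect_regions", "n_diff", "missing_rate",
                 "touching_fraction", "marker_positive_fraction"),
    screen = c("treated_arm", "vehicle_arm", "alpha", "sensitize_cut",
               "tolerance_cut"),
    signature = c("aggregate", "scheme"),
    linkage = c("candidate", "target", "condition_on", "method"),
    fourc = c("paired", "viewpoint"),
    prot = c("mode", "min_fraction", "min_count", "scope", "width",
             "downshift", "p_cut", "diff_cut", "scale", "preset"),
    ifquant = c("ball_radius_um", "median_radius_um", "window_radius_um",
                "k", "min_area_um2", "use_watershed", "threshold",
                "calibration"))
}

.manifest <- function(cfg, outputs) {
  inp <- unlist(cfg$inputs)
  list(stage = cfg$stage, seed = cfg$seed,
       parameters = cfg$params,
       inputs = as.list(if (length(inp))
         setNames(unname(tools::md5sum(inp)), names(inp)) else list()),
       outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                                  basename(outputs))),
       package_version = as.character(packageVersion("gcDormancy")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run one pipeline stage from a configuration
#'
#' Executes a stage of the dormancy-analysis pipeline on file inputs,
#' writes its outputs under \code{cfg$outdir} and records a manifest
#' (\code{manifest.json}) with input/output checksums, parameters, seed
#' and package version, so any result can be reproduced from its
#' manifest alone. All randomness within a stage derives from
#' \code{cfg$seed}, making repeated runs byte-identical.
#'
#' Stage inputs: \code{simulate} none (writes every synthetic input
#' consumed by the other stages); \code{screen} needs \code{plates};
#' \code{signature} needs \code{expr} and \code{genes}; \code{linkage}
#' needs \code{expr}, \code{acc} and \code{bed}; \code{fourc} needs
#' \code{profile} and \code{regions}; \code{prot} needs \code{matrix}
#' and \code{groups}; \code{ifquant} needs \code{image} (2-page TIFF
#' with JSON sidecar).
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return invisibly, the manifest list.
#' @examples
#' out <- tempfile("demo")
#' m <- runStage(runConfig("simulate", seed = 7, outdir = out,
#'                         params = list(n_compounds = 12, n_samples = 20,
#'                                       n_nuclei = 6, n_proteins = 40)))
#' m$stage
#' @export
runStage <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  for (f in unlist(cfg$inputs))
    if (!file.exists(f)) stop("input does not exist: ", f)
  p <- cfg$params
  gp <- function(key, default) if (!is.null(p[[key]])) p[[key]] else default
  out <- file.path(cfg$outdir, "")
  outputs <- character(0)
  add <- function(x) outputs <<- c(outputs, x)

  if (cfg$stage == "simulate") {
    sim <- simulatePlates(plateSimConfig(
      n_compounds = gp("n_compounds", 60L),
      interaction_set = gp("interaction_set", numeric(0)),
      seed = cfg$seed))
    add(writePlates(sim$plates, file.path(cfg$outdir, "plates.tsv")))
    write.table(sim$truth, file.path(cfg$outdir, "plates_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    add(file.path(cfg$outdir, "plates_truth.tsv"))

    cs <- simulateCohort(cohortSimConfig(
      n_samples = gp("n_samples", 120L),
      linkage_effect = gp("linkage_effect", sqrt(1.5)),
      gate = gp("gate", "none"), seed = cfg$seed + 1L))
    add(writeMatrixTSV(exprMatrix(cs$cohort),
                       file.path(cfg$outdir, "expr.tsv"), "gene"))
    add(writeMatrixTSV(accMatrix(cs$cohort),
                       file.path(cfg$outdir, "acc.tsv"), "enhancer"))
    add(writeBed(enhancerRanges(cs$cohort),
                 file.path(cfg$outdir, "enhancers.bed")))
    writeLines(cs$truth$signature_genes,
               file.path(cfg$outdir, "signature_genes.txt"))
    add(file.path(cfg$outdir, "signature_genes.txt"))

    fc <- simulateFourC(fourcSimConfig(
      n_fragments = gp("n_fragments", 60L),
      effect_regions = gp("effect_regions",
                          data.frame(start = 2760000, end = 2800000,
                                     effect = 2)),
      seed = cfg$seed + 2L))
    add(writeFourC(fc$profile, file.path(cfg$outdir, "fourc.tsv")))
    add(writeRegions(parseRegion(c(region_a = "chr11: 2760000-2800000")),
                     file.path(cfg$outdir, "regions.tsv")))

    lf <- simulateLFQ(n_proteins = gp("n_proteins", 300L),
                      n_diff = gp("n_diff", 10L),
                      missing_rate = gp("missing_rate", 0.3),
                      seed = cfg$seed + 3L)
    add(writeLFQ(lf$lfq, file.path(cfg$outdir, "lfq.tsv"),
                 file.path(cfg$outdir, "lfq_groups.tsv")))
    add(file.path(cfg$outdir, "lfq_groups.tsv"))

    im <- simulateImage(imageSimConfig(
      n_nuclei = gp("n_nuclei", 30L),
      touching_fraction = gp("touching_fraction", 0.1),
      marker_positive_fraction = gp("marker_positive_fraction", 0.5),
      seed = cfg$seed + 4L))
    add(writeImagePair(im$nuclear, im$marker, im$pixel_size,
                       file.path(cfg$outdir, "image.tif")))
  } else if (cfg$stage == "screen") {
    plates <- readPlates(cfg$inputs$plates)
    res <- classifyHits(
      scoreScreen(plates, treated_arm = gp("treated_arm", "pretreat"),
                  vehicle_arm = gp("vehicle_arm", "vehicle")),
      alpha = gp("alpha", 0.05),
      sensitize_cut = gp("sensitize_cut", -0.3),
      tolerance_cut = gp("tolerance_cut", 0.3))
    f <- file.path(cfg$outdir, "screen_results.tsv")
    write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
  } else if (cfg$stage == "signature") {
    expr <- readMatrixTSV(cfg$inputs$expr)
    genes <- readLines(cfg$inputs$genes)
    sc <- signatureScore(expr, genes, aggregate = gp("aggregate", "mean"))
    sc$stratum <- stratifySamples(sc, scheme = gp("scheme",
                                                  "quartile-extremes"))
    f <- file.path(cfg$outdir, "signature_scores.tsv")
    write.table(sc, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
  } else if (cfg$stage == "linkage") {
    expr <- readMatrixTSV(cfg$inputs$expr)
    acc <- readMatrixTSV(cfg$inputs$acc)
    enh <- readBed(cfg$inputs$bed)
    cohort <- CohortData(expr, acc[names(enh), , drop = FALSE], enh)
    res <- linkageAnalysis(cohort, gp("candidate", "candidate"),
                           gp("target", "TARGET"),
                           condition_on = gp("condition_on", NULL),
                           method = gp("method", "spearman"))
    f <- file.path(cfg$outdir, "linkage.json")
    jsonlite::write_json(
      list(candidate = res$candidate, target = res$target,
           rho_candidate = res$rho_candidate,
           empirical_quantile = res$empirical_quantile,
           neighbor_rhos = as.list(res$neighbor_rhos),
           conditioned_curve = res$conditioned_curve),
      f, auto_unbox = TRUE, digits = NA)
    add(f)
  } else if (cfg$stage == "fourc") {
    prof <- readFourC(cfg$inputs$profile,
                      viewpoint = gp("viewpoint", "viewpoint"))
    regions <- readRegions(cfg$inputs$regions)
    rows <- do.call(rbind, lapply(seq_along(regions), function(i) {
      r <- regionCompare(prof, regions[i], paired = gp("paired", TRUE))
      data.frame(region = names(regions)[i], n_fragments = r$n_fragments,
                 median_diff = r$median_diff, p = r$p.value)
    }))
    f <- file.path(cfg$outdir, "fourc_results.tsv")
    write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
  } else if (cfg$stage == "prot") {
    lfq <- readLFQ(cfg$inputs$matrix, cfg$inputs$groups)
    lfq <- filterValid(lfq, mode = gp("mode", "per-group-count"),
                       min_fraction = gp("min_fraction", 0.66),
                       min_count = gp("min_count", 2L),
                       scope = gp("scope", "all"))
    lfq <- imputeDownshift(lfq, width = gp("width", 0.3),
                           downshift = gp("downshift", 1.8),
                           seed = cfg$seed)
    res <- differentialTest(lfq, p_cut = gp("p_cut", 0.05),
                            diff_cut = gp("diff_cut", 1.5),
                            scale = gp("scale", "log2diff"))
    f <- file.path(cfg$outdir, "prot_results.tsv")
    write.table(res, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
  } else if (cfg$stage == "ifquant") {
    img <- readImagePair(cfg$inputs$image)
    res <- ifQuantify(img$nuclear, img$marker, img$pixel_size,
                      threshold = gp("threshold", NULL),
                      calibration = gp("calibration", "p99"),
                      ball_radius_um = gp("ball_radius_um", 40),
                      median_radius_um = gp("median_radius_um", 1.5),
                      window_radius_um = gp("window_radius_um", 8),
                      k = gp("k", 4),
                      min_area_um2 = gp("min_area_um2", 20),
                      use_watershed = gp("use_watershed", TRUE))
    add(writeLabelTiff(labelMap(res),
                       file.path(cfg$outdir, "labels.tif")))
    nt <- as.data.frame(nucleusTable(res))
    f <- file.path(cfg$outdir, "nuclei.csv")
    utils::write.csv(nt, f, row.names = FALSE)
    add(f)
    f2 <- file.path(cfg$outdir, "summary.json")
    jsonlite::write_json(
      list(n_nuclei = nrow(nt), n_positive = sum(nt$positive),
           threshold = positivityThreshold(res),
           expression_index = expressionIndex(res)),
      f2, auto_unbox = TRUE, digits = NA)
    add(f2)
  }

  manifest <- .manifest(cfg, outputs)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
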