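.defaultRunConfig <- function() {
  list(
    seed = NULL,
    output_dir = NULL,
    manifest = NULL,
    simulation = NULL,
    panel = NULL,
    panel_restrict = list(similarity = TRUE, venn = TRUE, pca = FALSE),
    filters = list(min_alt_reads = 3L, min_per_strand = 1L,
                   min_trio_depth = 3L, use_quality_depth = FALSE),
    math = list(mad_scale = 1.4826, min_sites = 5L),
    pca = list(k = 2L))
}

.mergeDefaults <- function(user, defaults, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    warning("ignoring unknown config key(s): ",
            paste(paste(c(path, ""), collapse = "."), unknown,
                  sep = "", collapse = ", "))
  for (nm in intersect(names(user), names(defaults))) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]]))
      defaults[[nm]] <- .mergeDefaults(user[[nm]], defaults[[nm]],
                                       c(path, nm))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Validate and normalize a pipeline run configuration
#'
#' Reads a YAML config (or takes an equivalent named list), fills
#' defaults and range-checks every field, reporting violations by field
#' name.  Exactly one input source must be present: either
#' \code{simulation} (a block of \code{\link{TrioSimConfig}} parameters
#' in snake_case, with \code{clone_scenarios: default} or an explicit
#' clone list) or \code{manifest} (path to a TSV with columns
#' \code{patient_id} and \code{vcf}).  Filter thresholds default to the
#' SNV acceptance rules (3 quality-passing alt reads, 1 per strand,
#' trio-wide depth 3); the MAD scale factor defaults to 1.4826.  A
#' top-level \code{seed} is mandatory.
#'
#' @param config path to a YAML file, or a named list.
#' @return the normalized config list (invisibly printable; fields as in
#'   the defaults).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  cfg <- .mergeDefaults(config, .defaultRunConfig())

  fail <- function(field, what) stop("config field '", field, "' ", what)
  if (is.null(cfg$seed) || is.na(suppressWarnings(as.integer(cfg$seed))))
    fail("seed", "is mandatory and must be an integer")
  cfg$seed <- as.integer(cfg$seed)

  hasSim <- !is.null(cfg$simulation)
  hasMan <- !is.null(cfg$manifest)
  if (hasSim == hasMan)
    stop("exactly one of config fields 'simulation' and 'manifest' ",
         "must be present")

  f <- cfg$filters
  for (nm in c("min_alt_reads", "min_per_strand", "min_trio_depth")) {
    v <- f[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      fail(paste0("filters.", nm), "must be a positive integer")
    cfg$filters[[nm]] <- as.integer(v)
  }
  if (!is.logical(f$use_quality_depth))
    fail("filters.use_quality_depth", "must be TRUE or FALSE")
  if (!is.numeric(cfg$math$mad_scale) || cfg$math$mad_scale <= 0)
    fail("math.mad_scale", "must be a positive number")
  if (!is.numeric(cfg$math$min_sites) || cfg$math$min_sites < 1)
    fail("math.min_sites", "must be a positive integer")
  cfg$math$min_sites <- as.integer(cfg$math$min_sites)
  if (!is.numeric(cfg$pca$k) || cfg$pca$k < 1)
    fail("pca.k", "must be a positive integer")
  cfg$pca$k <- as.integer(cfg$pca$k)

  if (hasSim) {
    s <- cfg$simulation
    known <- c("n_patients", "germline_snv_count", "tumor_purity",
               "culture_normal_fraction", "mean_depth", "depth_model",
               "low_quality_read_rate", "strand_bias", "clone_scenarios")
    unknown <- setdiff(names(s), known)
    if (length(unknown))
      warning("ignoring unknown simulation key(s): ",
              paste(unknown, collapse = ", "))
    # Build (and thereby range-check) the simulator config now so that
    # invalid values fail at validation time, not mid-run.
    cfg$simConfig <- .simConfigFromList(s, cfg$seed)
  }
  if (hasMan && !file.exists(cfg$manifest))
    fail("manifest", paste0("file not found: ", cfg$manifest))
  if (!is.null(cfg$panel) && !file.exists(cfg$panel))
    fail("panel", paste0("file not found: ", cfg$panel))
  structure(cfg, class = "triohetRunConfig")
}

.simConfigFromList <- function(s, seed) {
  nPatients <- as.integer(s$n_patients %||% 2L)
  clones <- s$clone_scenarios %||% "default"
  if (identical(clones, "default")) {
    clones <- defaultCloneScenarios(nPatients)
  } else if (is.list(clones)) {
    clones <- lapply(clones, function(p)
      do.call(rbind, lapply(p, as.data.frame)))
  } else stop("config field 'simulation.clone_scenarios' must be ",
              "'default' or a per-patient clone list")
  TrioSimConfig(
    nPatients = nPatients,
    germlineSnvCount = as.integer(s$germline_snv_count %||% 2000L),
    clones = clones,
    tumorPurity = s$tumor_purity %||% 0.7,
    cultureNormalFraction = s$culture_normal_fraction %||% 0.5,
    meanDepth = s$mean_depth %||% 80,
    depthModel = s$depth_model %||% "poisson",
    lowQualityReadRate = s$low_quality_read_rate %||% 0.05,
    strandBias = s$strand_bias %||% 0.5,
    seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readManifest <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "vcf") %in% names(df)))
    stop("manifest must have columns patient_id and vcf")
  base <- dirname(path)
  paths <- ifelse(file.exists(df$vcf), df$vcf, file.path(base, df$vcf))
  setNames(paths, df$patient_id)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full trio analysis pipeline
#'
#' Orchestrates simulate (or load) -> read + filter -> similarity ->
#' Venn -> MATH -> PCA from a single validated configuration, writing a
#' report bundle to \code{outDir}: \code{similarity.tsv} /
#' \code{similarity.json} (per-patient records plus pooled and mean
#' cohort aggregates), \code{venn_counts.tsv}, \code{math.tsv},
#' \code{pca_coordinates.tsv}, \code{pca_explained_variance.tsv}, and a
#' machine-readable \code{run_manifest.json} (package version, seed,
#' effective thresholds, per-patient filter logs).  Every patient appears
#' in every table, flagged rather than dropped when a quantity is
#' unreliable.  All randomness flows from the single configured seed, so
#' a rerun with the same config is numerically identical.  If a stage
#' fails, a \code{FAILED_<stage>} marker file is left in \code{outDir}
#' and the error is re-thrown.
#'
#' @param config a YAML path or list accepted by
#'   \code{\link{validateConfig}}, or an already-validated config.
#' @param outDir output directory (default: the config's
#'   \code{output_dir}).
#' @return invisibly, a list with the cohort, the similarity and Venn
#'   tables, the MATH table, the \linkS4class{PcaResult}, the
#'   triplet-grouping ratio and the output paths.
#' @examples
#' cfg <- list(seed = 1,
#'             simulation = list(n_patients = 2,
#'                               germline_snv_count = 150))
#' res <- runPipeline(cfg, outDir = tempfile("run"))
#' res$similarity
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (!inherits(config, "triohetRunConfig"))
    config <- validateConfig(config)
  outDir <- outDir %||% config$output_dir
  if (is.null(outDir))
    stop("config field 'output_dir' (or the outDir argument) is required")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(outDir, paste0("FAILED_", name)))
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  vcfPaths <- stage("input", {
    if (!is.null(config$simConfig)) {
      sim <- simulateTrioCohort(config$simConfig, file.path(outDir, "vcf"))
      sim$vcf
    } else .readManifest(config$manifest)
  })

  panel <- if (!is.null(config$panel))
    stage("panel", readGenePanel(config$panel)) else NULL
  panelFor <- function(analysis)
    if (isTRUE(config$panel_restrict[[analysis]])) panel else NULL

  cohort <- stage("filter", {
    f <- config$filters
    readTrioCohort(vcfPaths,
                   minAltReads = f$min_alt_reads,
                   minPerStrand = f$min_per_strand,
                   minDepth = f$min_trio_depth,
                   useQualityDepth = f$use_quality_depth)
  })

  simTab <- stage("similarity",
                  cohortSimilarityTable(cohort, panelFor("similarity")))
  vennTab <- stage("venn", cohortVennTable(cohort, panelFor("venn")))
  mathTab <- stage("math",
                   cohortMathTable(cohort,
                                   scaleFactor = config$math$mad_scale,
                                   minSites = config$math$min_sites))
  pcaOut <- stage("pca", {
    m <- buildGenotypeMatrix(cohort, panelFor("pca"))
    pca <- runPca(m, k = min(config$pca$k, nrow(m) - 1L, ncol(m)))
    grouping <- if (length(cohort) >= 2L)
      tripletGroupingScore(pca) else NA_real_
    list(pca = pca, grouping = grouping)
  })

  paths <- stage("report", {
    p <- list(
      similarity = .writeTsv(simTab, file.path(outDir, "similarity.tsv")),
      venn = .writeTsv(vennTab, file.path(outDir, "venn_counts.tsv")),
      math = .writeTsv(mathTab, file.path(outDir, "math.tsv")),
      pca_coordinates = .writeTsv(
        data.frame(sample = rownames(pcaOut$pca@coordinates),
                   pcaOut$pca@coordinates, check.names = FALSE),
        file.path(outDir, "pca_coordinates.tsv")),
      pca_variance = .writeTsv(
        data.frame(component = seq_along(pcaOut$pca@explainedVariance),
                   explained_variance = pcaOut$pca@explainedVariance),
        file.path(outDir, "pca_explained_variance.tsv")))
    write_json(
      list(per_patient = simTab, aggregate = attr(simTab, "aggregate")),
      file.path(outDir, "similarity.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    p$similarity_json <- file.path(outDir, "similarity.json")
    write_json(
      list(package = "triohet",
           version = as.character(packageVersion("triohet")),
           r_version = as.character(getRversion()),
           seed = config$seed,
           filters = config$filters,
           mad_scale = config$math$mad_scale,
           panel = config$panel %||% NA,
           triplet_grouping_score = pcaOut$grouping,
           filter_logs = lapply(cohort, filterLog)),
      file.path(outDir, "run_manifest.json"),
      auto_unbox = TRUE, digits = NA)
    p$run_manifest <- file.path(outDir, "run_manifest.json")
    p
  })

  invisible(list(cohort = cohort, similarity = simTab, venn = vennTab,
                 math = mathTab, pca = pcaOut$pca,
                 tripletGrouping = pcaOut$grouping, paths = paths,
                 config = config))
}
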