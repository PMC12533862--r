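# End-to-end triage pipeline: ranked screen -> enrichment factor ->
# key-residue gate -> candidate list -> MD stability summary.

.CONFIG_SCHEMA <- list(
  seed = NULL, output_dir = NULL,
  screen = list(table = NULL, lower_is_better = NULL, fraction = NULL,
                score_threshold = NULL, overlap_threshold = NULL,
                require_clinical = NULL),
  interaction = list(receptor = NULL, ligand = NULL, key_residues = NULL,
                     contact_cutoff = NULL,
                     hbond = list(max_da = NULL, max_ha = NULL,
                                  min_angle = NULL,
                                  heavy_atom_fallback = NULL),
                     weights = list(hbond = NULL, contact = NULL)),
  md = list(manifest = NULL, unit = NULL, early_stop = NULL,
            censor_value = NULL, n_replicates = NULL, window_start = NULL,
            window_end = NULL, binding_threshold = NULL,
            whole_replicate = NULL))

.checkConfigKeys <- function(cfg, schema, path = character()) {
  for (k in names(cfg)) {
    here <- paste(c(path, k), collapse = ".")
    if (!k %in% names(schema))
      stop(sprintf("unknown config key: %s", here))
    if (is.list(schema[[k]]) && length(schema[[k]]) && is.list(cfg[[k]]))
      .checkConfigKeys(cfg[[k]], schema[[k]], c(path, k))
  }
  invisible(TRUE)
}

#' Default pipeline configuration
#'
#' All pipeline constants with their defaults: 5 Angstrom close-contact
#' cutoff, 5.5 Angstrom early stop, 10 Angstrom censor value, 9-10 ns
#' ranking window, 3 replicates, top-1-percent enrichment fraction.
#'
#' @return Nested named list of defaults.
#' @export
configDefaults <- function() {
  list(
    seed = 1L, output_dir = "triage_out",
    screen = list(table = NULL, lower_is_better = TRUE, fraction = 0.01,
                  score_threshold = NULL, overlap_threshold = NULL,
                  require_clinical = FALSE),
    interaction = list(receptor = NULL, ligand = NULL, key_residues = NULL,
                       contact_cutoff = 5.0,
                       hbond = list(max_da = 3.5, max_ha = 2.5,
                                    min_angle = 120,
                                    heavy_atom_fallback = TRUE),
                       weights = list(hbond = 2, contact = 1)),
    md = list(manifest = NULL, unit = "angstrom", early_stop = 5.5,
              censor_value = 10, n_replicates = 3, window_start = 9,
              window_end = 10, binding_threshold = 5.5,
              whole_replicate = FALSE))
}

.mergeConfig <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]]))
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read and validate a pipeline configuration file
#'
#' YAML configuration; unknown keys are rejected, known keys are merged
#' over \code{\link{configDefaults}}. Relative input paths are resolved
#' against the config file's directory.
#'
#' @param path path to a YAML config file.
#' @return Validated config list (attribute \code{base} holds the
#'   directory used to resolve relative paths).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("config must be a YAML mapping")
  .checkConfigKeys(user, .CONFIG_SCHEMA)
  cfg <- .mergeConfig(configDefaults(), user)
  attr(cfg, "base") <- dirname(normalizePath(path))
  cfg
}

.resolvePath <- function(p, base) {
  if (is.null(p) || is.na(p)) return(p)
  if (grepl("^(/|[A-Za-z]:)", p) || is.null(base)) p
  else file.path(base, p)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the end-to-end triage pipeline
#'
#' Wires the stages together in flowchart order: rank the scored screen,
#' compute the enrichment factor over labeled actives, apply the
#' score/overlap/clinical candidate gates, and summarise MD stability for
#' the compounds listed in the replicate manifest. Each stage logs to
#' standard error via \code{message()}; stage errors are propagated with
#' the stage name. Outputs (ranked table, EF report, candidate list with
#' decision trail, stability summary, per-compound median series) are
#' written to the configured output directory; reruns with identical
#' config and inputs are byte-identical.
#'
#' @param config a config list from \code{\link{readRunConfig}} (or a path
#'   to a YAML config file).
#' @return Invisibly, a list of the in-memory stage results and the paths
#'   written.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  base <- attr(config, "base")
  outDir <- .resolvePath(config$output_dir, base)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  result <- list()

  ## screen ranking
  ranked <- NULL
  if (!is.null(config$screen$table)) {
    ranked <- .stage("screen", {
      p <- .resolvePath(config$screen$table, base)
      if (!file.exists(p))
        stop(sprintf("screen table not found: %s", p))
      df <- utils::read.delim(p, stringsAsFactors = FALSE)
      message(sprintf("screen: %d compounds read from %s", nrow(df), p))
      rankCompounds(screenTable(
        df, lowerIsBetter = isTRUE(config$screen$lower_is_better)))
    })
    f <- file.path(outDir, "ranked.tsv")
    .writeTsv(compounds(ranked), f)
    paths <- c(paths, f)
    result$ranked <- ranked
  }

  ## enrichment factor
  if (!is.null(ranked) && "active" %in% names(compounds(ranked)) &&
      any(as.logical(compounds(ranked)$active))) {
    ef <- .stage("enrichment", {
      r <- enrichmentFactor(ranked, config$screen$fraction)
      message(sprintf("enrichment: EF(%g%%) = %.4f",
                      100 * config$screen$fraction, efValue(r)))
      r
    })
    f <- file.path(outDir, "ef_report.json")
    jsonlite::write_json(list(
      fraction = ef@fraction, n_top = ef@nTop,
      n_actives_top = ef@nActivesTop, n_total = ef@nTotal,
      n_actives = ef@nActives, ef = ef@ef),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, f)
    result$ef <- ef
  }

  ## pose interaction scoring
  if (!is.null(config$interaction$receptor) &&
      !is.null(config$interaction$ligand)) {
    report <- .stage("interaction", {
      rp <- .resolvePath(config$interaction$receptor, base)
      lp <- .resolvePath(config$interaction$ligand, base)
      for (p in c(rp, lp)) if (!file.exists(p))
        stop(sprintf("input not found: %s", p))
      receptor <- readReceptor(rp)
      pose <- readLigand(lp)
      spec <- if (!is.null(config$interaction$key_residues)) {
        kp <- .resolvePath(config$interaction$key_residues, base)
        if (!file.exists(kp))
          stop(sprintf("key-residue file not found: %s", kp))
        keyResidueSpec(utils::read.delim(kp, stringsAsFactors = FALSE),
                       contactCutoff = config$interaction$contact_cutoff)
      } else sglt2KeyResidues(config$interaction$contact_cutoff)
      hb <- config$interaction$hbond
      w <- config$interaction$weights
      rep <- keyResidueScore(pose, receptor, spec,
        criteria = hbondCriteria(hb$max_da, hb$max_ha, hb$min_angle,
                                 hb$heavy_atom_fallback),
        weights = c(hbond = w$hbond, contact = w$contact))
      message(sprintf(
        "interaction: score %.3g, key-residue overlap %.3f",
        interactionScore(rep), keyResidueOverlap(rep)))
      rep
    })
    f <- file.path(outDir, "interaction_residues.tsv")
    .writeTsv(residueReport(report), f)
    paths <- c(paths, f)
    result$interaction <- report
  }

  ## candidate selection
  thr <- config$screen
  if (!is.null(ranked) &&
      (!is.null(thr$score_threshold) || !is.null(thr$overlap_threshold) ||
       isTRUE(thr$require_clinical))) {
    sel <- .stage("triage", {
      s <- selectCandidates(ranked, triageThresholds(
        score = if (is.null(thr$score_threshold)) NA_real_
                else thr$score_threshold,
        overlap = if (is.null(thr$overlap_threshold)) NA_real_
                  else thr$overlap_threshold,
        requireClinical = isTRUE(thr$require_clinical)))
      message(sprintf("triage: %d candidate(s) retained of %d",
                      nrow(s$candidates), nrow(compounds(ranked))))
      s
    })
    f1 <- file.path(outDir, "candidates.tsv")
    f2 <- file.path(outDir, "decisions.tsv")
    .writeTsv(sel$candidates, f1)
    .writeTsv(sel$decisions, f2)
    paths <- c(paths, f1, f2)
    result$triage <- sel
  }

  ## MD stability
  if (!is.null(config$md$manifest)) {
    stab <- .stage("md_stability", {
      mp <- .resolvePath(config$md$manifest, base)
      if (!file.exists(mp))
        stop(sprintf("MD manifest not found: %s", mp))
      man <- utils::read.delim(mp, stringsAsFactors = FALSE)
      if (!"compound" %in% names(man))
        stop("MD manifest needs a 'compound' column")
      repCols <- grep("^rep", names(man), value = TRUE)
      if (!length(repCols))
        stop("MD manifest needs replicate path columns (rep1, rep2, ...)")
      cfg <- stabilityConfig(
        earlyStop = config$md$early_stop,
        censorValue = config$md$censor_value,
        nReplicates = config$md$n_replicates,
        windowStart = config$md$window_start,
        windowEnd = config$md$window_end,
        bindingThreshold = config$md$binding_threshold,
        wholeReplicate = isTRUE(config$md$whole_replicate))
      unit <- if (identical(config$md$unit, "nm")) "nm" else "angstrom"
      res <- lapply(seq_len(nrow(man)), function(i) {
        reps <- lapply(repCols, function(cn) {
          rp <- .resolvePath(man[[cn]][i], dirname(mp))
          if (!file.exists(rp))
            stop(sprintf("replicate series not found: %s", rp))
          readRmsdSeries(rp, unit = unit, replicate = cn)
        })
        compoundStability(man$compound[i], reps, cfg)
      })
      for (r in res) {
        f <- file.path(outDir,
                       sprintf("median_series_%s.csv", r$id))
        utils::write.csv(data.frame(time_ns = seriesTimes(r$medianSeries),
                                    rmsd_A = seriesValues(r$medianSeries)),
                         f, row.names = FALSE, quote = FALSE)
        paths <- c(paths, f)
      }
      message(sprintf("md_stability: %d compound(s) summarised",
                      length(res)))
      rankLigands(res)
    })
    f <- file.path(outDir, "stability.tsv")
    .writeTsv(stab, f)
    paths <- c(paths, f)
    result$stability <- stab
  }

  ## plain-text summary
  sf <- file.path(outDir, "summary.txt")
  lines <- c("triage pipeline summary", "=======================")
  if (!is.null(result$ranked))
    lines <- c(lines, sprintf("compounds ranked: %d",
                              nrow(compounds(result$ranked))))
  if (!is.null(result$ef))
    lines <- c(lines, sprintf("EF(%g%%) = %.4f (%d/%d actives in top %d)",
                              100 * result$ef@fraction, result$ef@ef,
                              result$ef@nActivesTop, result$ef@nActives,
                              result$ef@nTop))
  if (!is.null(result$interaction))
    lines <- c(lines, sprintf(
      "pose key-residue overlap: %.3f (score %.3g)",
      keyResidueOverlap(result$interaction),
      interactionScore(result$interaction)))
  if (!is.null(result$triage))
    lines <- c(lines, sprintf("candidates retained: %d",
                              nrow(result$triage$candidates)))
  if (!is.null(result$stability))
    lines <- c(lines, sprintf(
      "MD-stable (bound) compounds: %d of %d",
      sum(result$stability$bound), nrow(result$stability)))
  writeLines(lines, sf)
  paths <- c(paths, sf)

  result$paths <- paths
  invisible(result)
}
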