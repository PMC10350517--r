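#' Default audit configuration
#'
#' Thresholds default to the printed analysis settings of the study design
#' this package audits: marker floor > 10 FPKM, 10-fold specificity, FDR
#' alpha 0.05, null half-width c = 0.05 and mean read support > 100.  The
#' synthetic block emulates a mixed culture contributing 85% neuronal / 15%
#' astrocytic mRNA whose treatment halves the neuronal contribution.
#'
#' @param seed integer seed.
#' @return nested list understood by [runFullAudit()].
#' @export
defaultAuditConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(
      nGenes = 1000, nEvents = 600, markerFrac = 0.2,
      psiDivergenceFrac = 0.5,
      weights = list(control = c(neuron = 0.85, astrocyte = 0.15),
                     treated = c(neuron = 0.50, astrocyte = 0.50)),
      replicates = 3, pureReplicates = 3, depth = 2000, exprNoiseSd = 0.2),
    thresholds = list(minFpkm = 10, minFold = 10, alpha = 0.05,
                      c = 0.05, minAvgCount = 100),
    nPerm = 999
  )
}

#' Read an audit configuration from YAML or JSON
#'
#' Any threshold omitted falls back to [defaultAuditConfig()]'s value; an
#' override of a default threshold is reported with a warning, since
#' unexamined analysis settings are exactly what a composition audit is
#' guarding against.
#'
#' @param path YAML (or JSON) file.
#' @return configuration list.
#' @export
readAuditConfig <- function(path) {
  stopIf(!file.exists(path), "config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  def <- defaultAuditConfig(seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
  if (!is.null(cfg$thresholds)) {
    for (nm in names(cfg$thresholds)) {
      if (!is.null(def$thresholds[[nm]]) &&
          cfg$thresholds[[nm]] != def$thresholds[[nm]])
        warning(sprintf("threshold override: %s = %s (default %s)", nm,
                        cfg$thresholds[[nm]], def$thresholds[[nm]]))
      def$thresholds[[nm]] <- cfg$thresholds[[nm]]
    }
  }
  for (nm in setdiff(names(cfg), "thresholds")) def[[nm]] <- cfg[[nm]]
  if (!is.null(def$synthetic$weights))
    def$synthetic$weights <- lapply(def$synthetic$weights, unlist)
  def
}

configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the end-to-end composition-confound audit on synthetic data
#'
#' Composes the full pipeline: generate two-cell-type references and a
#' mixed experiment with a composition shift ([generateReference()],
#' [simulateExperiment()]); simulate pure-population RNA-seq and curate
#' marker genes ([curateMarkers()]); audit composition
#' ([auditComposition()]); test differential inclusion in the mixed
#' experiment and between the pure cell types ([deltaPsiTest()],
#' [filterEvents()]); and correlate the two ([deltaDeltaCorrelation()]).
#' Within-cell-type splicing never changes in the simulation, so any
#' apparent condition effect the pipeline reports is, by construction, a
#' composition artefact — the run demonstrates that the diagnostic detects
#' it.
#'
#' @param config list as from [defaultAuditConfig()] or
#'   [readAuditConfig()], or a path to a YAML/JSON config.
#' @param outDir optional directory; when given, tables and a JSON summary
#'   are written there (expression and truth TSVs, rMATS-style counts,
#'   marker TSV, results TSVs, `summary.json`).  The summary is stamped
#'   with the config hash and seed, never with a timestamp, so identical
#'   runs are byte-identical.
#' @return list with elements `reference`, `experiment`, `markers`,
#'   `composition` ([CompositionReport-class]), `condEvents`,
#'   `cellTypeEvents`, `confound` ([ConfoundReport-class]) and `summary`.
#' @examples
#' \donttest{
#' res <- runFullAudit(defaultAuditConfig(seed = 1))
#' res$confound
#' }
#' @export
runFullAudit <- function(config = defaultAuditConfig(), outDir = NULL) {
  if (is.character(config)) config <- readAuditConfig(config)
  th <- config$thresholds
  sy <- config$synthetic
  seed <- as.integer(config$seed)

  ref <- generateReference(nGenes = sy$nGenes, nEvents = sy$nEvents,
                           markerFrac = sy$markerFrac,
                           psiDivergenceFrac = sy$psiDivergenceFrac,
                           seed = seed, minFpkm = th$minFpkm,
                           minFold = th$minFold)
  design <- MixtureDesign(conditions = names(sy$weights),
                          weights = sy$weights,
                          replicates = sy$replicates, depth = sy$depth)
  mixed <- simulateExperiment(ref, design, seed = seed,
                              exprNoiseSd = sy$exprNoiseSd)

  pureDesign <- MixtureDesign(
    conditions = c("neuron", "astrocyte"),
    weights = list(neuron = c(neuron = 1, astrocyte = 0),
                   astrocyte = c(neuron = 0, astrocyte = 1)),
    replicates = if (!is.null(sy$pureReplicates)) sy$pureReplicates else 3,
    depth = sy$depth)
  pure <- simulateExperiment(ref, pureDesign, seed = seed + 1L,
                             exprNoiseSd = sy$exprNoiseSd)

  pureConds <- rep(pureDesign@conditions, each = pureDesign@replicates)
  markers <- curateMarkers(
    exprTable(pure)[, pureConds == "neuron", drop = FALSE],
    exprTable(pure)[, pureConds == "astrocyte", drop = FALSE],
    minFpkm = th$minFpkm, minFold = th$minFold)

  conds <- rep(design@conditions, each = design@replicates)
  ctrl <- design@conditions[1]; treat <- design@conditions[2]
  markersUsed <- restrictToExpressed(markers, exprTable(mixed),
                                     conditions = conds, scope = ctrl,
                                     minFpkm = th$minFpkm)
  composition <- auditComposition(exprTable(mixed), conds, ctrl, treat,
                                  ref, markersUsed)

  condEvents <- filterEvents(
    deltaPsiTest(eventCounts(mixed), ctrl, treat, c = th$c),
    alpha = th$alpha, minAvgCount = th$minAvgCount)
  cellTypeEvents <- deltaPsiTest(eventCounts(pure), "neuron", "astrocyte",
                                 c = th$c)
  passing <- condEvents[condEvents$pass, , drop = FALSE]
  confound <- if (nrow(passing) >= 3)
    deltaDeltaCorrelation(passing, cellTypeEvents,
                          nPerm = if (!is.null(config$nPerm)) config$nPerm
                                  else 0,
                          seed = seed)
  else NULL

  wHat <- estimatedWeights(composition)
  shift <- max(abs(wHat[, 2] - wHat[, 1]))
  summary <- list(
    configHash = configHash(config), seed = seed,
    thresholds = th,
    nMarkers = nrow(markersUsed@table),
    nEventsTested = nrow(condEvents),
    nEventsPassing = sum(condEvents$pass),
    estimatedWeights = apply(wHat, 2, as.list),
    compositionShiftDetected = shift >= 0.02,
    note = if (shift < 0.02) "no composition shift detected" else
      sprintf("composition shift of %.3f in mRNA-mass weight detected",
              shift),
    r = if (is.null(confound)) NA else confound@r,
    rCI95 = if (is.null(confound)) c(NA, NA) else confound@rCI95,
    slope = if (is.null(confound)) NA else confound@slope,
    slopeCI95 = if (is.null(confound)) c(NA, NA) else confound@slopeCI95,
    pPerm = if (is.null(confound)) NA else confound@pPerm)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeExprTable(exprTable(mixed), file.path(outDir, "expression.tsv"))
    writeRmatsTable(eventCounts(mixed), file.path(outDir, "event_counts.tsv"))
    utils::write.table(
      data.frame(event_id = rownames(mixtureTruth(mixed)),
                 mixtureTruth(mixed), check.names = FALSE),
      file.path(outDir, "truth_psi.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeMarkerSet(markersUsed, file.path(outDir, "markers.tsv"))
    utils::write.table(condEvents, file.path(outDir, "diff_splice.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(confound))
      utils::write.table(confound@scatter,
                         file.path(outDir, "confound_scatter.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(reference = ref, experiment = mixed, pure = pure,
       markers = markersUsed, composition = composition,
       condEvents = condEvents, cellTypeEvents = cellTypeEvents,
       confound = confound, summary = summary)
}

#' Convert a supplementary source-data workbook to per-panel TSVs
#'
#' Reads every sheet of an xlsx workbook (one sheet per figure panel, a
#' header row of condition labels, one row per replicate) and writes one
#' TSV per sheet with `condition`, `replicate` and `value` columns in long
#' layout.  Blank cells are dropped with a count; sheets that do not parse
#' as numeric panels are passed through with a warning.  Requires the
#' `readxl` package.
#'
#' @param workbookPath path to the xlsx workbook.
#' @param outDir output directory for the TSVs (default: next to the
#'   workbook).
#' @return named list of the parsed panels (data.frames), invisibly
#'   returned alongside the written files; names are sheet names.
#' @export
convertSupplementary <- function(workbookPath,
                                 outDir = dirname(workbookPath)) {
  stopIf(!file.exists(workbookPath), "workbook not found: %s", workbookPath)
  stopIf(!requireNamespace("readxl", quietly = TRUE),
         "reading xlsx requires the 'readxl' package")
  sheets <- tryCatch(readxl::excel_sheets(workbookPath),
                     error = function(e)
                       stop(sprintf("unreadable workbook: %s (%s)",
                                    workbookPath, conditionMessage(e)),
                            call. = FALSE))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (sh in sheets) {
    tab <- as.data.frame(readxl::read_excel(workbookPath, sheet = sh))
    num <- vapply(tab, is.numeric, logical(1))
    if (!any(num)) {
      warning(sprintf("sheet '%s' has no numeric columns; passed through", sh))
      next
    }
    tab <- tab[, num, drop = FALSE]
    long <- do.call(rbind, lapply(colnames(tab), function(cond)
      data.frame(condition = cond,
                 replicate = seq_len(nrow(tab)),
                 value = tab[[cond]])))
    nBlank <- sum(is.na(long$value))
    long <- long[!is.na(long$value), , drop = FALSE]
    attr(long, "droppedBlank") <- nBlank
    out[[sh]] <- long
    utils::write.table(long,
                       file.path(outDir, paste0(gsub("[^A-Za-z0-9_.-]", "_", sh),
                                                ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

#' Recompute a figure-legend one-way ANOVA from a converted panel
#'
#' Takes a long-format panel (as produced by [convertSupplementary()] or
#' read from TSV) and runs [oneWayAnova()] across its conditions.
#'
#' @param panel data.frame with `condition` and `value` columns, or a TSV
#'   path.
#' @return list as from [oneWayAnova()].
#' @export
panelAnova <- function(panel) {
  if (is.character(panel)) panel <- utils::read.delim(panel)
  stopIf(!all(c("condition", "value") %in% colnames(panel)),
         "panel needs 'condition' and 'value' columns")
  oneWayAnova(split(panel$value, panel$condition))
}
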