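# End-to-end orchestration: simulateFixture() writes a complete synthetic
# input directory in the same TSV/GMT formats the readers consume, and
# runPipeline() drives score -> z-score -> extremes -> DEG -> PPEP (plus
# optional RDI comparison, signature overlap and survival scan) from a
# config list or YAML file, writing all stage outputs and a JSON manifest.
# Validation failures and computation failures raise distinct condition
# classes ("rdikit_validation_error" / "rdikit_computation_error") so a
# wrapper script can map them to distinct exit codes.

# Append a z(up) - z(dn) combined row for every up/dn signature pair of the
# collection present in the score matrix (pairs matched on the base name
# after stripping the _Up/_Dn suffix).
.addCombinedRows <- function(scores, collection) {
  es <- scoreValues(scores)
  dirs <- vapply(seq_len(length(collection)), function(i)
    sigDirection(collection[[i]]), character(1))
  nms <- names(collection)
  for (up in nms[dirs == "up"]) {
    base <- sub("_Up$", "", up, ignore.case = TRUE)
    dn <- nms[dirs == "dn"][
      sub("_Dn$", "", nms[dirs == "dn"], ignore.case = TRUE) == base]
    if (!up %in% rownames(es) || length(dn) != 1L ||
        !dn %in% rownames(es)) next
    comb <- zscoreValues(es[up, ]) - zscoreValues(es[dn, ])
    es <- rbind(es, matrix(comb, nrow = 1L,
                           dimnames = list(paste0(base, "_combined"),
                                           colnames(es))))
  }
  new("ScoreMatrix", scores = es, zscored = FALSE,
      params = scoreParams(scores))
}

.valStop <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("rdikit_validation_error", "rdikit_error")))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "rdikit_error")) stop(e)
    stop(errorCondition(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("rdikit_computation_error", "rdikit_error")))
  })
}

#' Write a complete synthetic fixture directory
#'
#' Generates a cohort from \code{config} and writes every input the
#' pipeline reads: \code{expression.tsv}, \code{signatures.gmt} (planted
#' signature plus its Up/Dn subsets), \code{pathways.gmt} (when a pathway
#' is planted), \code{rdi.tsv}, \code{survival.tsv} (when a survival spec
#' is present) and the ground truth (\code{truth.tsv} + sidecars).
#' Sub-seeds for the RDI, survival and decoy draws are derived from
#' \code{config@seed} by fixed offsets, so a fixture is fully determined by
#' its config.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param dir output directory (created if needed).
#' @param noise_sd measurement noise of the synthetic RDI (default 0.3).
#' @param n_decoys decoy pathways accompanying a planted pathway.
#' @return Invisibly, a named list of written paths.
#' @export
simulateFixture <- function(config, dir, noise_sd = 0.3, n_decoys = 19L) {
  stopifnot(is(config, "SimConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- makeExpression(config)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                signatures = file.path(dir, "signatures.gmt"),
                rdi = file.path(dir, "rdi.tsv"),
                truth = file.path(dir, "truth.tsv"))
  writeExpression(sim$expr, paths$expression)
  sigs <- SignatureCollection(
    c(list(sim$signature), truthSignatures(sim$truth)@signatures),
    source_label = "synthetic")
  writeGmt(sigs, paths$signatures)
  writeRdiTable(makeRdi(sim$truth, noise_sd = noise_sd,
                        seed = config@seed + 1L), paths$rdi)
  if (length(config@pathway_spec)) {
    paths$pathways <- file.path(dir, "pathways.gmt")
    writeGmt(makePathwayCollection(sim$truth, sim$expr,
                                   n_decoys = n_decoys,
                                   seed = config@seed + 3L),
             paths$pathways)
  }
  if (length(config@survival_spec)) {
    paths$survival <- file.path(dir, "survival.tsv")
    writeSurvivalTable(makeSurvival(sim$truth, config@survival_spec,
                                    seed = config@seed + 2L),
                       paths$survival)
  }
  writeSimTruth(sim$truth, paths$truth)
  invisible(paths)
}

.defaultRunConfig <- function() {
  list(paths = list(expression = NULL, signatures = NULL, pathways = NULL,
                    rdi = NULL, survival = NULL),
       platform = "intensity",
       params = list(alpha = 0.25, normalize = "range", min_set_size = 1,
                     k = 15, adj_p_max = 0.05, min_fold_change = 1.5,
                     scan = list(cut_quantiles = c(0.1, 0.9),
                                 min_frac = 0.1, alpha = 0.05, B = 200)),
       score_signature = NULL,
       seed = 1,
       out_dir = NULL,
       verbose = FALSE)
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full scoring-to-pathways pipeline
#'
#' Stages: read inputs; ssGSEA-score all signatures; z-score; (optional)
#' correlate scores with a transformed measured RDI table; select top-k /
#' bottom-k extremes on one score row; differential expression between the
#' extremes; (optional) PPEP pathway pattern matrix; (optional) pairwise
#' signature overlap; (optional) survival gradient scan. All outputs are
#' TSV plus a \code{manifest.json} echoing the resolved configuration,
#' package version, collected warnings and written files. Runs with the
#' same config are byte-identical.
#'
#' @param config a config list, or the path of a YAML file holding one.
#'   Required: \code{paths$expression}, \code{paths$signatures},
#'   \code{out_dir}. Optional paths: \code{pathways} (GMT),
#'   \code{rdi}, \code{survival}. See the package vignette for the full
#'   parameter block and defaults.
#' @param overrides named list merged over \code{config} (overrides win),
#'   mirroring command-line flag behaviour.
#' @return Invisibly, the output directory path.
#' @export
runPipeline <- function(config, overrides = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .valStop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .valStop("config must be a list or a YAML path")
  cfg <- .mergeConfig(.defaultRunConfig(), config)
  cfg <- .mergeConfig(cfg, overrides)

  # -- validation (before any computation) --
  if (is.null(cfg$out_dir)) .valStop("config requires 'out_dir'")
  for (p in c("expression", "signatures"))
    if (is.null(cfg$paths[[p]])) .valStop("config requires paths$", p)
  for (p in c("expression", "signatures", "pathways", "rdi", "survival")) {
    if (!is.null(cfg$paths[[p]]) && !file.exists(cfg$paths[[p]]))
      .valStop("input path does not exist: paths$", p, " = ",
               cfg$paths[[p]])
  }
  if (!cfg$platform %in% c("intensity", "counts"))
    .valStop("platform must be 'intensity' or 'counts'")
  if (cfg$params$k < 1) .valStop("params$k must be >= 1")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character()
  note <- function(stage, ...) {
    if (isTRUE(cfg$verbose)) message(sprintf("[%s] %s", stage,
                                             paste0(...)))
  }
  outputs <- character()
  out <- function(name) {
    f <- file.path(cfg$out_dir, name)
    outputs <<- c(outputs, f)
    f
  }

  withCallingHandlers({
    expr <- .stage("read", readExpression(cfg$paths$expression,
                                          platform = cfg$platform))
    sigs <- .stage("read", readGmt(cfg$paths$signatures))
    note("read", sprintf("%d genes x %d samples, %d signature(s)",
                         nrow(expr), ncol(expr), length(sigs)))

    params <- ssgseaParams(alpha = cfg$params$alpha,
                           normalize = cfg$params$normalize,
                           min_set_size = cfg$params$min_set_size)
    scores <- .stage("score", ssgseaScore(expr, sigs, params = params))
    scores <- .stage("score", .addCombinedRows(scores, sigs))
    writeScoreMatrix(scores, out("scores.tsv"))
    zsc <- .stage("zscore", zscoreRows(scores))
    writeScoreMatrix(zsc, out("scores_z.tsv"))
    note("score", sprintf("%d signature row(s) scored",
                          nrow(scoreValues(scores))))

    if (!is.null(cfg$paths$rdi)) {
      rdi <- .stage("rdi", readRdiTable(cfg$paths$rdi))
      tr <- .stage("rdi", transformRdiSf7(rdi))
      tabs <- c(
        stats::setNames(
          lapply(seq_len(nrow(scoreValues(zsc))), function(i)
            scoreValues(zsc)[i, ]),
          signatureNames(zsc)),
        list(RDI = tr))
      cmp <- .stage("rdi", correlationMatrix(tabs))
      cm <- data.frame(table = rownames(cmp@correlation),
                       cmp@correlation, check.names = FALSE)
      write.table(cm, out("correlation.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }

    sig_row <- cfg$score_signature
    if (is.null(sig_row)) {
      comb <- grep("_combined$", signatureNames(zsc), value = TRUE)
      sig_row <- if (length(comb)) comb[[1L]]
                 else signatureNames(zsc)[[1L]]
    }
    if (!sig_row %in% signatureNames(zsc))
      .valStop("score_signature '", sig_row, "' was not scored")
    sel <- .stage("extremes",
                  selectExtremes(scoreValues(zsc)[sig_row, ],
                                 k = cfg$params$k, score_source = sig_row))
    ext <- data.frame(
      sample = c(highSamples(sel), lowSamples(sel)),
      group = rep(c("high", "low"), each = sel@k),
      score = scoreValues(zsc)[sig_row,
                               c(highSamples(sel), lowSamples(sel))],
      stringsAsFactors = FALSE)
    write.table(ext, out("extremes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    thr <- degThresholds(cfg$params$adj_p_max, cfg$params$min_fold_change)
    deg <- .stage("dge", differentialExpression(expr, sel, thr))
    contrast <- contrastLabel("All", thr)
    writeDegList(deg, out(paste0("deg_", contrast, ".tsv")))
    note("dge", sprintf("%d DEG(s) at the thresholds", nrow(deg)))

    if (!is.null(cfg$paths$pathways)) {
      pws <- .stage("ppep", readGmt(cfg$paths$pathways))
      ppep <- .stage("ppep",
                     ppepMatrix(stats::setNames(list(deg$gene), contrast),
                                pws, expr))
      writePpepMatrix(ppep, out("ppep.tsv"))
      outputs <- c(outputs, file.path(cfg$out_dir, "ppep_long.tsv"))
    }

    if (length(sigs) >= 2L) {
      ov <- .stage("overlap", signatureOverlapMatrix(sigs, expr))
      write.table(ov, out("overlap.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }

    if (!is.null(cfg$paths$survival)) {
      surv <- .stage("survscan", readSurvivalTable(cfg$paths$survival))
      sa <- .stage("survscan",
                   gradientScan(scoreValues(zsc)[sig_row, ], surv,
                                cut_quantiles =
                                  cfg$params$scan$cut_quantiles,
                                min_frac = cfg$params$scan$min_frac,
                                alpha = cfg$params$scan$alpha,
                                B = cfg$params$scan$B,
                                seed = cfg$seed, score_name = sig_row))
      writeSurvivalAssoc(sa, out("survscan.tsv"))
      outputs <- c(outputs, file.path(cfg$out_dir, "survscan_cuts.tsv"))
    }
  }, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  manifest <- list(
    package = "rdikit",
    version = as.character(utils::packageVersion("rdikit")),
    config = cfg,
    outputs = basename(outputs),
    warnings = warn_log)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(cfg$out_dir)
}
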