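#' Run the tag-based differential expression pipeline end to end
#'
#' Orchestrates the full analysis from a structured YAML config (or an
#' equivalent R list): simulate references and libraries (optional, when
#' \code{simulate: true}), or load tag-count TSVs; build unitag libraries
#' with singlet exclusion; run the contrast panel; write contrast tables,
#' the UR/DR/NS summary, UR and DR Venn memberships; cluster DE
#' fold-change profiles into CDT/GTR; and record a JSON run manifest with
#' the config snapshot, seed, package version, input checksums and
#' per-stage row counts. Every stage writes its artifact to \code{outDir}
#' and is skipped when the artifact already exists (delete an intermediate
#' to rerun it and its dependents).
#'
#' Config keys (all optional unless noted): \code{seed}, \code{alpha}
#' (default 0.05), \code{scale} (1e6), \code{simulate} (logical),
#' \code{simulation} (arguments for [simulationConfig()]),
#' \code{libraries} (when not simulating: named map libraryId -> tag-count
#' TSV path), \code{contrasts} (list of \code{id/library_1/library_2};
#' default: the four-contrast stress design when the standard library ids
#' are present), \code{cluster_min_contrasts} (default 2).
#'
#' @param config path to a YAML config file, or a named list.
#' @param outDir output directory (required).
#' @param overwrite rerun every stage even if artifacts exist.
#' @return invisibly, a list with the manifest and the in-memory results
#'   (libraries, contrasts, summary, venn).
#' @export
runPipeline <- function(config, outDir, overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  seed <- config$seed %||% 1L
  alpha <- config$alpha %||% 0.05
  scale <- config$scale %||% 1e6
  manifest <- list(package = "sagedge",
                   version = as.character(utils::packageVersion("sagedge")),
                   seed = seed, alpha = alpha, scale = scale,
                   config = config, stages = list())
  stageDone <- function(name, ...) {
    manifest$stages[[name]] <<- c(list(completed = TRUE), list(...))
  }
  artifact <- function(f) file.path(outDir, f)

  # -- stage: acquire counts ------------------------------------------------
  countFiles <- character()
  if (isTRUE(config$simulate)) {
    simArgs <- config$simulation %||% list()
    simArgs$seed <- seed
    if (!is.null(simArgs$librarySizes))   # YAML maps arrive as lists
      simArgs$librarySizes <- unlist(simArgs$librarySizes)
    cfg <- do.call(simulationConfig, simArgs)
    refs <- simulateReferences(cfg)
    sim <- simulateLibraries(cfg, refs)
    refPaths <- writeReferences(refs, artifact("references"))
    for (lib in names(sim$counts)) {
      f <- artifact(sprintf("counts_%s.tsv", lib))
      if (overwrite || !file.exists(f)) writeTagCounts(sim$counts[[lib]], f)
      countFiles[lib] <- f
    }
    utils::write.table(sim$truth, artifact("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stageDone("simulate", n_transcripts = cfg$nTranscripts,
              libraries = names(sim$counts))
  } else {
    if (is.null(config$libraries))
      stop("config: either simulate: true or a 'libraries' map is required")
    countFiles <- unlist(config$libraries)
    missing <- countFiles[!file.exists(countFiles)]
    if (length(missing))
      stop("missing tag-count file(s): ", paste(missing, collapse = ", "))
  }
  manifest$input_checksums <- as.list(tools::md5sum(countFiles))

  # -- stage: build libraries ----------------------------------------------
  meta <- list(ET0 = c("tolerant", "control"),
               `ET1.6` = c("tolerant", "stress_bulk"),
               BT0 = c("sensitive", "control"),
               `BT1.6` = c("sensitive", "stress_bulk"))
  libraries <- list()
  for (lib in names(countFiles)) {
    counts <- readTagCounts(countFiles[[lib]])
    m <- meta[[lib]] %||% c("unknown", "unknown")
    libraries[[lib]] <- buildLibrary(counts, lib, m[1L], m[2L],
                                     excludeSinglets = TRUE)
  }
  stageDone("libraries",
            unitags = lapply(libraries, function(l) length(tagCounts(l))),
            singlets_excluded = lapply(libraries, singletsExcluded))

  # -- stage: contrasts -----------------------------------------------------
  specs <- if (!is.null(config$contrasts)) {
    do.call(rbind, lapply(config$contrasts, function(cc)
      data.frame(contrast_id = cc$id, library_1 = cc$library_1,
                 library_2 = cc$library_2, stringsAsFactors = FALSE)))
  } else if (all(c("ET0", "ET1.6", "BT0", "BT1.6") %in% names(libraries))) {
    data.frame(
      contrast_id = c("I", "II", "III", "IV"),
      library_1 = c("ET1.6", "BT1.6", "ET0", "ET1.6"),
      library_2 = c("ET0", "BT0", "BT0", "BT1.6"),
      stringsAsFactors = FALSE)
  } else stop("config: 'contrasts' required for non-standard library ids")
  contrasts <- runContrastPanel(specs, libraries, alpha = alpha,
                                scale = scale)
  for (id in names(contrasts))
    writeContrastResult(contrasts[[id]],
                        artifact(sprintf("contrast_%s.tsv", id)))
  stageDone("contrasts", rows = lapply(contrasts, nrow))

  # -- stage: summary + venn ------------------------------------------------
  summary <- summaryTable(contrasts)
  utils::write.table(summary, artifact("summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  urSets <- lapply(contrasts, function(r) r$tag[r$call == "UR"])
  drSets <- lapply(contrasts, function(r) r$tag[r$call == "DR"])
  venn <- list(UR = vennCounts(urSets), DR = vennCounts(drSets))
  vennDf <- data.frame(
    direction = rep(names(venn), vapply(venn, length, integer(1))),
    region = unlist(lapply(venn, names), use.names = FALSE),
    n = unlist(venn, use.names = FALSE))
  utils::write.table(vennDf, artifact("venn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stageDone("summary", contrasts = nrow(summary))

  # -- stage: clustering ----------------------------------------------------
  minC <- config$cluster_min_contrasts %||% 2L
  deTags <- unique(unlist(lapply(contrasts, function(r)
    r$tag[r$call %in% c("UR", "DR")])))
  if (length(deTags) >= 2L && length(contrasts) >= minC) {
    m <- fcMatrix(contrasts)
    keep <- rowSums(!is.na(m)) >= 1L
    m <- m[keep, , drop = FALSE]
    if (nrow(m) >= 2L) {
      tree <- clusterRows(m)
      writeCdtGtr(m, tree, artifact("heatmap"))
      stageDone("cluster", rows = nrow(m))
    }
  }

  manifest$completed <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, artifact("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(manifest = manifest, libraries = libraries,
                 contrasts = contrasts, summary = summary, venn = venn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
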