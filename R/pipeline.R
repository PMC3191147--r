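.configDefaults <- function() {
  list(
    seed = 1L,
    repeats = NULL, repeats_dialect = "bed",
    genes = NULL, genes_dialect = "bed",
    mean_thresh = 5, sd_thresh = 5, fdr_alpha = 0.05,
    scale = 1e6, max_mismatch = 1L,
    boot_B = 1000L, boot_scales = seq(0.5, 1.4, by = 0.1),
    linkage = "average",
    deg = NULL, deg_fc = 2, deg_p = 0.05
  )
}

#' Read a pipeline run configuration (YAML)
#'
#' Required fields: `genome` (FASTA path) and `libraries` (list of
#' `{id, path, tissue, group}` entries with group "clone" or "control").
#' Optional: `repeats`/`genes` annotation paths with their dialects,
#' thresholds (`mean_thresh`, `sd_thresh`, `fdr_alpha`), `scale`,
#' `max_mismatch`, bootstrap settings (`boot_B`, `boot_scales`,
#' `linkage`), `seed`, and per-tissue differential-expression gene lists
#' (`deg`: tissue -> TSV with columns gene, fc, p_value; intake filter
#' FC >= `deg_fc` or <= 1/`deg_fc`, p < `deg_p`).
#'
#' @param path YAML file.
#' @return Run-configuration list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(.configDefaults(), cfg)
  .validateRunConfig(cfg)
}

.validateRunConfig <- function(cfg) {
  if (is.null(cfg$genome)) stop("config: 'genome' path missing")
  if (is.null(cfg$libraries) || !length(cfg$libraries))
    stop("config: 'libraries' missing")
  libs <- cfg$libraries
  if (!is.data.frame(libs))
    libs <- do.call(rbind, lapply(libs, function(l)
      data.frame(id = l$id, path = l$path, tissue = l$tissue,
                 group = l$group, stringsAsFactors = FALSE)))
  need <- c("id", "path", "tissue", "group")
  if (!all(need %in% names(libs)))
    stop("config: each library needs id, path, tissue, group")
  if (!all(libs$group %in% c("clone", "control")))
    stop("config: library group must be 'clone' or 'control'")
  cfg$libraries <- libs
  stopifnot(cfg$mean_thresh > 0, cfg$sd_thresh > 0,
            cfg$fdr_alpha > 0, cfg$scale > 0)
  cfg
}

#' Build and export the virtual library artifacts
#'
#' Runs the in-silico digestion and writes the library TSV, fragment and
#' CpG-island BED files, site annotation TSV and an accounting summary
#' (site, fragment, NlaIII-free-interval, unique-tag, CGI-site and
#' repeat-site counts with percentages).
#'
#' @param genome FASTA path or DNAStringSet.
#' @param repeats,genes Interval data.frames or `NULL`.
#' @param outDir Output directory.
#' @param configHash,seed Reproducibility header fields.
#' @return The [VirtualTagLibrary-class], invisibly.
#' @export
buildLibraryArtifacts <- function(genome, repeats = NULL, genes = NULL,
                                  outDir, configHash = "NA", seed = NA) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  lib <- buildVirtualLibrary(genome, repeats = repeats, genes = genes)
  if (libraryStats(lib)$n_sites == 0L)
    warning("genome contains no MluI recognition sites; library is empty")
  exportLibraryTsv(lib, file.path(outDir, "library.tsv"), configHash, seed)
  fr <- virtualFragments(lib)
  fr$label <- fr$side
  writeBedIntervals(fr, file.path(outDir, "fragments.bed"))
  cg <- cgiRegions(lib)
  if (nrow(cg)) cg$label <- sprintf("CGI%04d", seq_len(nrow(cg)))
  else cg$label <- character(0)
  writeBedIntervals(cg, file.path(outDir, "cgis.bed"))
  writeResultTsv(siteAnnotation(lib), file.path(outDir, "site_annotation.tsv"),
                 configHash, seed)
  writeResultTsv(librarySummary(lib), file.path(outDir, "library_summary.tsv"),
                 configHash, seed)
  invisible(lib)
}

## DEG list intake: TSV with columns gene, fc, p_value
.readDegList <- function(path, fcThresh, pThresh) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "fc", "p_value")
  if (!all(need %in% names(df)))
    stop("DEG file needs columns gene, fc, p_value: ", path)
  keep <- (df$fc >= fcThresh | df$fc <= 1 / fcThresh) & df$p_value < pThresh
  unique(df$gene[keep])
}

#' Run the complete MMSDK analysis pipeline
#'
#' Executes: virtual-library construction, tag reading and mapping, count
#' matrices at both confidence tiers, repeat/unique partition, two-step
#' filtering, normalization, hierarchical clustering with multiscale
#' bootstrap (all libraries and per tissue), per-tissue differential
#' methylation with FDR, repeat-class Wilcoxon tests, neighbor-gene
#' grouping, and (optionally) cross-comparison with differential
#' expression gene lists. All artifacts are TSV/Newick files carrying a
#' config-hash/seed header; identical configurations give byte-identical
#' outputs.
#'
#' @param config Run configuration (list as from [readRunConfig()], or a
#'   YAML path).
#' @param outDir Output directory.
#' @return Invisibly, a list of in-memory results (library, matrices,
#'   trees, differential tables).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- .validateRunConfig(utils::modifyList(.configDefaults(), config))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- .hashConfig(config)
  seed <- config$seed
  log <- file.path(outDir, "run.log")
  logLine <- function(...) cat(..., "\n", sep = "", file = log, append = TRUE)
  cat("", file = log)
  logLine("mmsdk pipeline, package version ",
          as.character(utils::packageVersion("mmsdk")))
  logLine("config_hash=", hash, " seed=", seed)
  logLine("thresholds: mean=", config$mean_thresh, " sd=", config$sd_thresh,
          " fdr_alpha=", config$fdr_alpha, " max_mismatch=",
          config$max_mismatch, " scale=", config$scale,
          " boot_B=", config$boot_B)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- library ------------------------------------------------------------
  repeats <- if (!is.null(config$repeats))
    readRepeatAnnotation(config$repeats, config$repeats_dialect) else NULL
  genes <- if (!is.null(config$genes))
    readGeneAnnotation(config$genes, config$genes_dialect) else NULL
  lib <- stage("build-library",
    buildLibraryArtifacts(config$genome, repeats, genes, outDir, hash, seed))
  ann <- siteAnnotation(lib)

  ## ---- map ----------------------------------------------------------------
  libsDf <- config$libraries
  assignments <- stage("map", {
    reads <- lapply(seq_len(nrow(libsDf)), function(i)
      readTagSequences(libsDf$path[i], libsDf$id[i]))
    mapTags(do.call(rbind, reads), lib,
            maxMismatch = config$max_mismatch, seed = .subSeed(seed, 10L))
  })
  writeResultTsv(mappingSummary(assignments),
                 file.path(outDir, "mapping_summary.tsv"), hash, seed)

  ## ---- count --------------------------------------------------------------
  tcmHigh <- stage("count",
    buildCountMatrix(assignments, lib, "high", libraryIds = libsDf$id))
  tcmLow <- buildCountMatrix(assignments, lib, "low", libraryIds = libsDf$id)
  for (tn in c("high", "low")) {
    m <- if (tn == "high") tcmHigh else tcmLow
    df <- data.frame(site = rownames(m),
                     SummarizedExperiment::assay(m, "counts"),
                     check.names = FALSE)
    writeResultTsv(df, file.path(outDir, sprintf("counts_%s.tsv", tn)),
                   hash, seed)
  }
  empty <- countEmptySites(tcmLow)

  ## ---- partition / filter / normalize --------------------------------------
  partsHigh <- stage("partition", partitionByRepeat(tcmHigh, ann))
  partsLow <- partitionByRepeat(tcmLow, ann)
  writeResultTsv(filterReport(partsHigh$unique, config$mean_thresh,
                              config$sd_thresh),
                 file.path(outDir, "filter_report.tsv"), hash, seed)
  filtered <- stage("filter",
    filterTags(partsHigh$unique, config$mean_thresh, config$sd_thresh))
  normUnique <- stage("normalize", normalizeCounts(filtered, config$scale))
  normRepeat <- if (nrow(partsLow$repeat_))
    normalizeCounts(partsLow$repeat_, config$scale) else NULL

  ## ---- cluster --------------------------------------------------------------
  groupsVec <- stats::setNames(libsDf$group, libsDf$id)
  tissueOf <- stats::setNames(libsDf$tissue, libsDf$id)
  trees <- list()
  clusterSets <- c(list(all = colnames(normUnique)),
                   split(libsDf$id, libsDf$tissue))
  for (nm in names(clusterSets)) {
    ids <- clusterSets[[nm]]
    if (length(ids) < 3L) next
    tr <- tryCatch(
      multiscaleBootstrap(normUnique[, ids, drop = FALSE],
                          scales = config$boot_scales, B = config$boot_B,
                          seed = .subSeed(seed, 20L), linkage = config$linkage),
      error = function(e) {
        warning("clustering '", nm, "' skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(tr)) next
    trees[[nm]] <- tr
    writeNewick(tr, file.path(outDir, sprintf("cluster_%s.nwk", nm)))
    writeResultTsv(clusterTable(tr),
                   file.path(outDir, sprintf("cluster_%s.tsv", nm)),
                   hash, seed)
  }

  ## ---- differential / repeat tests / genes ---------------------------------
  diffs <- list(); repTests <- list(); neighborTabs <- list(); crossTabs <- list()
  for (t in unique(libsDf$tissue)) {
    ids <- libsDf$id[libsDf$tissue == t]
    if (length(unique(groupsVec[ids])) < 2L) next
    dres <- stage(paste0("diff-", t),
      runDifferential(filtered[, ids, drop = FALSE], groupsVec, ann,
                      alpha = config$fdr_alpha))
    diffs[[t]] <- dres
    writeResultTsv(dres, file.path(outDir, sprintf("differential_%s.tsv", t)),
                   hash, seed)
    if (!is.null(normRepeat)) {
      rt <- stage(paste0("repeat-test-", t),
        repeatClassTest(normRepeat[, ids, drop = FALSE], groupsVec))
      repTests[[t]] <- rt
      writeResultTsv(rt, file.path(outDir, sprintf("repeat_test_%s.tsv", t)),
                     hash, seed)
    }
    ng <- annotateNeighborGenes(dres)
    neighborTabs[[t]] <- ng
    writeResultTsv(ng, file.path(outDir, sprintf("neighbor_genes_%s.tsv", t)),
                   hash, seed)
    if (!is.null(config$deg) && !is.null(config$deg[[t]])) {
      if (!file.exists(config$deg[[t]]))
        stop("DEG file for tissue '", t, "' not found: ", config$deg[[t]])
      degGenes <- .readDegList(config$deg[[t]], config$deg_fc, config$deg_p)
      cc <- crossCompare(ng$gene, degGenes)
      crossTabs[[t]] <- cc
      writeResultTsv(
        data.frame(n_meth = cc$n_meth, n_deg = cc$n_deg,
                   n_overlap = cc$n_overlap,
                   overlap = paste(cc$overlap, collapse = ",")),
        file.path(outDir, sprintf("cross_compare_%s.tsv", t)), hash, seed)
    }
  }

  ## ---- run summary ----------------------------------------------------------
  s <- libraryStats(lib)
  sigRows <- lapply(names(diffs), function(t)
    data.frame(metric = sprintf("significant_sites_%s", t),
               value = sum(diffs[[t]]$significant),
               percent = formatPercent(sum(diffs[[t]]$significant),
                                       nrow(diffs[[t]]), 2)))
  summary <- rbind(
    librarySummary(lib),
    data.frame(metric = "empty_sites", value = empty$n_empty, percent = NA),
    data.frame(metric = "mappable_sites", value = s$n_sites - empty$n_empty,
               percent = empty$mappable_percent),
    data.frame(metric = "tested_sites_per_tissue", value = nrow(filtered),
               percent = NA),
    do.call(rbind, sigRows)
  )
  writeResultTsv(summary, file.path(outDir, "summary.tsv"), hash, seed)
  logLine("completed: ", nrow(libsDf), " libraries, ", s$n_sites, " sites")

  invisible(list(library = lib, assignments = assignments,
                 counts_high = tcmHigh, counts_low = tcmLow,
                 filtered = filtered, normalized = normUnique,
                 trees = trees, differential = diffs,
                 repeat_tests = repTests, neighbor_genes = neighborTabs,
                 cross_compare = crossTabs, summary = summary))
}
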