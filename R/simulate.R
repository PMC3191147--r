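#' Simulation configuration
#'
#' Defines the synthetic study: a multi-chromosome genome with planted
#' MluI sites flanked by NlaIII sites, CpG-island promoters and annotated
#' repeat/gene intervals; per-site unmethylation probabilities with a
#' tissue effect and a clone-vs-control effect at a chosen fraction of
#' sites; and Poisson-sampled 17-bp tag reads with per-base errors. The
#' default design mirrors a two-tissue, two-clone / two-control cohort.
#'
#' @param seed Master seed; all randomness derives from it.
#' @param nChroms,sitesPerChrom Genome layout (default 2 x 150 MluI sites).
#' @param gcBackground Background GC fraction (default 0.42).
#' @param flankRange Range (bp) of the planted NlaIII distance on each
#'   side of an MluI site (default 20-2000).
#' @param spacerRange Range (bp) of background between site cassettes.
#' @param cgiFraction Fraction of sites embedded in a planted CpG island.
#' @param cgiLength,cgiGc,cgiObsExp CpG-island block length, GC fraction
#'   and observed/expected CpG target (defaults 800, 0.65, 0.8).
#' @param repeatFraction Fraction of (non-CGI) sites inside a planted
#'   repeat interval.
#' @param repeatClasses Repeat class labels sampled for planted repeats.
#' @param geneFraction Fraction of sites given a downstream gene interval.
#' @param tissues,groupSizes Tissue labels and replicates per group
#'   (default 2 clones + 2 controls per tissue).
#' @param baseUnmethProb Baseline per-site unmethylation probability.
#' @param tissueFraction,tissueMultiplier Fraction of sites with a
#'   tissue-specific effect and the multiplier applied in the second
#'   tissue.
#' @param cloneFraction,cloneMultiplier Fraction of sites per tissue with
#'   a clone effect, and the rate multiplier between groups.
#' @param cloneDirection `"hyper"` (clones more methylated: clone
#'   unmethylation probability divided by the multiplier — the direction
#'   observed in cloned animals) or `"hypo"` (multiplied).
#' @param depth Expected tags per fully unmethylated site per library.
#' @param readErrorRate Per-base substitution error rate of emitted reads.
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(seed = 1L,
                             nChroms = 2L, sitesPerChrom = 150L,
                             gcBackground = 0.42,
                             flankRange = c(20L, 2000L),
                             spacerRange = c(800L, 2000L),
                             cgiFraction = 0.3, cgiLength = 800L,
                             cgiGc = 0.65, cgiObsExp = 0.8,
                             repeatFraction = 0.2,
                             repeatClasses = c("SINE/tRNA-Glu", "LINE/L1",
                                               "SINE/MIR", "LTR/ERV1"),
                             geneFraction = 0.5,
                             tissues = c("muscle", "liver"),
                             groupSizes = c(clone = 2L, control = 2L),
                             baseUnmethProb = 0.5,
                             tissueFraction = 0.3, tissueMultiplier = 0.3,
                             cloneFraction = 0.1, cloneMultiplier = 3,
                             cloneDirection = c("hyper", "hypo"),
                             depth = 50, readErrorRate = 0.005) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              sitesPerChrom = as.integer(sitesPerChrom),
              gcBackground = gcBackground, flankRange = as.integer(flankRange),
              spacerRange = as.integer(spacerRange),
              cgiFraction = cgiFraction, cgiLength = as.integer(cgiLength),
              cgiGc = cgiGc, cgiObsExp = cgiObsExp,
              repeatFraction = repeatFraction, repeatClasses = repeatClasses,
              geneFraction = geneFraction, tissues = tissues,
              groupSizes = groupSizes, baseUnmethProb = baseUnmethProb,
              tissueFraction = tissueFraction,
              tissueMultiplier = tissueMultiplier,
              cloneFraction = cloneFraction, cloneMultiplier = cloneMultiplier,
              cloneDirection = match.arg(cloneDirection),
              depth = depth, readErrorRate = readErrorRate)
  probs <- c(cfg$gcBackground, cfg$cgiFraction, cfg$repeatFraction,
             cfg$geneFraction, cfg$baseUnmethProb, cfg$tissueFraction,
             cfg$cloneFraction, cfg$readErrorRate, cfg$cgiGc)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$cloneMultiplier <= 0 || cfg$tissueMultiplier <= 0)
    stop("multipliers must be positive")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (diff(cfg$flankRange) < 0 || cfg$flankRange[1] < 20L)
    stop("flank range must be increasing and start at >= 20 bp")
  class(cfg) <- "SimulationConfig"
  cfg
}

## iid DNA with given GC fraction
.rseq <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## reduce the observed/expected CpG ratio of s toward `target` by swapping
## a fraction of CG dinucleotides to GC (GC content unchanged)
.thinCpG <- function(s, target) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  cg <- which(ch[-length(ch)] == "C" & ch[-1L] == "G")
  if (!length(cg)) return(s)
  keep <- stats::runif(length(cg)) < target
  for (i in cg[!keep]) { ch[i] <- "G"; ch[i + 1L] <- "C" }
  paste(ch, collapse = "")
}

#' Simulate a genome with planted restriction-site architecture
#'
#' Each MluI site is planted as a cassette CATG ... ACGCGT ... CATG with
#' flank distances drawn from `flankRange`, separated by background
#' sequence. A configured fraction of sites is embedded in a CpG-island
#' block satisfying the island criteria; repeat and gene intervals are
#' recorded as annotation (their base content is ordinary background —
#' downstream analysis consumes only the annotation). Because background
#' sequence can create extra motifs, the truth is defined post hoc by
#' scanning the emitted genome.
#'
#' @param config A [simulationConfig()].
#' @return list(genome = DNAStringSet, truth = list with planted-site
#'   table, realized MluI/NlaIII site tables, repeat/gene/CGI interval
#'   data.frames).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(.subSeed(config$seed, 1L), {
    chroms <- character(config$nChroms)
    names(chroms) <- sprintf("chr%d", seq_len(config$nChroms))
    planted <- list(); repeats <- list(); genes <- list(); cgis <- list()
    geneCounter <- 0L
    for (ci in seq_len(config$nChroms)) {
      chromName <- names(chroms)[ci]
      segs <- character(0)
      pos <- 0L                       # 0-based length so far
      for (si in seq_len(config$sitesPerChrom)) {
        isCgi <- stats::runif(1) < config$cgiFraction
        isRep <- !isCgi && stats::runif(1) < config$repeatFraction
        hasGene <- stats::runif(1) < config$geneFraction
        spacer <- sample(config$spacerRange[1]:config$spacerRange[2], 1L)
        segs <- c(segs, .rseq(spacer, config$gcBackground))
        pos <- pos + spacer
        if (isCgi) {
          gapL <- sample(20:200, 1L); gapR <- sample(20:200, 1L)
          core <- 4L + gapL + 6L + gapR + 4L
          pad <- max(0L, as.integer((config$cgiLength - core) / 2))
          mk <- function(n) .thinCpG(.rseq(n, config$cgiGc), config$cgiObsExp)
          block <- paste0(mk(pad), "CATG", mk(gapL), "ACGCGT", mk(gapR),
                          "CATG", mk(pad))
          cgis[[length(cgis) + 1L]] <- data.frame(
            chrom = chromName, start = pos, end = pos + nchar(block),
            stringsAsFactors = FALSE)
          mluStart <- pos + pad + 4L + gapL
          segs <- c(segs, block)
          pos <- pos + nchar(block)
        } else {
          gapL <- sample(config$flankRange[1]:config$flankRange[2], 1L)
          gapR <- sample(config$flankRange[1]:config$flankRange[2], 1L)
          block <- paste0("CATG", .rseq(gapL, config$gcBackground), "ACGCGT",
                          .rseq(gapR, config$gcBackground), "CATG")
          mluStart <- pos + 4L + gapL
          segs <- c(segs, block)
          pos <- pos + nchar(block)
        }
        if (isRep) {
          ext <- sample(20:200, 2L, replace = TRUE)
          repeats[[length(repeats) + 1L]] <- data.frame(
            chrom = chromName, start = max(0L, mluStart - ext[1]),
            end = mluStart + 6L + ext[2],
            label = sample(config$repeatClasses, 1L),
            stringsAsFactors = FALSE)
        }
        if (hasGene) {
          geneCounter <- geneCounter + 1L
          gs <- mluStart + 6L + sample(200:1000, 1L)
          genes[[length(genes) + 1L]] <- data.frame(
            chrom = chromName, start = gs, end = gs + sample(500:3000, 1L),
            label = sprintf("GENE%04d", geneCounter),
            stringsAsFactors = FALSE)
        }
        planted[[length(planted) + 1L]] <- data.frame(
          chrom = chromName, start = mluStart, is_cgi = isCgi,
          is_repeat = isRep, stringsAsFactors = FALSE)
      }
      ## terminal spacer so planted gene/repeat intervals stay inside
      segs <- c(segs, .rseq(4000L, config$gcBackground))
      chroms[ci] <- paste(segs, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(chroms)
    plantedDf <- do.call(rbind, planted)
    bindOr <- function(l, empty) if (length(l)) do.call(rbind, l) else empty
    repeatsDf <- bindOr(repeats, .emptyIntervals())
    genesDf <- bindOr(genes, .emptyIntervals())
    cgisDf <- bindOr(cgis, .emptyIntervals()[, 1:3])
    ## truth defined post hoc from the emitted sequence
    mlu <- findRestrictionSites(genome, MLUI_MOTIF, "MluI")
    nla <- findRestrictionSites(genome, NLAIII_MOTIF, "NlaIII")
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    genesDf$end <- pmin(genesDf$end, lens[genesDf$chrom])
    repeatsDf$end <- pmin(repeatsDf$end, lens[repeatsDf$chrom])
    list(genome = genome,
         truth = list(planted_sites = plantedDf, mlu_sites = mlu,
                      nla_sites = nla, repeats = repeatsDf, genes = genesDf,
                      cgis = cgisDf))
  })
}

#' Simulate per-site, per-library unmethylation probabilities
#'
#' Starts every site at the baseline probability; a tissue-specific subset
#' is scaled by the tissue multiplier in the second tissue; per tissue, a
#' differential subset is scaled by the clone effect in clone libraries
#' (`"hyper"` divides the probability, i.e. clones more methylated).
#' Probabilities are clipped to \[0, 1\]; replicates share probabilities,
#' so biological noise enters only through count sampling.
#'
#' @param truth Truth list from [simulateGenome()].
#' @param config A [simulationConfig()].
#' @return list(probs = matrix sites x libraries, design = data.frame
#'   (library_id, tissue, group, replicate), diff_sites = per-tissue list
#'   of truly differential site ids, tissue_sites = tissue-affected ids).
#' @export
simulateMethylomes <- function(truth, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  sites <- truth$mlu_sites$site_id
  n <- length(sites)
  design <- expand.grid(
    replicate = seq_len(max(config$groupSizes)),
    group = names(config$groupSizes),
    tissue = config$tissues,
    stringsAsFactors = FALSE)[, c("tissue", "group", "replicate")]
  design <- design[design$replicate <=
                     config$groupSizes[design$group], , drop = FALSE]
  design$library_id <- sprintf("%s_%s_%d", design$tissue, design$group,
                               design$replicate)
  rownames(design) <- NULL
  .withSeed(.subSeed(config$seed, 2L), {
    tissueSites <- sample(sites, round(config$tissueFraction * n))
    diffSites <- lapply(stats::setNames(config$tissues, config$tissues),
                        function(t) sample(sites,
                                           round(config$cloneFraction * n)))
    probs <- matrix(config$baseUnmethProb, n, nrow(design),
                    dimnames = list(sites, design$library_id))
    if (length(config$tissues) > 1L) {
      secondTissue <- design$tissue == config$tissues[2]
      probs[tissueSites, secondTissue] <-
        probs[tissueSites, secondTissue] * config$tissueMultiplier
    }
    for (t in config$tissues) {
      cloneLibs <- design$library_id[design$tissue == t &
                                     design$group == "clone"]
      fac <- if (config$cloneDirection == "hyper")
        1 / config$cloneMultiplier else config$cloneMultiplier
      probs[diffSites[[t]], cloneLibs] <- probs[diffSites[[t]], cloneLibs] * fac
    }
    probs[] <- pmin(pmax(probs, 0), 1)
    list(probs = probs, design = design, diff_sites = diffSites,
         tissue_sites = tissueSites)
  })
}

#' Simulate tag reads from a methylome
#'
#' Per site and library the true tag count is Poisson with mean
#' `depth * unmethylation probability`; each read is one of the site's
#' virtual tag sequences (uniformly chosen when the site has two) with
#' independent per-base substitution errors, and reads are shuffled.
#' Sites with no virtual tag (too-short fragment interiors) emit nothing
#' and are flagged inaccessible in the returned truth.
#'
#' @param methylome Output of [simulateMethylomes()].
#' @param lib The [VirtualTagLibrary-class] built on the simulated genome.
#' @param config A [simulationConfig()].
#' @return list(reads = named list of per-library data.frames (read_id,
#'   sequence, library_id), true_counts = sites x libraries matrix,
#'   accessible = logical per site).
#' @export
simulateTagReads <- function(methylome, lib, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  probs <- methylome$probs
  sites <- rownames(probs)
  allTags <- rbind(virtualTags(lib), duplicatedTags(lib))
  tagBySite <- split(allTags$sequence, allTags$mlu_site_id)
  accessible <- sites %in% names(tagBySite)
  reads <- vector("list", ncol(probs))
  names(reads) <- colnames(probs)
  trueCounts <- matrix(0L, length(sites), ncol(probs),
                       dimnames = dimnames(probs))
  .withSeed(.subSeed(config$seed, 3L), {
    for (l in colnames(probs)) {
      counts <- stats::rpois(length(sites), config$depth * probs[, l])
      counts[!accessible] <- 0L
      trueCounts[, l] <- counts
      emit <- which(counts > 0L)
      siteRep <- rep(sites[emit], counts[emit])
      seqs <- vapply(siteRep, function(s) {
        tg <- tagBySite[[s]]
        if (length(tg) == 1L) tg else sample(tg, 1L)
      }, character(1), USE.NAMES = FALSE)
      if (config$readErrorRate > 0 && length(seqs)) {
        nerr <- stats::rbinom(length(seqs), TAG_LENGTH, config$readErrorRate)
        for (i in which(nerr > 0L)) {
          posn <- sample.int(TAG_LENGTH, nerr[i])
          for (p in posn) {
            b <- substr(seqs[i], p, p)
            substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), b),
                                            1L)
          }
        }
      }
      ord <- sample.int(length(seqs))
      reads[[l]] <- data.frame(
        read_id = sprintf("%s_r%06d", l, seq_along(seqs)),
        sequence = seqs[ord], library_id = l, stringsAsFactors = FALSE)
    }
  })
  list(reads = reads, true_counts = trueCounts, accessible = accessible)
}

#' Run the full simulation: genome, library, methylomes, reads
#'
#' @param config A [simulationConfig()].
#' @return list(config, genome, truth, library, methylome, tags) where
#'   `tags` is the output of [simulateTagReads()].
#' @export
simulateMmsdkExperiment <- function(config = simulationConfig()) {
  gen <- simulateGenome(config)
  lib <- buildVirtualLibrary(gen$genome, repeats = gen$truth$repeats,
                             genes = gen$truth$genes)
  meth <- simulateMethylomes(gen$truth, config)
  tg <- simulateTagReads(meth, lib, config)
  list(config = config, genome = gen$genome, truth = gen$truth,
       library = lib, methylome = meth, tags = tg)
}

#' Write a simulated experiment to disk
#'
#' Emits genome FASTA, repeat/gene BED, per-library read FASTA and truth
#' TSVs, in the formats the pipeline readers consume.
#'
#' @param sim Output of [simulateMmsdkExperiment()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                repeats = file.path(dir, "repeats.bed"),
                genes = file.path(dir, "genes.bed"),
                truth = file.path(dir, "truth_diff_sites.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  writeBedIntervals(sim$truth$repeats, paths$repeats)
  writeBedIntervals(sim$truth$genes, paths$genes)
  td <- do.call(rbind, lapply(names(sim$methylome$diff_sites), function(t)
    data.frame(tissue = t, mlu_site_id = sim$methylome$diff_sites[[t]],
               stringsAsFactors = FALSE)))
  utils::write.table(td, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$reads <- character(0)
  for (l in names(sim$tags$reads)) {
    rd <- sim$tags$reads[[l]]
    p <- file.path(dir, paste0(l, ".fa"))
    ss <- Biostrings::DNAStringSet(rd$sequence)
    names(ss) <- rd$read_id
    Biostrings::writeXStringSet(ss, p)
    paths$reads[l] <- p
  }
  paths
}
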