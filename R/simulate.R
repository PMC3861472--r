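#' Configuration for the synthetic SuperSAGE experiment generator
#'
#' Bundles the knobs of the simulated four-library root-dehydration design:
#' a tolerant and a sensitive accession, each with an unstressed control
#' and a stress bulk pooling six stress times. Defaults mirror the study
#' conditions: per-accession sequenced-tag totals of 1,030,443 (tolerant)
#' and 1,520,843 (sensitive), split equally between control and stress
#' bulk; planted differential expression on 30 percent of transcripts
#' (matching the DE-call fraction the stress-vs-control contrast of such a
#' design produces) with |FC| drawn log-uniformly between 2 and 50 and 65
#' percent inductions; per-base substitution errors that spawn sister
#' tags.
#'
#' @param nTranscripts number of reference transcripts (default 1000).
#' @param transcriptLength min/max transcript length (default c(300, 1500)).
#' @param nChromosomeGenes number of transcripts also embedded as two-exon
#'   genes on a decoy chromosome (default \code{nTranscripts \%/\% 10}).
#' @param librarySizes named integer vector of sequenced-tag totals for
#'   ET0, ET1.6, BT0, BT1.6.
#' @param deFraction fraction of transcripts planted as differentially
#'   expressed in the stress bulks (default 0.3).
#' @param effectRange range of planted |FC| values, sampled log-uniformly
#'   (default c(2, 50)).
#' @param urFraction fraction of planted effects that are inductions
#'   (default 0.65).
#' @param timeProfile \code{"persistent"} (effect at all six stress times)
#'   or \code{"transient"} (effect at the first two times only; the bulk
#'   dilutes it 3-fold).
#' @param deMassFactor per-gene frequency-mass budget of a planted effect,
#'   relative to an average transcript (default 0.5). Effect sizes are
#'   coupled inversely to baseline abundance -- strong inductions start
#'   from rare transcripts and repressions hit abundant ones, as in real
#'   stress transcriptomes -- so that planting perturbs total library
#'   composition only mildly and planted fold changes are realized on the
#'   normalized-frequency scale.
#' @param errorRate per-base substitution probability in the 22 non-anchor
#'   positions (default 1e-3).
#' @param seed RNG seed recorded in the output (default 1).
#' @return a list of class \code{sagedgeSimConfig}.
#' @export
simulationConfig <- function(nTranscripts = 1000L,
                             transcriptLength = c(300L, 1500L),
                             nChromosomeGenes = NULL,
                             librarySizes = c(ET0 = 515222L, ET1.6 = 515221L,
                                              BT0 = 760422L, BT1.6 = 760421L),
                             deFraction = 0.3,
                             effectRange = c(2, 50),
                             urFraction = 0.65,
                             timeProfile = c("persistent", "transient"),
                             deMassFactor = 0.5,
                             errorRate = 1e-3,
                             seed = 1L) {
  timeProfile <- match.arg(timeProfile)
  if (is.null(nChromosomeGenes)) nChromosomeGenes <- nTranscripts %/% 10L
  stopifnot(deFraction >= 0, deFraction <= 1, urFraction >= 0,
            urFraction <= 1, errorRate >= 0, errorRate < 1,
            deMassFactor > 0, all(librarySizes > 0),
            all(c("ET0", "ET1.6", "BT0", "BT1.6") %in% names(librarySizes)))
  structure(list(
    nTranscripts = as.integer(nTranscripts),
    transcriptLength = as.integer(transcriptLength),
    nChromosomeGenes = as.integer(nChromosomeGenes),
    librarySizes = librarySizes, deFraction = deFraction,
    effectRange = effectRange, urFraction = urFraction,
    timeProfile = timeProfile, deMassFactor = deMassFactor,
    errorRate = errorRate,
    seed = as.integer(seed)), class = "sagedgeSimConfig")
}

.randomSeq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

#' Simulate reference transcripts and a decoy chromosome
#'
#' Generates \code{nTranscripts} random transcripts, each ending in a
#' CATG site with exactly 22 downstream bases so that 3'-most tag
#' extraction recovers a known planted tag. A subset of transcripts is
#' additionally embedded on a decoy chromosome as two-exon genes separated
#' by introns and intergenic spacers, with matching gene models, so that
#' region classification (exon / intron / border / intergenic) can be
#' exercised against known coordinates.
#'
#' @param cfg a [simulationConfig()].
#' @return list with elements \code{transcripts} (named character),
#'   \code{chromosome} (single named character), \code{models} (gene-model
#'   list, see [geneModel()]), and \code{truth}: data.frame with
#'   \code{transcript_id, tag, tag_start} (0-based start of the tag in the
#'   transcript), \code{on_chromosome}, and for embedded genes the 0-based
#'   chromosome start of the tag (\code{chrom_tag_start}, NA when the tag
#'   spans the intron or the transcript is not embedded).
#' @export
simulateReferences <- function(cfg) {
  stopifnot(inherits(cfg, "sagedgeSimConfig"))
  set.seed(cfg$seed)
  n <- cfg$nTranscripts
  lens <- sample(seq(cfg$transcriptLength[1L], cfg$transcriptLength[2L]),
                 n, replace = TRUE)
  tails <- character(n)
  repeat {  # 22-base tails define the tags; force uniqueness
    redo <- which(tails == "" | duplicated(tails))
    if (!length(redo)) break
    tails[redo] <- .randomSeq(length(redo), 22L)
  }
  bodies <- vapply(seq_len(n), function(i)
    .randomSeq(1L, lens[i] - 26L), character(1))
  transcripts <- paste0(bodies, TAG_ANCHOR, tails)
  names(transcripts) <- sprintf("TR%04d", seq_len(n))
  tags <- paste0(TAG_ANCHOR, tails)

  nGenes <- min(cfg$nChromosomeGenes, n)
  models <- list()
  chromParts <- character()
  chromTagStart <- rep(NA_integer_, n)
  pos <- 0L  # current chromosome length
  for (i in seq_len(nGenes)) {
    spacer <- .randomSeq(1L, 300L)
    intron <- .randomSeq(1L, 200L)
    tx <- transcripts[[i]]
    cut <- nchar(tx) %/% 2L
    exon1 <- substr(tx, 1L, cut)
    exon2 <- substr(tx, cut + 1L, nchar(tx))
    geneStart <- pos + 300L + 1L  # 1-based
    ex <- rbind(c(geneStart, geneStart + cut - 1L),
                c(geneStart + cut + 200L,
                  geneStart + cut + 200L + nchar(exon2) - 1L))
    colnames(ex) <- c("start", "end")
    models[[i]] <- geneModel(sprintf("G%04d", i), "chr1", ex)
    chromParts <- c(chromParts, spacer, exon1, intron, exon2)
    # the tag occupies the last 26 transcript bases; it lies fully in
    # exon 2 as long as exon 2 is at least 26 bases long
    if (nchar(exon2) >= 26L)
      chromTagStart[i] <- ex[2L, 2L] - 26L  # 0-based
    pos <- ex[2L, 2L]
  }
  chromParts <- c(chromParts, .randomSeq(1L, 300L))
  chromosome <- c(chr1 = paste(chromParts, collapse = ""))

  truth <- data.frame(
    transcript_id = names(transcripts), tag = tags,
    tag_start = lens - 26L,
    on_chromosome = seq_len(n) <= nGenes,
    chrom_tag_start = chromTagStart,
    stringsAsFactors = FALSE)
  list(transcripts = transcripts, chromosome = chromosome,
       models = models, truth = truth)
}

#' Simulate the four tag-count libraries with planted ground truth
#'
#' Draws per-library unitag counts multinomially (so each library's total
#' equals its configured size exactly) from per-transcript expected
#' frequencies. Baseline abundances are log-normal; a planted fraction of
#' transcripts is differentially expressed in the stress bulks with the
#' configured effect sizes, the bulk being an equal-weight mixture over
#' six per-time profiles. Sequencing errors convert a binomial share of
#' each tag's reads into single-base sister tags.
#'
#' @param cfg a [simulationConfig()].
#' @param refs output of [simulateReferences()] (the planted tags are
#'   taken from \code{refs$truth}).
#' @return list with \code{counts}: named list of four named integer
#'   vectors (tag -> count) keyed ET0/ET1.6/BT0/BT1.6; \code{truth}:
#'   data.frame per transcript with baseline abundance, planted |FC|,
#'   direction and the per-library expected frequencies; \code{sisters}:
#'   data.frame mapping each error-derived tag to its parent and error
#'   position.
#' @export
simulateLibraries <- function(cfg, refs) {
  stopifnot(inherits(cfg, "sagedgeSimConfig"))
  set.seed(cfg$seed + 1L)
  tags <- refs$truth$tag
  n <- length(tags)
  baseline <- stats::rlnorm(n, meanlog = 0, sdlog = 1.2)
  nDe <- round(cfg$deFraction * n)
  deIdx <- if (nDe) sample(n, nDe) else integer()
  fc <- rep(1, n)
  dirUp <- rep(NA, n)
  if (nDe) {
    mag <- exp(stats::runif(nDe, log(cfg$effectRange[1L]),
                            log(cfg$effectRange[2L])))
    up <- stats::runif(nDe) < cfg$urFraction
    fc[deIdx] <- ifelse(up, mag, 1 / mag)
    dirUp[deIdx] <- up
    # couple effect size inversely to abundance: a planted effect moves a
    # frequency mass of ~deMassFactor average transcripts, so induced
    # stress genes start rare and repressed ones are abundant, and the
    # total composition shift stays small (planted FCs are then realized
    # on the normalized-frequency scale, not swamped by renormalization)
    meanB <- exp(1.2^2 / 2)          # mean of the baseline log-normal
    jitter <- stats::rlnorm(nDe, 0, 0.3)
    relChange <- ifelse(up, mag - 1, 1 - 1 / mag)
    # mass-neutral budgets: repressed genes release in expectation exactly
    # the frequency mass the induced ones absorb
    budget <- ifelse(up, cfg$deMassFactor,
                     cfg$deMassFactor * max(1L, sum(up)) / max(1L, sum(!up)))
    baseline[deIdx] <- meanB * budget * jitter / relChange
  }
  # stress bulk = equal-weight mixture over six time profiles
  activeTimes <- if (cfg$timeProfile == "persistent") 6L else 2L
  bulkMult <- (activeTimes * fc + (6L - activeTimes)) / 6L

  expFreq <- list(
    ET0 = baseline, `ET1.6` = baseline * bulkMult,
    BT0 = baseline, `BT1.6` = baseline * bulkMult)

  counts <- list(); sisters <- list()
  for (lib in names(cfg$librarySizes)) {
    size <- cfg$librarySizes[[lib]]
    prob <- expFreq[[lib]] / sum(expFreq[[lib]])
    cnt <- as.integer(stats::rmultinom(1L, size, prob))
    names(cnt) <- tags
    if (cfg$errorRate > 0) {
      pErr <- 1 - (1 - cfg$errorRate)^22  # anchor errors break CATG upstream
      nErr <- stats::rbinom(n, cnt, pErr)
      for (i in which(nErr > 0L)) {
        cnt[i] <- cnt[i] - nErr[i]
        posns <- sample(5:26, nErr[i], replace = TRUE)
        for (p in posns) {
          old <- substr(tags[i], p, p)
          newBase <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          sis <- tags[i]
          substr(sis, p, p) <- newBase
          cnt[sis] <- if (sis %in% names(cnt)) cnt[[sis]] + 1L else 1L
          sisters[[length(sisters) + 1L]] <-
            data.frame(library = lib, parent = tags[i], sister = sis,
                       position = p - 1L, stringsAsFactors = FALSE)
        }
      }
    }
    counts[[lib]] <- cnt[cnt > 0L]
  }
  truth <- data.frame(
    transcript_id = refs$truth$transcript_id, tag = tags,
    baseline = baseline, planted_fc = fc, direction_up = dirUp,
    de = seq_len(n) %in% deIdx, stringsAsFactors = FALSE)
  for (lib in names(expFreq)) truth[[paste0("freq_", lib)]] <-
    expFreq[[lib]] / sum(expFreq[[lib]])
  sisters <- if (length(sisters)) do.call(rbind, sisters) else
    data.frame(library = character(), parent = character(),
               sister = character(), position = integer(),
               stringsAsFactors = FALSE)
  list(counts = counts, truth = truth, sisters = sisters)
}

#' Simulate a qPCR Ct table with known expression ratios
#'
#' Generates control/treatment Ct values for a target gene with a planted
#' expression ratio and shift-free reference genes: treatment target Cts
#' drop by \eqn{\log_{1+E}(ratio)} cycles; Gaussian noise is added per
#' technical replicate on top of a per-biological-replicate effect.
#'
#' @param genes character vector of target gene names.
#' @param ratios numeric vector of true treatment/control ratios (> 0),
#'   one per gene.
#' @param references reference gene names (default c("actin", "rna18s")).
#' @param efficiencies named efficiency fractions; default 1 for all.
#' @param nBio,nTech biological / technical replicates (default 3 each).
#' @param baselineCt mean control Ct (default 24).
#' @param noiseSd technical noise sd in cycles (default 0.1).
#' @param bioSd between-biological-replicate sd (default 0.05).
#' @param seed RNG seed.
#' @return list with \code{ct}: Ct data.frame (see [readCtTable()]) and
#'   \code{truth}: the planted ratios.
#' @export
simulateCtTables <- function(genes, ratios,
                             references = c("actin", "rna18s"),
                             efficiencies = NULL, nBio = 3L, nTech = 3L,
                             baselineCt = 24, noiseSd = 0.1, bioSd = 0.05,
                             seed = 1L) {
  stopifnot(length(genes) == length(ratios), all(ratios > 0))
  set.seed(seed)
  allGenes <- c(genes, references)
  if (is.null(efficiencies))
    efficiencies <- stats::setNames(rep(1, length(allGenes)), allGenes)
  shift <- stats::setNames(c(log(ratios) / log(1 + efficiencies[genes]),
                             rep(0, length(references))), allGenes)
  rows <- list()
  for (g in allGenes) for (grp in c("control", "treatment")) {
    for (b in seq_len(nBio)) {
      bioEff <- stats::rnorm(1L, 0, bioSd)
      mu <- baselineCt + bioEff -
        if (grp == "treatment") shift[[g]] else 0
      for (tr in seq_len(nTech)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, group = grp,
          bio_rep = paste0(substr(grp, 1L, 1L), b), tech_rep = tr,
          ct = mu + stats::rnorm(1L, 0, noiseSd),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(ct = do.call(rbind, rows),
       truth = stats::setNames(ratios, genes))
}

#' Write simulated references to FASTA and GFF3 files
#'
#' @param refs output of [simulateReferences()].
#' @param dir output directory (created if absent).
#' @return invisibly, named character vector of the paths written
#'   (\code{transcripts}, \code{chromosome}, \code{gff3}).
#' @export
writeReferences <- function(refs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa1 <- file.path(dir, "transcripts.fasta")
  fa2 <- file.path(dir, "chromosome.fasta")
  gff <- file.path(dir, "genes.gff3")
  writeReferenceFasta(refs$transcripts, fa1)
  writeReferenceFasta(refs$chromosome, fa2)
  lines <- c("##gff-version 3")
  for (m in refs$models) {
    span <- range(m$exons)
    lines <- c(lines,
      paste(m$target_id, "sagedge", "gene", span[1L], span[2L], ".",
            m$strand, ".", paste0("ID=", m$gene_id), sep = "\t"),
      vapply(seq_len(nrow(m$exons)), function(i)
        paste(m$target_id, "sagedge", "exon", m$exons[i, 1L],
              m$exons[i, 2L], ".", m$strand, ".",
              paste0("ID=", m$gene_id, ".e", i, ";Parent=", m$gene_id),
              sep = "\t"), character(1)))
  }
  writeLines(lines, gff)
  invisible(c(transcripts = fa1, chromosome = fa2, gff3 = gff))
}
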