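#' Amplification efficiency from a standard-curve slope
#'
#' Applies E = 10^(-1/slope) - 1, the standard conversion from the Ct vs
#' log10(dilution) regression slope. A perfect doubling reaction has slope
#' -1/log10(2) = -3.3219 and E = 1. The amplification base used in ratio
#' calculations is 1 + E.
#'
#' @param slope standard-curve slope(s), Ct per log10 dilution; must be
#'   negative.
#' @param warnRange efficiencies outside this range trigger a warning
#'   (default c(0.6, 1.1)).
#' @return efficiency fraction(s) E >= 0.
#' @examples
#' efficiencyFromSlope(-1 / log10(2))  # exactly 1
#' efficiencyFromSlope(-3.6)           # 0.8957
#' @export
efficiencyFromSlope <- function(slope, warnRange = c(0.6, 1.1)) {
  if (any(slope >= 0)) stop("standard-curve slope must be negative")
  e <- 10^(-1 / slope) - 1
  if (any(e < warnRange[1L] | e > warnRange[2L]))
    warning("efficiency outside the usual range [",
            warnRange[1L], ", ", warnRange[2L], "]")
  e
}

#' Read a Ct table
#'
#' TSV dialect: \code{gene, group, bio_rep, tech_rep, ct} with group in
#' \{control, treatment\}.
#'
#' @param path TSV file.
#' @return data.frame with those five columns.
#' @export
readCtTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "group", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(d)))
    stop("Ct table must have columns ", paste(need, collapse = ", "))
  d[need]
}

# collapse technical replicates: mean Ct per gene x group x bio_rep
.collapseTechReps <- function(ct) {
  ag <- stats::aggregate(ct$ct,
                         by = list(gene = ct$gene, group = ct$group,
                                   bio_rep = ct$bio_rep),
                         FUN = mean)
  names(ag)[4L] <- "ct"
  ag
}

# expression ratio given per-bio-rep mean Cts and a control/treatment split
.ratioFromCollapsed <- function(collapsed, target, references, bases,
                                groupOf) {
  factorOf <- function(gene) {
    g <- collapsed[collapsed$gene == gene, ]
    grp <- groupOf[as.character(g$bio_rep)]
    dct <- mean(g$ct[grp == "control"]) - mean(g$ct[grp == "treatment"])
    bases[[gene]]^dct
  }
  tf <- factorOf(target)
  rf <- vapply(references, factorOf, numeric(1))
  tf / exp(mean(log(rf)))
}

#' Efficiency-corrected relative expression ratio (REST style)
#'
#' Computes the mean relative gene expression level of a target gene in
#' treatment vs control, corrected per gene for amplification efficiency
#' and normalized against one or more reference genes. Per gene, technical
#' replicates are first averaged within biological replicate, then
#' \eqn{\Delta Ct = mean(Ct_{control}) - mean(Ct_{treatment})} and the gene
#' factor is \eqn{(1+E)^{\Delta Ct}}. The ratio is the target factor over
#' the geometric mean of the reference factors; with a single reference of
#' E = 1 this reduces to the classic \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param ct Ct table (see [readCtTable()]).
#' @param target target gene name.
#' @param references character vector of reference gene names.
#' @param efficiencies named numeric vector gene -> efficiency fraction E
#'   (default: 1 for every gene, i.e. perfect doubling).
#' @return the expression ratio (> 0; > 1 means up in treatment).
#' @export
restRatio <- function(ct, target, references, efficiencies = NULL) {
  genes <- c(target, references)
  for (g in genes) {
    sub <- ct[ct$gene == g, ]
    if (!all(c("control", "treatment") %in% sub$group))
      stop("gene '", g, "' must appear in both groups")
  }
  if (is.null(efficiencies))
    efficiencies <- stats::setNames(rep(1, length(genes)), genes)
  if (!all(genes %in% names(efficiencies)))
    stop("missing efficiency for some gene(s)")
  bases <- as.list(1 + efficiencies[genes])
  collapsed <- .collapseTechReps(ct[ct$gene %in% genes, ])
  reps <- unique(collapsed[, c("group", "bio_rep")])
  if (anyDuplicated(reps$bio_rep))
    stop("bio_rep labels must be unique across groups")
  groupOf <- stats::setNames(reps$group, as.character(reps$bio_rep))
  .ratioFromCollapsed(collapsed, target, references, bases, groupOf)
}

#' Fixed-reallocation randomization test for a REST ratio
#'
#' Significance of an expression ratio by pair-wise fixed reallocation:
#' whole biological replicates (each carrying all genes' Cts together) are
#' reassigned between control and treatment keeping the group sizes, the
#' ratio is recomputed, and the p-value is the fraction of reallocations
#' whose |log ratio| is at least the observed one (observed arrangement
#' included, so p >= 1/permutations). When the reallocation space has at
#' most \code{exhaustiveLimit} arrangements it is enumerated exhaustively;
#' otherwise \code{permutations} Monte-Carlo draws are used.
#'
#' @inheritParams restRatio
#' @param permutations Monte-Carlo draws (default 2000).
#' @param seed RNG seed for the Monte-Carlo path.
#' @param exhaustiveLimit enumerate exhaustively when
#'   \code{choose(n, n_control)} is at most this (default 10000).
#' @return list with \code{ratio}, \code{p}, \code{call} ("up", "down" or
#'   "n.s." at alpha = 0.05), \code{n_arrangements} and \code{exhaustive}.
#' @export
restRandomizationTest <- function(ct, target, references,
                                  efficiencies = NULL, permutations = 2000L,
                                  seed = NULL, exhaustiveLimit = 10000L) {
  if (permutations < 1L) stop("permutations must be >= 1")
  genes <- c(target, references)
  if (is.null(efficiencies))
    efficiencies <- stats::setNames(rep(1, length(genes)), genes)
  bases <- as.list(1 + efficiencies[genes])
  collapsed <- .collapseTechReps(ct[ct$gene %in% genes, ])
  reps <- unique(collapsed[, c("group", "bio_rep")])
  ctrlReps <- as.character(reps$bio_rep[reps$group == "control"])
  trtReps <- as.character(reps$bio_rep[reps$group == "treatment"])
  if (length(ctrlReps) < 2L || length(trtReps) < 2L)
    stop("need >= 2 biological replicates per group")
  allReps <- c(ctrlReps, trtReps)
  n1 <- length(ctrlReps)
  ratioFor <- function(ctrlSet) {
    groupOf <- stats::setNames(
      ifelse(allReps %in% ctrlSet, "control", "treatment"), allReps)
    .ratioFromCollapsed(collapsed, target, references, bases, groupOf)
  }
  obs <- ratioFor(ctrlReps)
  stat <- abs(log(obs))
  nArr <- choose(length(allReps), n1)
  if (nArr <= exhaustiveLimit) {
    sets <- utils::combn(allReps, n1, simplify = FALSE)
    stats_ <- vapply(sets, function(s) abs(log(ratioFor(s))), numeric(1))
    p <- mean(stats_ >= stat - 1e-12)
    exhaustive <- TRUE
    nUsed <- length(sets)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 1L  # observed arrangement counts
    for (b in seq_len(permutations - 1L)) {
      s <- sample(allReps, n1)
      if (abs(log(ratioFor(s))) >= stat - 1e-12) hits <- hits + 1L
    }
    p <- hits / permutations
    exhaustive <- FALSE
    nUsed <- permutations
  }
  call <- if (p < 0.05) (if (obs > 1) "up" else "down") else "n.s."
  list(ratio = obs, p = p, call = call, n_arrangements = nUsed,
       exhaustive = exhaustive)
}

#' Agreement between a SuperSAGE call and a qPCR time course
#'
#' The two platforms agree when at least one qPCR time point is
#' significant (p < 0.05) with a ratio direction matching the SuperSAGE
#' UR/DR call.
#'
#' @param sageCall "UR", "DR" or "NS".
#' @param qpcrResults list of [restRandomizationTest()] results (one per
#'   time point), or a data.frame with columns \code{ratio, p}.
#' @return logical(1).
#' @export
concordanceCheck <- function(sageCall, qpcrResults) {
  if (is.data.frame(qpcrResults)) {
    ratios <- qpcrResults$ratio; ps <- qpcrResults$p
  } else {
    ratios <- vapply(qpcrResults, `[[`, numeric(1), "ratio")
    ps <- vapply(qpcrResults, `[[`, numeric(1), "p")
  }
  if (!length(ratios)) stop("need at least one time point")
  sig <- ps < 0.05
  if (sageCall == "UR") any(sig & ratios > 1)
  else if (sageCall == "DR") any(sig & ratios < 1)
  else FALSE
}
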