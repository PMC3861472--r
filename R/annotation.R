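#' Default taxonomy tiers for best-hit preference
#'
#' Tier 1: the focal species (soybean); tier 2: related legumes; tier 3:
#' other angiosperms; tier 4: anything else. Users studying other systems
#' supply their own map.
#'
#' @return named integer vector mapping taxon label to tier.
#' @export
defaultTaxonTiers <- function() {
  c("Glycine max" = 1L,
    "Phaseolus vulgaris" = 2L, "Phaseolus coccineus" = 2L,
    "Vigna unguiculata" = 2L, "Medicago truncatula" = 2L,
    "Lotus japonicus" = 2L, "Cicer arietinum" = 2L,
    "Pisum sativum" = 2L, "Arachis hypogaea" = 2L,
    "Arabidopsis thaliana" = 3L)
}

#' Default blacklist patterns for uninformative descriptions
#' @return character vector of regular expressions (matched
#'   case-insensitively on word boundaries).
#' @export
defaultDescriptionBlacklist <- function() {
  c("unknown", "clone", "chromosome", "hypothetical", "unnamed",
    "uncharacteri[sz]ed")
}

#' Is a hit description informative?
#'
#' A description is adequate when it is non-empty and matches none of the
#' blacklist patterns (defaults: "unknown", "clone", "chromosome",
#' "hypothetical", ...; case-insensitive, word-boundary). Hits with
#' inadequate descriptions carry no usable gene/function information and
#' are down-weighted during best-hit selection.
#'
#' @param description character vector of free-text descriptions.
#' @param blacklist character vector of regex patterns.
#' @return logical vector.
#' @examples
#' isAdequate(c("lipoxygenase", "unknown mRNA", ""))
#' @export
isAdequate <- function(description,
                       blacklist = defaultDescriptionBlacklist()) {
  description[is.na(description)] <- ""
  ok <- nzchar(trimws(description))
  for (pat in blacklist)
    ok <- ok & !grepl(paste0("\\b", pat, "\\b"), description,
                      ignore.case = TRUE)
  ok
}

.hitClass <- function(adequate, hasGo) {
  # (iii) description + GO > (ii) one of the two > (i) neither
  ifelse(adequate & hasGo, 3L, ifelse(adequate | hasGo, 2L, 1L))
}

#' Select the most informative hit for a unitag
#'
#' Applies three consecutive rounds of redundancy elimination: hits with
#' both an adequate description and GO terms beat hits with only one of
#' the two, which beat hits with neither. Within the winning class, hits
#' are ranked by taxonomy tier (focal species first, then related species,
#' then other angiosperms), then alignment score, alignment length,
#' identity, and finally target id as a deterministic tie-break.
#'
#' @param hits data.frame with columns \code{target_id, description,
#'   go_terms} (semicolon-separated GO ids, "" for none), \code{taxon},
#'   \code{alignment_score, alignment_length, identity}. All rows belong
#'   to one tag.
#' @param tiers named integer vector mapping taxon to tier
#'   (default [defaultTaxonTiers()]); unlisted taxa get tier 4.
#' @param blacklist description blacklist for [isAdequate()].
#' @return the selected row (a one-row data.frame) or \code{NULL} for an
#'   empty input.
#' @export
selectBestHit <- function(hits, tiers = defaultTaxonTiers(),
                          blacklist = defaultDescriptionBlacklist()) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  adequate <- isAdequate(hits$description, blacklist)
  hasGo <- nzchar(trimws(ifelse(is.na(hits$go_terms), "", hits$go_terms)))
  cls <- .hitClass(adequate, hasGo)
  tier <- tiers[hits$taxon]
  tier[is.na(tier)] <- 4L
  ord <- order(-cls, tier, -hits$alignment_score, -hits$alignment_length,
               -hits$identity, hits$target_id)
  hits[ord[1L], , drop = FALSE]
}

#' Score an anchor hit for annotation ranking
#'
#' A surrogate for an alignment bit score that preserves the ordering
#' perfect > one-mismatch over full-length 26-mer hits.
#'
#' @param mismatches integer vector of mismatch counts.
#' @param penalty score deduction per mismatch (default 2).
#' @return integer scores, \code{26 - penalty * mismatches}.
#' @export
alignmentScore <- function(mismatches, penalty = 2L) {
  TAG_LENGTH - penalty * as.integer(mismatches)
}

#' Read an annotation table
#'
#' TSV dialect: \code{target_id, description, go_terms}
#' (semicolon-separated GO ids such as \code{GO:0005515}), \code{taxon}.
#'
#' @param path TSV file.
#' @return data.frame with those four character columns.
#' @export
readAnnotationTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("target_id", "description", "go_terms", "taxon")
  if (!all(need %in% names(d)))
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  ids <- unlist(strsplit(d$go_terms[nzchar(d$go_terms)], ";"))
  bad <- ids[!grepl("^GO:\\d{7}$", trimws(ids))]
  if (length(bad))
    warning("malformed GO id(s): ", paste(utils::head(bad, 3), collapse = ", "))
  d[need]
}

#' Summarize UR/DR calls per GO term
#'
#' For each GO term, counts the distinct unitags called UR and DR in a
#' contrast. A tag annotated with k GO terms contributes to k rows (so
#' column sums can exceed the number of distinct DE tags); NS tags
#' contribute nothing.
#'
#' @param calls named character vector: tag -> "UR"/"DR"/"NS".
#' @param annotations named list or named character vector: tag ->
#'   semicolon-separated GO ids (tags without annotation may be absent).
#' @param namespaces optional named character vector: GO id -> namespace
#'   label ("BP"/"MF"/"CC"); unlisted terms get NA.
#' @return data.frame \code{go_id, namespace, n_UR, n_DR}, one row per GO
#'   term with at least one DE tag, sorted by descending \code{n_UR + n_DR}
#'   then go_id.
#' @export
summarizeGo <- function(calls, annotations, namespaces = NULL) {
  empty <- data.frame(go_id = character(), namespace = character(),
                      n_UR = integer(), n_DR = integer(),
                      stringsAsFactors = FALSE)
  de <- names(calls)[calls %in% c("UR", "DR")]
  de <- de[de %in% names(annotations)]
  if (!length(de)) return(empty)
  rows <- lapply(de, function(tg) {
    gos <- unique(trimws(strsplit(as.character(annotations[[tg]]), ";")[[1L]]))
    gos <- gos[nzchar(gos)]
    if (!length(gos)) return(NULL)
    data.frame(go_id = gos, call = unname(calls[tg]),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  ur <- table(rows$go_id[rows$call == "UR"])
  dr <- table(rows$go_id[rows$call == "DR"])
  terms <- sort(unique(rows$go_id))
  out <- data.frame(
    go_id = terms,
    namespace = if (is.null(namespaces)) NA_character_
                else unname(namespaces[terms]),
    n_UR = as.integer(ifelse(terms %in% names(ur), ur[terms], 0L)),
    n_DR = as.integer(ifelse(terms %in% names(dr), dr[terms], 0L)),
    stringsAsFactors = FALSE)
  out <- out[order(-(out$n_UR + out$n_DR), out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
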