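revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# all anchor placements of `tag` on one strand of one reference sequence.
# Candidate windows are the CATG sites of the reference (the anchor must
# match exactly), then the 22 downstream bases are compared base-by-base.
.scanOneStrand <- function(tag, refseq, maxMismatch) {
  starts <- gregexpr(TAG_ANCHOR, refseq, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(NULL)
  starts <- starts[starts + TAG_LENGTH - 1L <= nchar(refseq)]
  if (!length(starts)) return(NULL)
  tagTail <- strsplit(substr(tag, 5L, TAG_LENGTH), "")[[1L]]
  hits <- lapply(starts, function(s) {
    win <- strsplit(substring(refseq, s + 4L, s + TAG_LENGTH - 1L), "")[[1L]]
    mm <- which(win != tagTail)
    if (length(mm) > maxMismatch) return(NULL)
    data.frame(start = s - 1L,  # 0-based
               mismatches = length(mm),
               mismatch_pos = if (length(mm)) mm[1L] + 3L else NA_integer_,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  hits
}

#' Anchor a unitag on reference sequences (one-mismatch rule)
#'
#' Places a 26-bp unitag on each reference sequence, tolerating at most
#' \code{maxMismatch} mismatches (0 or 1) in tag positions 4-25 while the
#' CATG anchor (positions 0-3) must match exactly on the aligned strand --
#' the "tolerating a single mismatch" (TSM) acceptance rule. Every
#' placement is reported; best-hit resolution happens downstream during
#' annotation.
#'
#' @param tag a valid 26-bp CATG-anchored tag.
#' @param refs named character vector of reference sequences (see
#'   [readReferenceFasta()]).
#' @param maxMismatch 0 or 1 (default 1).
#' @param strands \code{"plus_only"} (ESTs/transcripts: the paper's
#'   plus/plus rule) or \code{"both"} (genomic references, where genes lie
#'   on both strands).
#' @return data.frame with columns \code{tag, target, start} (0-based
#'   half-open interval start on the plus strand of the target),
#'   \code{strand} ("+"/"-"), \code{mismatches}, \code{mismatch_pos}
#'   (0-based position in the tag, NA for perfect hits), ordered by
#'   (target, start, strand).
#' @examples
#' tag <- paste0("CATG", strrep("A", 22))
#' ref <- c(r1 = paste0("GGGG", tag, "CCCC"))
#' matchTag(tag, ref)
#' @export
matchTag <- function(tag, refs, maxMismatch = 1L,
                     strands = c("plus_only", "both")) {
  strands <- match.arg(strands)
  stopifnot(isValidTag(tag), length(refs) > 0L, maxMismatch %in% c(0L, 1L))
  out <- list()
  for (id in names(refs)) {
    refseq <- toupper(refs[[id]])
    h <- .scanOneStrand(tag, refseq, maxMismatch)
    if (!is.null(h)) {
      h$target <- id; h$strand <- "+"
      out[[length(out) + 1L]] <- h
    }
    if (strands == "both") {
      rc <- revComp(refseq)
      h <- .scanOneStrand(tag, rc, maxMismatch)
      if (!is.null(h)) {
        # convert start on the reverse-complement back to plus-strand coords
        h$start <- nchar(refseq) - (h$start + TAG_LENGTH)
        h$target <- id; h$strand <- "-"
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out))
    return(data.frame(tag = character(), target = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), mismatch_pos = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$tag <- tag
  res <- res[order(res$target, res$start, res$strand),
             c("tag", "target", "start", "strand", "mismatches",
               "mismatch_pos")]
  rownames(res) <- NULL
  res
}

#' Read gene models from a GFF3 file
#'
#' Imports \code{gene} and \code{exon} features via
#' [rtracklayer::import()] and returns a per-gene list of exon intervals in
#' GFF3 1-based inclusive convention.
#'
#' @param path GFF3 file.
#' @return list of gene models; each element has \code{gene_id},
#'   \code{target_id}, \code{strand} and \code{exons}, a two-column matrix
#'   of 1-based inclusive \code{start, end} pairs sorted by start.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) return(list())
  parent <- vapply(ex$Parent, function(p) as.character(p)[1L], character(1))
  models <- lapply(split(seq_along(ex), parent), function(i) {
    e <- ex[i]
    ord <- order(GenomicRanges::start(e))
    list(gene_id = parent[i[1L]],
         target_id = as.character(GenomicRanges::seqnames(e))[1L],
         strand = as.character(GenomicRanges::strand(e))[1L],
         exons = cbind(start = GenomicRanges::start(e)[ord],
                       end = GenomicRanges::end(e)[ord]))
  })
  unname(models)
}

#' Build a gene model in code
#'
#' @param gene_id gene identifier.
#' @param target_id id of the reference sequence carrying the gene.
#' @param exons two-column matrix of 1-based inclusive exon intervals,
#'   non-overlapping.
#' @param strand "+" or "-".
#' @return a gene-model list as returned by [readGeneModels()].
#' @export
geneModel <- function(gene_id, target_id, exons, strand = "+") {
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("gene model '", gene_id, "': exons overlap or are unsorted")
  list(gene_id = gene_id, target_id = target_id, strand = strand,
       exons = exons)
}

#' Classify an anchor site against gene models
#'
#' Assigns the 26-nt anchored interval exactly one category:
#' \code{exon} if it lies entirely within exonic bases of an overlapping
#' gene, \code{intron} if it overlaps a gene but no exonic base,
#' \code{exon_intron_border} if it covers both exonic and non-exonic bases
#' of an overlapping gene, and \code{intergenic} if no gene model overlaps
#' it.
#'
#' @param hit one row of a [matchTag()] result (or any list with
#'   \code{target} and \code{start}, 0-based).
#' @param models list of gene models ([geneModel()] / [readGeneModels()]).
#' @return one of \code{"exon"}, \code{"intron"},
#'   \code{"exon_intron_border"}, \code{"intergenic"}.
#' @export
classifyRegion <- function(hit, models) {
  s1 <- hit$start + 1L              # 1-based inclusive interval
  e1 <- hit$start + TAG_LENGTH
  onTarget <- Filter(function(m) m$target_id == hit$target, models)
  overlapping <- Filter(function(m) {
    span <- range(m$exons)
    s1 <= span[2L] && e1 >= span[1L]
  }, onTarget)
  if (!length(overlapping)) return("intergenic")
  for (m in overlapping) {
    if (nrow(m$exons) > 1L &&
        any(m$exons[-1L, 1L] <= m$exons[-nrow(m$exons), 2L]))
      stop("gene model '", m$gene_id, "': exons overlap or are unsorted")
    cover <- sum(pmax(0L, pmin(e1, m$exons[, 2L]) -
                        pmax(s1, m$exons[, 1L]) + 1L))
    if (cover == TAG_LENGTH) return("exon")
  }
  anyExonBase <- any(vapply(overlapping, function(m)
    any(pmin(e1, m$exons[, 2L]) >= pmax(s1, m$exons[, 1L])), logical(1)))
  if (anyExonBase) "exon_intron_border" else "intron"
}

#' Partition unitags by anchoring evidence (three-set Venn)
#'
#' Splits the universe of anchored unitags into the seven exclusive regions
#' of the three-set Venn over EST, chromosome and scaffold evidence.
#'
#' @param estHits,chromHits,scaffoldHits character vectors of tag ids.
#' @return the [vennSets()] result for the three sets, named
#'   \code{est}, \code{chromosome}, \code{scaffold}.
#' @export
partitionByEvidence <- function(estHits, chromHits, scaffoldHits) {
  vennSets(list(est = estHits, chromosome = chromHits,
                scaffold = scaffoldHits))
}

#' Write anchor hits with region calls to a TSV
#'
#' @param hits a [matchTag()]-style data.frame, optionally with a
#'   \code{region} column.
#' @param path output TSV.
#' @return invisibly, \code{path}.
#' @export
writeAnchorHits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
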