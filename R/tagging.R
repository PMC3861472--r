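#' Extract 26-bp CATG-anchored tags from a nucleotide sequence
#'
#' Emulates NlaIII-based SuperSAGE tag generation: a tag is the CATG
#' restriction site plus the 22 bases immediately downstream. In
#' \code{"three_prime_most"} mode (complete digestion of the transcript)
#' only the 3'-most qualifying site yields a tag; if the 3'-most CATG has
#' fewer than 22 downstream bases the next upstream qualifying site is used.
#' In \code{"all_sites"} mode (partial digestion) every qualifying site
#' yields a tag. Candidate tags containing N are dropped.
#'
#' @param sequence a single nucleotide string over \{A,C,G,T,N\}
#'   (case-insensitive).
#' @param mode \code{"three_prime_most"} (default) or \code{"all_sites"}.
#' @return character vector of 26-bp tags (possibly empty).
#' @examples
#' extractTags("GGGGCATGACGTACGTACGTACGTACGTAC")
#' extractTags(paste0("CATGAAAACATG", strrep("T", 22)), mode = "all_sites")
#' @export
extractTags <- function(sequence, mode = c("three_prime_most", "all_sites")) {
  mode <- match.arg(mode)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  seq <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d",
                 substr(seq, bad, bad), bad))
  starts <- gregexpr(TAG_ANCHOR, seq, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(character())
  ok <- starts + TAG_LENGTH - 1L <= nchar(seq)
  starts <- starts[ok]
  if (!length(starts)) return(character())
  if (mode == "three_prime_most") starts <- starts[length(starts)]
  tags <- substring(seq, starts, starts + TAG_LENGTH - 1L)
  tags[!grepl("N", tags, fixed = TRUE)]
}

#' Aggregate sequenced tags into a unitag library
#'
#' Aggregates a multiset of sequenced 26-bp tags into unitag counts. With
#' \code{excludeSinglets = TRUE} (the default, mirroring standard SuperSAGE
#' practice) unitags seen exactly once are removed, but the library size
#' \code{totalSequenced} retains the pre-exclusion mass, which is the N used
#' for frequency normalization.
#'
#' @param tags character vector: one element per sequenced tag (repeats
#'   encode abundance). Alternatively a named integer vector of pre-counted
#'   tags.
#' @param libraryId library label, e.g. "ET0".
#' @param accession \code{"tolerant"} or \code{"sensitive"} (free-form
#'   allowed).
#' @param condition \code{"control"} or \code{"stress_bulk"}.
#' @param excludeSinglets drop unitags with count 1 (default TRUE).
#' @param verbose log the number of excluded singlets (default FALSE).
#' @return a [TagLibrary-class] object.
#' @examples
#' t1 <- paste0("CATG", strrep("A", 22)); t2 <- paste0("CATG", strrep("C", 22))
#' buildLibrary(c(t1, t1, t2), "demo")
#' @export
buildLibrary <- function(tags, libraryId, accession = "unknown",
                         condition = "unknown", excludeSinglets = TRUE,
                         verbose = FALSE) {
  if (!is.null(names(tags)) && is.numeric(tags)) {
    counts <- as.integer(tags)
    names(counts) <- names(tags)
  } else {
    stopifnot(is.character(tags))
    if (length(tags) && !all(isValidTag(tags)))
      stop("malformed tag(s): ",
           paste(utils::head(tags[!isValidTag(tags)], 3L), collapse = ", "))
    tab <- table(tags)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  if (length(counts) && !all(isValidTag(names(counts))))
    stop("malformed tag(s) in counts")
  total <- sum(as.numeric(counts))
  if (total <= 0) stop("library '", libraryId, "' is empty (totalSequenced must be > 0)")
  nSinglets <- 0L
  if (excludeSinglets) {
    singlet <- counts == 1L
    nSinglets <- sum(singlet)
    counts <- counts[!singlet]
  }
  if (verbose)
    message(sprintf("library %s: %d unitags kept, %d singlets excluded",
                    libraryId, length(counts), nSinglets))
  counts <- counts[order(names(counts))]
  new("TagLibrary", libraryId = libraryId, accession = accession,
      condition = condition, counts = counts,
      totalSequenced = as.integer(total), singletsExcluded = nSinglets)
}

#' Find sister unitags (single-base variants)
#'
#' Sister unitags differ by exactly one base at one position; they arise
#' from SNPs, alternative transcripts or sequencing errors. Pairs are found
#' with a neighbourhood-hash index (each tag is keyed 22 times, once per
#' maskable non-anchor position), so runtime is linear in the number of
#' tags rather than quadratic.
#'
#' @param unitags character vector of valid unitag sequences (a set;
#'   duplicates are removed).
#' @return data.frame with columns \code{tag_a}, \code{tag_b} (with
#'   \code{tag_a < tag_b} lexicographically), and \code{position}, the
#'   0-based index of the differing base (always >= 4: the CATG anchor is
#'   shared by construction). Rows sorted by \code{tag_a}, then
#'   \code{tag_b}.
#' @examples
#' a <- paste0("CATG", strrep("A", 22))
#' b <- paste0("CATG", "T", strrep("A", 21))
#' findSisters(c(a, b))
#' @export
findSisters <- function(unitags) {
  unitags <- unique(unitags)
  if (length(unitags) && !all(isValidTag(unitags)))
    stop("invalid tag(s) passed to findSisters")
  empty <- data.frame(tag_a = character(), tag_b = character(),
                      position = integer(), stringsAsFactors = FALSE)
  if (length(unitags) < 2L) return(empty)
  pairsA <- character(); pairsB <- character(); pos <- integer()
  # bucket tags by the 26-mer with position p masked; tags sharing a bucket
  # differ only at p (or are identical, excluded by unique() above)
  for (p in 5:TAG_LENGTH) {
    keys <- paste0(substr(unitags, 1L, p - 1L), ".",
                   substr(unitags, p + 1L, TAG_LENGTH))
    grp <- split(unitags, keys)
    grp <- grp[lengths(grp) > 1L]
    for (g in grp) {
      g <- sort(g)
      idx <- utils::combn(length(g), 2L)
      pairsA <- c(pairsA, g[idx[1L, ]])
      pairsB <- c(pairsB, g[idx[2L, ]])
      pos <- c(pos, rep(p - 1L, ncol(idx)))
    }
  }
  if (!length(pairsA)) return(empty)
  out <- data.frame(tag_a = pairsA, tag_b = pairsB, position = pos,
                    stringsAsFactors = FALSE)
  out <- out[order(out$tag_a, out$tag_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read reference sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning uppercase
#' character sequences named by the first whitespace-delimited token of each
#' FASTA header.
#'
#' @param path FASTA file (multi-record, wrapped lines allowed).
#' @return named character vector of uppercase sequences.
#' @export
readReferenceFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA record ids in ", path)
  seqs
}

#' Write reference sequences to a FASTA file
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeReferenceFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read or write a tag-count table
#'
#' The tag-count dialect is a two-column TSV with header
#' \code{tag<TAB>count}, one row per unitag.
#'
#' @param path TSV file path.
#' @return \code{readTagCounts}: named integer vector of counts.
#' @export
readTagCounts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tag", "count") %in% names(d)))
    stop("tag-count table must have columns 'tag' and 'count': ", path)
  counts <- as.integer(d$count)
  names(counts) <- d$tag
  counts
}

#' @rdname readTagCounts
#' @param counts named integer vector (names are tag sequences).
#' @export
writeTagCounts <- function(counts, path) {
  utils::write.table(
    data.frame(tag = names(counts), count = as.integer(counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
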