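#' Round half-up to a fixed number of decimals
#'
#' Base R's [round()] rounds half to even; printed summary tables in the
#' SAGE literature use conventional half-up rounding (18.083 -> 18.1).
#'
#' @param x numeric vector.
#' @param digits decimals kept (default 1).
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Summary table of UR/DR/NS counts and percentages
#'
#' Builds the classic contrast summary: counts of up-regulated,
#' down-regulated and non-significant unitags per contrast plus their
#' percentages of the contrast universe, rounded half-up to one decimal.
#'
#' @param results named list of contrast results ([runContrast()]
#'   data.frames), or a named list of count vectors
#'   \code{c(UR = , DR = , NS = )} when only the bookkeeping is wanted.
#' @return data.frame with one row per contrast and columns
#'   \code{contrast, n_UR, n_DR, n_NS, n_total, pct_UR, pct_DR, pct_NS}.
#' @examples
#' summaryTable(list(I = c(UR = 13532, DR = 7423, NS = 53878)))
#' @export
summaryTable <- function(results) {
  rows <- lapply(names(results), function(id) {
    r <- results[[id]]
    if (is.data.frame(r)) {
      n <- c(UR = sum(r$call == "UR"), DR = sum(r$call == "DR"),
             NS = sum(r$call == "NS"))
    } else {
      n <- r[c("UR", "DR", "NS")]
    }
    tot <- sum(n)
    data.frame(contrast = id,
               n_UR = unname(n["UR"]), n_DR = unname(n["DR"]),
               n_NS = unname(n["NS"]), n_total = tot,
               pct_UR = roundHalfUp(n[["UR"]] / tot * 100),
               pct_DR = roundHalfUp(n[["DR"]] / tot * 100),
               pct_NS = roundHalfUp(n[["NS"]] / tot * 100),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exclusive Venn regions of 2-4 named sets
#'
#' Computes every exclusive region of the Venn diagram over the given sets:
#' each element of the union is assigned to exactly one region according to
#' its membership signature, so region sizes always sum to the union size.
#'
#' @param sets named list of 2 to 4 character vectors.
#' @return named list of character vectors; names are membership
#'   signatures built from the set names joined by \code{"&"} (e.g.
#'   \code{"I"}, \code{"I&II"}). All \code{2^k - 1} regions are returned,
#'   empty ones as \code{character(0)}.
#' @examples
#' vennSets(list(I = c("a", "b", "c"), II = "b", IV = c("b", "c")))
#' @export
vennSets <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 4L) stop("vennSets supports 2 to 4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  # membership signature as an integer code, one bit per set
  code <- integer(length(universe))
  for (i in seq_len(k))
    code <- code + (universe %in% sets[[i]]) * 2L^(i - 1L)
  regions <- list()
  for (m in seq_len(2L^k - 1L)) {
    sig <- as.logical(bitwAnd(m, 2L^(seq_len(k) - 1L)))
    nm <- paste(names(sets)[sig], collapse = "&")
    regions[[nm]] <- universe[code == m]
  }
  regions
}

#' Sizes of Venn regions
#' @param sets named list of 2-4 character vectors (see [vennSets()]).
#' @return named integer vector of exclusive region sizes.
#' @export
vennCounts <- function(sets) {
  lengths(vennSets(sets))
}

#' Four-way characterization of annotated tags
#'
#' Partitions a tag set by annotation completeness into
#' \code{desc_and_go}, \code{desc_only}, \code{go_only} and \code{neither}
#' (the classic "with description / with GO" table layout). Tags missing
#' from the annotation map fall in \code{neither}.
#'
#' @param tags character vector of tag ids.
#' @param annotations data.frame with columns \code{tag},
#'   \code{description}, \code{go_terms} (semicolon-separated, "" for
#'   none), or a named list tag -> list(description=, go_terms=).
#' @param blacklist description blacklist for [isAdequate()].
#' @return named integer vector with the four cells and \code{total}.
#' @export
characterizeTags <- function(tags, annotations,
                             blacklist = defaultDescriptionBlacklist()) {
  tags <- unique(tags)
  if (is.data.frame(annotations)) {
    idx <- match(tags, annotations$tag)
    desc <- ifelse(is.na(idx), "", annotations$description[idx])
    gos <- ifelse(is.na(idx), "", annotations$go_terms[idx])
  } else {
    desc <- vapply(tags, function(t)
      if (t %in% names(annotations))
        as.character(annotations[[t]]$description) else "", character(1))
    gos <- vapply(tags, function(t)
      if (t %in% names(annotations))
        as.character(annotations[[t]]$go_terms) else "", character(1))
  }
  hasDesc <- isAdequate(desc, blacklist)
  hasGo <- nzchar(trimws(ifelse(is.na(gos), "", gos)))
  c(desc_and_go = sum(hasDesc & hasGo),
    desc_only   = sum(hasDesc & !hasGo),
    go_only     = sum(!hasDesc & hasGo),
    neither     = sum(!hasDesc & !hasGo),
    total       = length(tags))
}

#' Run a panel of library contrasts
#'
#' @param specs data.frame with columns \code{contrast_id, library_1,
#'   library_2}.
#' @param libraries named list of [TagLibrary-class] objects.
#' @param ... passed to [runContrast()] (alpha, scale, adjust).
#' @return named list of contrast-result data.frames, one per
#'   \code{contrast_id}.
#' @export
runContrastPanel <- function(specs, libraries, ...) {
  stopifnot(all(c("contrast_id", "library_1", "library_2") %in% names(specs)))
  out <- list()
  for (i in seq_len(nrow(specs))) {
    l1 <- specs$library_1[i]; l2 <- specs$library_2[i]
    if (l1 == l2) stop("contrast '", specs$contrast_id[i],
                       "': the two libraries must differ")
    if (!l1 %in% names(libraries) || !l2 %in% names(libraries))
      stop("contrast '", specs$contrast_id[i], "': unknown library id")
    out[[specs$contrast_id[i]]] <-
      runContrast(libraries[[l1]], libraries[[l2]], ...)
  }
  out
}

#' Write a contrast result table to TSV
#' @param result a [runContrast()] data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeContrastResult <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
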