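#' Normalize a tag count to tags per million
#'
#' @param count raw unitag count(s), \code{0 <= count <= N}.
#' @param N library size (total sequenced tags, before singlet exclusion).
#' @param scale normalization divisor target (default 1e6, tags per
#'   million).
#' @return normalized frequency, \code{count / N * scale}.
#' @examples
#' normalizeFrequency(103, 1030443)
#' @export
normalizeFrequency <- function(count, N, scale = 1e6) {
  if (any(N <= 0)) stop("library size N must be > 0")
  if (any(count < 0) || any(count > N)) stop("count must satisfy 0 <= count <= N")
  count / N * scale
}

#' Audic-Claverie significance of a two-library count difference
#'
#' Exact test for a difference between tag counts x and y observed in two
#' libraries of sizes N1 and N2. Conditional on the pooled count n = x + y,
#' y is Binomial(n, N2/(N1+N2)) under the null of equal relative abundance;
#' the two-sided p-value is twice the smaller tail probability (observed
#' outcome included), capped at 1. Tail sums come from [stats::pbinom()],
#' which is numerically stable for counts well beyond 1e6.
#'
#' @param x,y raw counts in library 1 and 2 (vectors recycle).
#' @param N1,N2 library sizes.
#' @return two-sided p-value(s) in \[0, 1\].
#' @examples
#' audicClaveriePValue(5, 0, 1e6, 1e6)   # 0.0625
#' audicClaveriePValue(10, 1, 1e6, 1e6)  # 0.01171875
#' @export
audicClaveriePValue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library sizes must be positive")
  n <- x + y
  p2 <- N2 / (N1 + N2)
  lower <- stats::pbinom(y, n, p2)                        # P(Y <= y)
  upper <- stats::pbinom(y - 1, n, p2, lower.tail = FALSE) # P(Y >= y)
  pmin(1, 2 * pmin(lower, upper))
}

#' Signed fold change of two normalized frequencies
#'
#' The fold change is the ratio R = f1'/f2' of the normalized frequencies,
#' where a zero frequency is first replaced by one (so a tag absent from
#' one library still yields a finite FC). R >= 1 is reported as is; R < 1
#' is reported as -1/R, so negative values indicate repression and |FC| is
#' always >= 1.
#'
#' @param f1,f2 normalized frequencies (tags per million), >= 0.
#' @return signed fold change(s).
#' @examples
#' foldChange(45, 0)  # 45
#' foldChange(2, 4)   # -2
#' @export
foldChange <- function(f1, f2) {
  if (any(f1 < 0) || any(f2 < 0)) stop("frequencies must be non-negative")
  f1s <- ifelse(f1 == 0, 1, f1)
  f2s <- ifelse(f2 == 0, 1, f2)
  R <- f1s / f2s
  ifelse(R >= 1, R, -1 / R)
}

#' Classify a unitag contrast as UR, DR or NS
#'
#' Up-regulated (UR) if p < alpha and FC > 1; down-regulated (DR) if
#' p < alpha and FC < -1; non-significant (NS) otherwise, including FC
#' exactly 1 and ties at p == alpha (the cut is strict).
#'
#' @param p p-value(s) in \[0, 1\].
#' @param fc signed fold change(s) with |fc| >= 1.
#' @param alpha significance level (default 0.05).
#' @return character vector over \{"UR", "DR", "NS"\}.
#' @export
classifyCall <- function(p, fc, alpha = 0.05) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  ifelse(p < alpha & fc > 1, "UR",
         ifelse(p < alpha & fc < -1, "DR", "NS"))
}

#' Compare two unitag libraries (Audic-Claverie contrast)
#'
#' Runs the full two-library contrast over the union of both libraries'
#' unitags (a tag absent from one library counts 0 there): tags-per-million
#' normalization, the exact Audic-Claverie p-value on the raw counts, the
#' signed fold change on the normalized frequencies (zero replaced by one),
#' and the UR/DR/NS call at \code{alpha}.
#'
#' @param lib1,lib2 [TagLibrary-class] objects; \code{lib1} is the
#'   numerator of the fold change (so UR means up in \code{lib1}).
#' @param alpha significance level (default 0.05).
#' @param scale normalization divisor (default 1e6).
#' @param adjust optional multiple-testing correction passed to
#'   [stats::p.adjust()] (e.g. \code{"BH"}); \code{"none"} (the default)
#'   applies no correction. Correction is an extension beyond the classic
#'   SuperSAGE workflow, which tests each unitag at raw p < 0.05.
#' @return data.frame with one row per unitag in the union:
#'   \code{tag, count_1, count_2, freq_1, freq_2, p_value, fold_change,
#'   call}, ordered by descending |fold_change|, then tag. Attributes
#'   \code{N1}, \code{N2} record the library sizes.
#' @examples
#' t1 <- paste0("CATG", strrep("A", 22)); t2 <- paste0("CATG", strrep("C", 22))
#' l1 <- buildLibrary(stats::setNames(c(50L, 3L), c(t1, t2)), "A")
#' l2 <- buildLibrary(stats::setNames(c(2L, 3L), c(t1, t2)), "B")
#' runContrast(l1, l2)
#' @export
runContrast <- function(lib1, lib2, alpha = 0.05, scale = 1e6,
                        adjust = "none") {
  stopifnot(is(lib1, "TagLibrary"), is(lib2, "TagLibrary"))
  universe <- sort(union(names(tagCounts(lib1)), names(tagCounts(lib2))))
  x <- tagCounts(lib1)[universe]; x[is.na(x)] <- 0L
  y <- tagCounts(lib2)[universe]; y[is.na(y)] <- 0L
  N1 <- totalSequenced(lib1); N2 <- totalSequenced(lib2)
  f1 <- normalizeFrequency(x, N1, scale)
  f2 <- normalizeFrequency(y, N2, scale)
  p <- audicClaveriePValue(x, y, N1, N2)
  if (!identical(adjust, "none")) p <- stats::p.adjust(p, method = adjust)
  fc <- foldChange(f1, f2)
  res <- data.frame(
    tag = universe, count_1 = as.integer(x), count_2 = as.integer(y),
    freq_1 = unname(f1), freq_2 = unname(f2), p_value = unname(p),
    fold_change = unname(fc),
    call = classifyCall(unname(p), unname(fc), alpha),
    stringsAsFactors = FALSE)
  res <- res[order(-abs(res$fold_change), res$tag), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "N1") <- N1
  attr(res, "N2") <- N2
  attr(res, "contrast") <- paste(libraryId(lib1), "vs", libraryId(lib2))
  res
}
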