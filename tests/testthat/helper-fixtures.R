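# shared fixture builders; everything is generated in code

BASES <- c("A", "C", "G", "T")

# a valid tag from a 22-character tail (padded/recycled as needed)
makeTag <- function(tail) {
  tail <- paste(rep(strsplit(tail, "")[[1]], length.out = 22), collapse = "")
  paste0("CATG", tail)
}

randomTags <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unique(vapply(seq_len(n), function(i)
    paste0("CATG", paste(sample(BASES, 22, replace = TRUE), collapse = "")),
    character(1)))
}

randomSeq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

mutateAt <- function(s, pos) {
  old <- substr(s, pos, pos)
  substr(s, pos, pos) <- sample(setdiff(BASES, old), 1)
  s
}

# O(n^2) all-pairs Hamming-1 oracle for sister detection
bruteForceSisters <- function(tags) {
  tags <- sort(unique(tags))
  out <- list()
  if (length(tags) >= 2) {
    for (i in seq_len(length(tags) - 1)) for (j in (i + 1):length(tags)) {
      a <- strsplit(tags[i], "")[[1]]; b <- strsplit(tags[j], "")[[1]]
      diff <- which(a != b)
      if (length(diff) == 1)
        out[[length(out) + 1]] <- data.frame(
          tag_a = tags[i], tag_b = tags[j], position = diff - 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(tag_a = character(), tag_b = character(),
                      position = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# direct-summation oracle for the conditional binomial two-sided p-value
bruteForceAcP <- function(x, y, N1, N2) {
  n <- x + y
  if (n == 0) return(1)
  p2 <- N2 / (N1 + N2)
  probs <- vapply(0:n, function(k)
    exp(lchoose(n, k) + k * log(p2) + (n - k) * log(1 - p2)), numeric(1))
  lower <- sum(probs[seq_len(y + 1)])          # P(Y <= y)
  upper <- sum(probs[(y + 1):(n + 1)])         # P(Y >= y)
  min(1, 2 * min(lower, upper))
}

# brute-force sliding-window Hamming scan over every offset of every
# reference, both strands; independent of the anchored index in matchTag
bruteForceMatch <- function(tag, refs, maxMismatch = 1) {
  tagChars <- strsplit(tag, "")[[1]]
  hits <- list()
  for (id in names(refs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") refs[[id]] else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(refs[[id]])))
      L <- nchar(s)
      if (L < 26) next
      chars <- strsplit(s, "")[[1]]
      for (off in seq_len(L - 25)) {
        win <- chars[off:(off + 25)]
        if (any(win[1:4] != tagChars[1:4])) next   # CATG-integrity rule
        mm <- sum(win[5:26] != tagChars[5:26])
        if (mm <= maxMismatch) {
          start <- if (strand == "+") off - 1L else L - (off - 1L) - 26L
          hits[[length(hits) + 1]] <- data.frame(
            target = id, start = start, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(target = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$target, out$start, out$strand), , drop = FALSE]
}

# naive agglomerative clustering oracle (average/complete/single linkage)
# on a precomputed distance matrix; returns sorted merge heights
bruteForceLinkageHeights <- function(d, method = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  dist2 <- function(a, b) {
    vals <- d[a, b, drop = FALSE]
    switch(method, average = mean(vals), complete = max(vals),
           single = min(vals))
  }
  while (length(active) > 1) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_len(length(active) - 1)) for (j in (i + 1):length(active)) {
      dd <- dist2(active[[i]], active[[j]])
      if (dd < bestD) { bestD <- dd; best <- c(i, j) }
    }
    heights <- c(heights, bestD)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  heights
}

# small standard four-library simulated experiment reused across tests
smallSimulation <- function(seed = 42, ...) {
  cfg <- simulationConfig(
    nTranscripts = 200L, nChromosomeGenes = 20L,
    librarySizes = c(ET0 = 20000L, ET1.6 = 20000L,
                     BT0 = 20000L, BT1.6 = 20000L),
    seed = seed, ...)
  refs <- simulateReferences(cfg)
  sim <- simulateLibraries(cfg, refs)
  list(cfg = cfg, refs = refs, sim = sim)
}

# vectorized brute-force anchoring oracle: full sliding-window Hamming scan
# via a 26 x W character matrix per strand
bruteForceMatchFast <- function(tags, refs, maxMismatch = 1) {
  mats <- list()
  for (id in names(refs)) for (strand in c("+", "-")) {
    s <- if (strand == "+") refs[[id]] else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(refs[[id]])))
    L <- nchar(s)
    if (L < 26) next
    chars <- strsplit(s, "")[[1]]
    W <- L - 25L
    mats[[paste0(id, strand)]] <- list(
      id = id, strand = strand, L = L,
      M = matrix(chars[outer(1:26, 0:(W - 1), "+")], nrow = 26))
  }
  lapply(stats::setNames(tags, tags), function(tag) {
    tagChars <- strsplit(tag, "")[[1]]
    out <- list()
    for (m in mats) {
      neq <- m$M != tagChars
      ok <- colSums(neq[1:4, , drop = FALSE]) == 0   # CATG intact
      mm <- colSums(neq[5:26, , drop = FALSE])
      hit <- which(ok & mm <= maxMismatch)
      if (length(hit)) {
        start <- if (m$strand == "+") hit - 1L else m$L - (hit - 1L) - 26L
        out[[length(out) + 1]] <- data.frame(
          target = m$id, start = start, strand = m$strand,
          mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
    if (!length(out))
      return(data.frame(target = character(), start = integer(),
                        strand = character(), mismatches = integer(),
                        stringsAsFactors = FALSE))
    o <- do.call(rbind, out)
    o <- o[order(o$target, o$start, o$strand), , drop = FALSE]
    rownames(o) <- NULL
    o
  })
}
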