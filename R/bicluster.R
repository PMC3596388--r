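#' Time-stamp transformation of gene state sequences
#'
#' Appends the time point to each gene state, so that identical states at
#' different time points never compare equal: the token at time t with state s
#' is the ordered pair (t, s). For display, tokens with t <= 9 and s <= 9 are
#' rendered as the decimal t*10 + s (so states \{3, 2, 1\} over time points
#' 1..3 render as \{13, 22, 31\}); larger indices render as "t_s" to avoid
#' decimal collisions.
#'
#' @param gsm a \linkS4class{GeneStateMatrix}.
#' @return A named list (per gene) of lists with elements \code{time},
#'   \code{state} (integer vectors) and \code{rendered} (character).
#' @export
transformStates <- function(gsm) {
  tp <- seq_along(gsm@timePoints)
  out <- lapply(seq_along(gsm@geneIds), function(g) {
    s <- gsm@states[g, ]
    list(time = tp, state = as.integer(s), rendered = renderTokens(tp, s))
  })
  names(out) <- gsm@geneIds
  out
}

#' Render (time, state) tokens for display
#'
#' @param time,state parallel integer vectors.
#' @return character vector: \code{t*10 + s} when both are single-digit,
#'   otherwise \code{"t_s"}.
#' @export
renderTokens <- function(time, state) {
  unname(ifelse(time <= 9L & state <= 9L, as.character(time * 10L + state),
                paste0(time, "_", state)))
}

# Fast Bicluster construction for hot loops: mutate a valid prototype to
# bypass per-object validity checks (thousands of biclusters per cohort).
.biclusterProto <- new("Bicluster", genes = "g", tStart = 1L, tEnd = 1L,
                       profile = 1L, score = NA_real_)

.newBicluster <- function(genes, tStart, tEnd, profile, score = NA_real_) {
  x <- .biclusterProto
  attr(x, "genes") <- genes
  attr(x, "tStart") <- tStart
  attr(x, "tEnd") <- tEnd
  attr(x, "profile") <- profile
  attr(x, "score") <- score
  x
}

# MSD radix sort of suffixes. Suffix k is (start[k], over states[gene[k], ]).
# Token key at depth d of a suffix starting at a is (a + d, state); time is
# the most significant digit, so one counting-sort pass per depth.
.msdRadixSort <- function(gene, start, states, T, Q) {
  rec <- function(idx, depth) {
    if (length(idx) <= 1L) return(idx)
    pos <- start[idx] + depth
    done <- pos > T
    out <- idx[done]                       # exhausted suffixes sort first
    idx <- idx[!done]
    if (!length(idx)) return(out)
    pos <- start[idx] + depth
    key <- pos * (Q + 1L) + states[cbind(gene[idx], pos)]
    cnt <- tabulate(key, nbins = (T + 1L) * (Q + 1L))
    for (k in which(cnt > 0L)) {
      bucket <- idx[key == k]
      out <- c(out, rec(bucket, depth + 1L))
    }
    out
  }
  rec(seq_along(gene), 0L)
}

#' Build the sorted suffix index of a gene state matrix
#'
#' Every (gene, start time) suffix of the time-stamped token sequences is
#' sorted by MSD (most-significant-digit-first) radix sort on its (time,
#' state) token keys; the longest common prefix length of each adjacent
#' sorted pair is recorded. Suffixes starting at different time points share
#' no token, hence have LCP 0.
#'
#' @param gsm a \linkS4class{GeneStateMatrix}.
#' @return A list of class \code{SuffixIndex} with components \code{gene}
#'   (integer gene index per sorted suffix), \code{start} (its start time
#'   index), \code{lcp} (\code{lcp[k]} = LCP of sorted suffixes k-1 and k;
#'   \code{lcp[1] = 0}) and \code{geneIds}.
#' @export
buildSuffixIndex <- function(gsm) {
  n <- length(gsm@geneIds)
  T <- length(gsm@timePoints)
  gene <- rep(seq_len(n), times = T)
  start <- rep(seq_len(T), each = n)
  ord <- .msdRadixSort(gene, start, gsm@states, T, gsm@Q)
  gene <- gene[ord]; start <- start[ord]
  N <- length(ord)
  lcp <- integer(N)
  if (N > 1L) for (k in 2:N) {
    if (start[k] != start[k - 1L]) next    # different first token
    a <- start[k]
    len <- T - a + 1L
    s1 <- gsm@states[gene[k - 1L], a:T]
    s2 <- gsm@states[gene[k], a:T]
    neq <- which(s1 != s2)
    lcp[k] <- if (length(neq)) neq[1L] - 1L else len
  }
  structure(list(gene = gene, start = start, lcp = lcp, geneIds = gsm@geneIds),
            class = "SuffixIndex")
}

#' Extract all maximal temporal biclusters from a gene state matrix
#'
#' A bicluster is a gene set G and a contiguous time window [a, b] such that
#' every gene in G carries an identical state profile over the window, with
#' b - a + 1 >= ml and |G| >= mo. Returned biclusters are maximal: G contains
#' every gene matching the profile (row-maximal), and neither extending the
#' window to a-1 nor to b+1 preserves G (column-maximal).
#'
#' The implementation sorts all time-stamped suffixes, computes adjacent
#' longest-common-prefix lengths, and enumerates LCP runs with a stack: each
#' run of suffixes sharing a prefix of exactly length v (split at v+1 or
#' reaching the last time point) yields the candidate (start a, window
#' [a, a+v-1], genes of the run). Candidates that can be extended to the left
#' (all member genes agree at a-1) are discarded as non-maximal.
#'
#' @param gsm a \linkS4class{GeneStateMatrix}.
#' @param ml minimum window length (>= 1).
#' @param mo minimum number of genes (>= 2).
#' @return list of \linkS4class{Bicluster}, ordered by window start, then
#'   end, then lexicographic gene set. \code{ml > T} or \code{mo > n} give an
#'   empty list.
#' @export
qlBiclustering <- function(gsm, ml = 2L, mo = 2L) {
  ml <- as.integer(ml); mo <- as.integer(mo)
  stopifnot(ml >= 1L, mo >= 2L)
  T <- length(gsm@timePoints)
  n <- length(gsm@geneIds)
  if (ml > T || mo > n) return(list())
  sx <- buildSuffixIndex(gsm)
  N <- length(sx$gene)
  lcp <- c(sx$lcp, 0L)                     # sentinel pop-all at the end
  stackV <- integer(N + 1L); stackL <- integer(N + 1L); top <- 1L
  stackV[1L] <- 0L; stackL[1L] <- 1L
  res <- list()
  for (i in 2:(N + 1L)) {
    lb <- i - 1L
    while (stackV[top] > lcp[i]) {
      v <- stackV[top]; left <- stackL[top]; top <- top - 1L
      lb <- left
      r <- i - 1L
      if (v < ml || (r - left + 1L) < mo) next
      a <- sx$start[left]
      memb <- sx$gene[left:r]
      if (a > 1L) {                        # left-extension check
        prev <- gsm@states[memb, a - 1L]
        if (all(prev == prev[1L])) next
      }
      res[[length(res) + 1L]] <- list(a = a, b = a + v - 1L, genes = memb)
    }
    if (stackV[top] < lcp[i]) {
      top <- top + 1L
      stackV[top] <- lcp[i]; stackL[top] <- lb
    }
  }
  .orderBiclusters(lapply(res, function(cand) {
    genes <- sort(gsm@geneIds[cand$genes])
    .newBicluster(genes, cand$a, cand$b,
                  gsm@states[cand$genes[1L], cand$a:cand$b, drop = TRUE])
  }))
}

.orderBiclusters <- function(bics) {
  if (!length(bics)) return(list())
  a <- vapply(bics, function(b) b@tStart, 1L)
  b <- vapply(bics, function(x) x@tEnd, 1L)
  g <- vapply(bics, function(x) paste(x@genes, collapse = ";"), "")
  bics[order(a, b, g)]
}

#' Brute-force enumeration oracle for maximal temporal biclusters
#'
#' Independent reference implementation for small instances: every window of
#' length >= ml is scanned, genes are grouped by their exact state
#' subsequence, groups below mo are dropped, and a group is kept only when
#' the same gene set is not present at a strictly containing window.
#'
#' @param gsm a \linkS4class{GeneStateMatrix} (intended for n <= 15, T <= 10).
#' @param ml minimum window length.
#' @param mo minimum gene count.
#' @return list of \linkS4class{Bicluster} in the same deterministic order as
#'   \code{\link{qlBiclustering}}.
#' @export
enumerateBiclustersOracle <- function(gsm, ml = 2L, mo = 2L) {
  T <- length(gsm@timePoints)
  cand <- list()
  for (a in seq_len(T)) for (b in a:T) {
    if (b - a + 1L < ml) next
    prof <- apply(gsm@states[, a:b, drop = FALSE], 1L, paste, collapse = ",")
    for (grp in split(seq_along(prof), prof)) {
      if (length(grp) < mo) next
      cand[[length(cand) + 1L]] <- list(a = a, b = b, genes = sort(grp))
    }
  }
  keep <- vapply(seq_along(cand), function(i) {
    ci <- cand[[i]]
    !any(vapply(cand, function(cj)
      (cj$a < ci$a || cj$b > ci$b) && cj$a <= ci$a && cj$b >= ci$b &&
        identical(cj$genes, ci$genes), TRUE))
  }, TRUE)
  cand <- cand[keep]
  key <- vapply(cand, function(x) paste(x$a, x$b, paste(x$genes, collapse = ";")), "")
  cand <- cand[!duplicated(key)]
  .orderBiclusters(lapply(cand, function(x)
    Bicluster(sort(gsm@geneIds[x$genes]), x$a, x$b,
              gsm@states[x$genes[1L], x$a:x$b])))
}
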