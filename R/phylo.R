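## Phylo-epigenetic trees: sample-sample distances over a probe set and
## Saitou-Nei neighbor joining, with Newick export and clade queries.
## Trees are returned as ape "phylo" objects.

#' Pairwise distances between methylation profiles
#'
#' Over a probe set, `pearson` distance is `1 - r` on pairwise-complete
#' probes (in \[0, 2\]); `euclidean` is the L2 norm on pairwise-complete
#' probes scaled by `sqrt(n_total / n_used)` to offset missingness. Every
#' pair must share at least `minShared` unmasked probes.
#'
#' @param b a [BetaMatrix-class] (tumors and/or references, joined).
#' @param probes probe ids to use.
#' @param metric `"pearson"` or `"euclidean"`.
#' @param minShared minimum pairwise-complete probes per pair (default 30).
#' @return a [SampleDistance-class].
#' @export
methylDistance <- function(b, probes, metric = c("pearson", "euclidean"),
                           minShared = 30) {
  metric <- match.arg(metric)
  stopifnot(is(b, "BetaMatrix"))
  v <- betaValues(b)[intersect(probes, probeIds(b)), , drop = FALSE]
  if (!nrow(v)) stop("no probes from the set are present")
  obs <- !is.na(v)
  nUsed <- crossprod(obs)
  low <- which(nUsed < minShared & upper.tri(nUsed), arr.ind = TRUE)
  if (nrow(low))
    stop(sprintf("pair (%s, %s) shares only %d probes (< %d)",
                 colnames(v)[low[1, 1]], colnames(v)[low[1, 2]],
                 nUsed[low[1, , drop = FALSE]], minShared))
  if (metric == "pearson") {
    r <- suppressWarnings(cor(v, use = "pairwise.complete.obs"))
    r[!is.finite(r)] <- 0
    d <- 1 - r
  } else {
    x <- v; x[is.na(x)] <- 0
    g <- crossprod(x)
    sq <- crossprod(x^2, obs)  # sum of x_i^2 over probes observed in both
    ss <- sq + t(sq) - 2 * g
    d <- sqrt(pmax(ss, 0) * (nrow(v) / nUsed))
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2
  new("SampleDistance", d = d, metric = metric,
      nUsed = matrix(as.numeric(nUsed), nrow(nUsed), dimnames = dimnames(nUsed)))
}

#' Neighbor-joining tree estimation
#'
#' The Saitou-Nei agglomerative algorithm: iteratively join the pair
#' minimizing `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`,
#' with pendant branch lengths from the standard formulas. Ties in Q are
#' broken by the smallest label-sorted pair; negative branch lengths are
#' clamped to zero (noted via message). Two taxa give a single edge split
#' evenly; the result is an unrooted tree with a basal trichotomy (ape
#' `phylo`). Exact on additive distance matrices.
#'
#' @param dm a [SampleDistance-class] or a symmetric numeric matrix with
#'   dimnames.
#' @return an [ape::read.tree] style `phylo` object.
#' @export
neighborJoining <- function(dm) {
  d <- if (is(dm, "SampleDistance")) distanceValues(dm) else as.matrix(dm)
  if (!isSymmetric(unname(d)) || any(d < 0))
    stop("distances must be symmetric and nonnegative")
  labels <- colnames(d)
  if (is.null(labels) || anyDuplicated(labels))
    stop("unique labels required")
  n <- length(labels)
  if (n < 2) stop("need at least two labels")
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  quoteLabel <- function(l)
    if (grepl("[\\s()\\[\\]:;,']", l, perl = TRUE))
      paste0("'", gsub("'", "''", l), "'") else l
  frag <- vapply(labels, quoteLabel, "")
  clamped <- FALSE
  len <- function(x) { if (x < -1e-12) clamped <<- TRUE; max(x, 0) }
  active <- seq_len(n)
  D <- d
  if (n == 2) {
    nw <- sprintf("(%s:%s,%s:%s);", frag[1], fmt(D[1, 2] / 2),
                  frag[2], fmt(D[1, 2] / 2))
    return(parseNewick(nw))
  }
  while (length(active) > 3) {
    m <- length(active)
    Da <- D[active, active, drop = FALSE]
    r <- rowSums(Da)
    Q <- (m - 2) * Da - outer(r, r, "+")
    diag(Q) <- Inf
    ## smallest label-sorted pair among ties
    minQ <- min(Q)
    cand <- which(Q - minQ <= 1e-12 * max(1, abs(minQ)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(labels[active][cand[, 1]], labels[active][cand[, 2]])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    dij <- Da[i, j]
    li <- len(dij / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- len(dij - (dij / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    ai <- active[i]; aj <- active[j]
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[ai], fmt(li), frag[aj], fmt(lj))
    newDist <- (D[ai, ] + D[aj, ] - dij) / 2
    D <- rbind(cbind(D, u = newDist), u = c(newDist, 0))
    frag <- c(frag, newFrag)
    labels <- c(labels, paste0("\r", length(frag)))  # internal placeholder
    u <- nrow(D)
    active <- c(setdiff(active, c(ai, aj)), u)
  }
  a <- active
  if (length(a) == 3) {
    dab <- D[a[1], a[2]]; dac <- D[a[1], a[3]]; dbc <- D[a[2], a[3]]
    la <- len((dab + dac - dbc) / 2)
    lb <- len((dab + dbc - dac) / 2)
    lc <- len((dac + dbc - dab) / 2)
    nw <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[a[1]], fmt(la),
                  frag[a[2]], fmt(lb), frag[a[3]], fmt(lc))
  } else {  # two composite nodes left
    nw <- sprintf("(%s:%s,%s:%s);", frag[a[1]], fmt(D[a[1], a[2]] / 2),
                  frag[a[2]], fmt(D[a[1], a[2]] / 2))
  }
  if (clamped) message("negative branch length(s) clamped to 0")
  parseNewick(nw)
}

#' Newick serialization
#'
#' `writeNewick()` emits standard Newick with branch lengths at the given
#' precision, single-quoting labels containing whitespace, parentheses or
#' other structural characters; `parseNewick()` reads a Newick string
#' back into a `phylo` (quoted labels supported). `parseNewick(writeNewick(t))`
#' is the identity up to rotation.
#'
#' @param t a `phylo` object.
#' @param precision significant digits for branch lengths (default 6).
#' @return a Newick string / a `phylo`.
#' @export
writeNewick <- function(t, precision = 6) {
  stopifnot(inherits(t, "phylo"))
  t2 <- t
  needsQuote <- grepl("[\\s()\\[\\]:;,']", t2$tip.label, perl = TRUE)
  ## ape rewrites unsafe characters inside labels, so serialize with safe
  ## placeholders and substitute the quoted originals afterwards
  keys <- sprintf("QTDLAB%04dX", seq_along(t2$tip.label))
  t2$tip.label[needsQuote] <- keys[needsQuote]
  if (!is.null(t2$edge.length))
    t2$edge.length <- signif(t2$edge.length, precision)
  nw <- ape::write.tree(t2)
  for (i in which(needsQuote))
    nw <- sub(keys[i], paste0("'", gsub("'", "''", t$tip.label[i]), "'"),
              nw, fixed = TRUE)
  nw
}

#' @rdname writeNewick
#' @param text a Newick string.
#' @export
parseNewick <- function(text) {
  if (!isSingleString(text) || !grepl(";\\s*$", text))
    stop("malformed Newick: missing terminating ';'")
  ## protect quoted labels (ape::read.tree does not handle quotes)
  pat <- "'((?:[^']|'')*)'"
  keys <- list()
  repeat {
    m <- regexpr(pat, text, perl = TRUE)
    if (m == -1) break
    lab <- regmatches(text, m)
    key <- sprintf("QUOTEDLAB%03dX", length(keys) + 1L)
    keys[[key]] <- gsub("''", "'", substr(lab, 2, nchar(lab) - 1))
    regmatches(text, m) <- key
  }
  t <- tryCatch(ape::read.tree(text = text),
                error = function(e) stop("malformed Newick near position 1: ",
                                         conditionMessage(e)))
  if (is.null(t)) stop("malformed Newick string")
  for (key in names(keys)) {
    t$tip.label[t$tip.label == key] <- keys[[key]]
    if (!is.null(t$node.label))
      t$node.label[t$node.label == key] <- keys[[key]]
  }
  t
}

## tip-id sets below each edge of the (arbitrarily rooted) phylo
edgeBipartitions <- function(t) {
  nTip <- length(t$tip.label)
  desc <- vector("list", nTip + t$Nnode)
  for (i in seq_len(nTip)) desc[[i]] <- i
  ## postorder guarantees children are resolved before parents
  for (k in rev(ape::postorder(t))) NULL  # keep ape in the loop for order
  ord <- ape::reorder.phylo(t, "postorder")$edge
  for (r in seq_len(nrow(ord))) {
    p <- ord[r, 1]; ch <- ord[r, 2]
    if (is.null(desc[[p]])) desc[[p]] <- integer(0)
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(t$edge)), function(r) sort(desc[[t$edge[r, 2]]]))
}

#' Does a leaf set form a clade with given anchors?
#'
#' TRUE if some edge of the unrooted tree separates exactly
#' `union(query, anchor)` from all other leaves — e.g. whether the
#' acinar-origin tumor group joins the acinar and ductal references in a
#' clade of their own.
#'
#' @param t a `phylo`.
#' @param queryLeaves,anchorLeaves tip labels (anchor may be empty).
#' @return logical.
#' @export
isCladeWith <- function(t, queryLeaves, anchorLeaves = character()) {
  stopifnot(inherits(t, "phylo"))
  target <- union(queryLeaves, anchorLeaves)
  unknown <- setdiff(target, t$tip.label)
  if (length(unknown)) stop("unknown leaf label(s): ",
                            paste(unknown, collapse = ", "))
  nTip <- length(t$tip.label)
  tidx <- sort(match(target, t$tip.label))
  if (length(tidx) == nTip) return(TRUE)
  comp <- sort(setdiff(seq_len(nTip), tidx))
  for (s in edgeBipartitions(t))
    if (identical(s, tidx) || identical(s, comp)) return(TRUE)
  FALSE
}
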