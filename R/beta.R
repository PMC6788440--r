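## Sorensen-family beta diversity partitioned into turnover and nestedness,
## pairwise and multiple-site, plus neighbor-joining clustering of sites.

.asIncidence <- function(x) {
  if (is(x, "CommunityMatrix")) return(incidence(x))
  m <- as.matrix(x)
  if (is.numeric(m)) m <- m > 0
  storage.mode(m) <- "logical"
  if (is.null(rownames(m))) rownames(m) <- paste0("site", seq_len(nrow(m)))
  m
}

#' Pairwise beta-diversity partition
#'
#' For every pair of sites, the Sorensen dissimilarity and its partition
#' into turnover and nestedness-resultant components. With `a` shared
#' species and `b`, `c` species exclusive to either site:
#' `sim = min(b, c) / (a + min(b, c))` (Simpson dissimilarity, pure
#' turnover), `sor = (b + c) / (2a + b + c)`, and `sne = sor - sim`.
#' A pair of two empty sites is undefined and reported as `NA` (never a
#' silent 0, which would corrupt downstream clustering).
#'
#' @param x a [CommunityMatrix-class], or a sites x species matrix
#'   (numeric counts or logical presence).
#' @param ... unused.
#' @return list of three symmetric matrices `sor`, `sim`, `sne` with zero
#'   diagonals.
#' @examples
#' m <- rbind(s1 = c(1, 1, 1, 0), s2 = c(1, 0, 0, 1))
#' pairwisePartition(m)
#' @export
setMethod("pairwisePartition", "ANY", function(x, ...) {
  inc <- .asIncidence(x)
  n <- nrow(inc)
  if (n < 2) stop("pairwise partition needs at least two sites",
                  call. = FALSE)
  lab <- rownames(inc)
  sor <- sim <- sne <- matrix(0, n, n, dimnames = list(lab, lab))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sum(inc[i, ] & inc[j, ])
    b <- sum(inc[i, ] & !inc[j, ])
    cc <- sum(!inc[i, ] & inc[j, ])
    if (a + b + cc == 0) {
      sor[i, j] <- sor[j, i] <- NA_real_
      sim[i, j] <- sim[j, i] <- NA_real_
      sne[i, j] <- sne[j, i] <- NA_real_
      next
    }
    mn <- min(b, cc)
    s_sim <- if (a + mn > 0) mn / (a + mn) else 0
    s_sor <- (b + cc) / (2 * a + b + cc)
    sim[i, j] <- sim[j, i] <- s_sim
    sor[i, j] <- sor[j, i] <- s_sor
    sne[i, j] <- sne[j, i] <- s_sor - s_sim
  }
  list(sor = sor, sim = sim, sne = sne)
})

#' Multiple-site beta-diversity partition
#'
#' The multiple-site Sorensen dissimilarity of a set of sites and its
#' partition into turnover and nestedness. With `S_i` the richness of site
#' `i`, `S_T` the pooled richness and `b_ij` the number of species present
#' in `i` but not `j`:
#' \deqn{\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij}, b_{ji})}
#'   {\sum_i S_i - S_T + \sum_{i<j}\min(b_{ij}, b_{ji})}}
#' \deqn{\beta_{SOR} = \frac{\sum_{i<j}\min + \sum_{i<j}\max}
#'   {2(\sum_i S_i - S_T) + \sum_{i<j}\min + \sum_{i<j}\max}}
#' and `beta_sne = beta_sor - beta_sim`. Empty sites are excluded with a
#' warning. For two sites the result coincides with the pairwise partition.
#'
#' @param x a [CommunityMatrix-class] or a sites x species matrix. Pass one
#'   mountain at a time (see [subsetMountain()]).
#' @param ... unused.
#' @return a [BetaPartition-class] with `scope = "multisite"`.
#' @export
setMethod("multisitePartition", "ANY", function(x, ...) {
  inc <- .asIncidence(x)
  empty <- rowSums(inc) == 0
  if (any(empty)) {
    warning("excluding ", sum(empty), " site(s) with no species: ",
            paste(rownames(inc)[empty], collapse = ", "), call. = FALSE)
    inc <- inc[!empty, , drop = FALSE]
  }
  n <- nrow(inc)
  if (n < 2) stop("multiple-site partition needs at least two non-empty sites",
                  call. = FALSE)
  Si <- rowSums(inc)
  ST <- sum(colSums(inc) > 0)
  smin <- smax <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    bij <- sum(inc[i, ] & !inc[j, ])
    bji <- sum(!inc[i, ] & inc[j, ])
    smin <- smin + min(bij, bji)
    smax <- smax + max(bij, bji)
  }
  core <- sum(Si) - ST
  sim <- if (core + smin > 0) smin / (core + smin) else 0
  sor <- if (2 * core + smin + smax > 0)
    (smin + smax) / (2 * core + smin + smax) else 0
  new("BetaPartition", sor = sor, sim = sim, sne = sor - sim,
      scope = "multisite", sites = rownames(inc))
})

## ---- neighbor-joining ---------------------------------------------------

#' Neighbor-joining tree from a site distance matrix
#'
#' Standard neighbor-joining agglomeration (Q-criterion minimization with
#' the usual branch-length and distance updates), used to cluster trapping
#' locations from pairwise Sorensen dissimilarities. Ties in the Q
#' criterion are broken deterministically by the lexicographic order of the
#' joined clusters' smallest leaf labels, so equal-distance inputs yield
#' label-ordered cherries. Negative branch lengths — possible for
#' non-additive dissimilarities — are clamped to zero with a warning; the
#' unclamped tree is retained in the `"rawNewick"` attribute. On an
#' additive (tree-metric) input the generating topology and branch lengths
#' are recovered exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal and site labels
#'   (or a `dist`); at least three sites; `NA` entries are not allowed.
#' @return an unrooted `phylo` tree (see \pkg{ape}), with attributes
#'   `"rawNewick"` (pre-clamping Newick) and `"nNegative"` (number of
#'   clamped branches).
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' njTree(d)  # branch lengths 1, 2, 3
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor-joining needs at least three sites",
                  call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("site", seq_len(n))
  if (anyNA(d))
    stop("distance matrix contains NA (undefined pairs); resolve them first",
         call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(diag(d) != 0))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)

  labs <- rownames(d)          # representative (smallest) leaf label
  sub <- labs                  # growing Newick substrings
  raw_neg <- 0L
  fmt <- function(x) sprintf("%.10g", x)

  while (length(labs) > 3) {
    m <- length(labs)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ## deterministic tie-break: lexicographic on the pair of representatives
    key <- apply(cand, 1, function(ij) {
      pr <- sort(c(labs[ij[1]], labs[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0 || lj < 0) raw_neg <- raw_neg + sum(c(li, lj) < 0)
    node <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":", fmt(lj), ")")
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    labs <- c(labs[keep], min(labs[c(i, j)]))
    sub <- c(sub[keep], node)
    dimnames(d2) <- list(labs, labs)
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (any(c(la, lb, lc) < 0)) raw_neg <- raw_neg + sum(c(la, lb, lc) < 0)
  raw <- paste0("(", sub[1], ":", fmt(la), ",", sub[2], ":", fmt(lb), ",",
                sub[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = raw)
  if (any(tree$edge.length < 0)) {
    warning(sum(tree$edge.length < 0),
            " negative branch length(s) clamped to 0 ",
            "(raw tree kept in attr 'rawNewick')", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "rawNewick") <- raw
  attr(tree, "nNegative") <- raw_neg
  tree
}

#' Write a tree as Newick
#'
#' Serializes a `phylo` tree with branch lengths; any residual negative
#' branch length is clamped to zero with a warning before writing. The
#' string round-trips through `ape::read.tree`.
#'
#' @param tree a `phylo` object (e.g., from [njTree()]).
#' @param path optional file path; when `NULL` the string is returned only.
#' @return the Newick string, invisibly when `path` is given.
#' @export
writeNewick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0 on output",
            call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
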