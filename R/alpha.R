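## Per-site alpha-diversity indices.

.checkCommunity <- function(counts) {
  if (!length(counts) || sum(counts) <= 0)
    stop("diversity index undefined for an empty community", call. = FALSE)
  if (any(counts < 0))
    stop("community counts must be non-negative", call. = FALSE)
}

#' Shannon diversity of one community
#'
#' `H' = -sum(p_i * log(p_i))` over species with `p_i > 0`, where `p_i` are
#' relative abundances; `0 * log(0)` is taken as 0. Natural log by default
#' (so `H'` is in nats and `H_max = ln S`), the community-ecology
#' convention; other bases via `base`.
#'
#' @param counts non-negative numeric vector of per-species abundances.
#' @param base logarithm base (default `exp(1)`).
#' @return `H'` (>= 0).
#' @examples
#' shannonIndex(c(10, 10, 10, 10))  # log(4)
#' @export
shannonIndex <- function(counts, base = exp(1)) {
  .checkCommunity(counts)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Simpson diversity of one community
#'
#' The complement form `D = 1 - sum(p_i^2)` (a diversity that rises with
#' evenness, in `[0, 1 - 1/S]`); the inverse form `1 / sum(p_i^2)` is
#' available with `inverse = TRUE`.
#'
#' @param counts non-negative numeric vector of per-species abundances.
#' @param inverse return `1 / sum(p_i^2)` instead of `1 - sum(p_i^2)`.
#' @return Simpson diversity.
#' @examples
#' simpsonIndex(c(1, 1))  # 0.5
#' @export
simpsonIndex <- function(counts, inverse = FALSE) {
  .checkCommunity(counts)
  p <- counts[counts > 0] / sum(counts)
  lambda <- sum(p^2)
  if (inverse) 1 / lambda else 1 - lambda
}

#' Pielou's evenness of one community
#'
#' `J' = H' / H_max` with `H_max = ln S`; 1 when all `S` species are equally
#' abundant. Undefined for `S <= 1`: the function then signals an error
#' rather than silently returning 0.
#'
#' @param counts non-negative numeric vector of per-species abundances.
#' @return `J'` in (0, 1].
#' @examples
#' pielouEvenness(c(5, 5, 5, 5))  # 1
#' @export
pielouEvenness <- function(counts) {
  .checkCommunity(counts)
  s <- sum(counts > 0)
  if (s <= 1)
    stop("Pielou's evenness is undefined for S <= 1", call. = FALSE)
  shannonIndex(counts) / log(s)
}

#' Per-site diversity profile
#'
#' Species richness `S`, Shannon `H'` (nats), Simpson `D` and Pielou `J'`
#' for every site of a [CommunityMatrix-class]. `J'` is `NA` where `S <= 1`;
#' a site with no captures is flagged and carries `NA` indices.
#'
#' @param x a [CommunityMatrix-class].
#' @param ... unused.
#' @return data.frame with `site`, `mountain`, `elevation`, `S`, `H`, `D`,
#'   `J`, `n_captures`, `flagged`.
#' @export
setMethod("diversityProfile", "CommunityMatrix", function(x, ...) {
  cm <- x@counts
  sd <- x@siteData
  out <- data.frame(site = sd$site, mountain = sd$mountain,
                    elevation = sd$elevation,
                    S = NA_integer_, H = NA_real_, D = NA_real_,
                    J = NA_real_, n_captures = rowSums(cm),
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cm))) {
    v <- cm[i, ]
    if (sum(v) == 0) { out$flagged[i] <- TRUE; next }
    out$S[i] <- sum(v > 0)
    out$H[i] <- shannonIndex(v)
    out$D[i] <- simpsonIndex(v)
    out$J[i] <- if (out$S[i] >= 2) pielouEvenness(v) else NA_real_
  }
  rownames(out) <- NULL
  out
})
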