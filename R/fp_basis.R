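#' The standard fractional-polynomial power set
#'
#' Powers -2, -1, -0.5, 0.5, 1, 2, 3 plus the natural logarithm, encoded as
#' power 0.
#'
#' @return Numeric vector of 8 powers.
#' @export
fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Enumerate fractional-polynomial power multisets
#'
#' All multisets of sizes 1..`max_degree` drawn from `powers`, each in
#' canonical non-decreasing order. With the standard 8-element power set and
#' degree up to 4 this yields the full 494-model candidate family.
#'
#' @param max_degree Maximum degree (multiset size), >= 1.
#' @param powers Candidate power set; 0 denotes ln.
#' @return List of numeric vectors (one multiset per candidate model).
#' @examples
#' length(enumerate_fp_powers(4))  # 494
#' @export
enumerate_fp_powers <- function(max_degree = 4, powers = fp_power_set()) {
  if (!is.numeric(max_degree) || max_degree < 1)
    stop("max_degree must be >= 1")
  powers <- sort(unique(powers))
  if (!length(powers)) stop("power set must be non-empty")
  out <- list()
  for (d in seq_len(max_degree)) {
    idx <- utils::combn(length(powers) + d - 1L, d)
    # bijection between d-combinations with repetition and d-subsets
    idx <- idx - (seq_len(d) - 1L)
    out <- c(out, lapply(seq_len(ncol(idx)), function(j) powers[idx[, j]]))
  }
  out
}

#' Number of candidate FP models
#'
#' Closed form \eqn{\sum_{d=1}^{D} \binom{|P|+d-1}{d}} for multisets of size
#' up to D from a power set P.
#'
#' @inheritParams enumerate_fp_powers
#' @return Integer count.
#' @export
n_fp_models <- function(max_degree = 4, powers = fp_power_set()) {
  p <- length(unique(powers))
  sum(choose(p + seq_len(max_degree) - 1, seq_len(max_degree)))
}

.canonical_powers <- function(powers) {
  if (!is.numeric(powers) || !length(powers) || length(powers) > 6)
    stop("powers must be a numeric vector of length 1..6")
  sort(powers)
}

#' Fractional-polynomial design basis
#'
#' Builds the n x d basis matrix for a power multiset. A distinct power p
#' contributes the column age^p (with age^0 meaning ln age); each repetition
#' of a power multiplies the previous term by a further ln(age), so powers
#' (0, 1, 1) give columns ln(a), a, a*ln(a).
#'
#' @param ages Numeric vector of positive ages (years).
#' @param powers Power multiset (any order; canonicalized internally).
#' @return Matrix with one column per basis term, named e.g. `"age^1"`,
#'   `"age^1*ln"`, `"ln(age)"`.
#' @examples
#' fp_basis(c(1, 2), c(0, 1, 1))
#' @export
fp_basis <- function(ages, powers) {
  if (any(!is.finite(ages)) || any(ages <= 0))
    stop("all ages must be positive and finite")
  powers <- .canonical_powers(powers)
  la <- log(ages)
  cols <- vector("list", length(powers))
  nms <- character(length(powers))
  prev_p <- NA_real_
  rep_k <- 0L
  for (j in seq_along(powers)) {
    p <- powers[j]
    if (!is.na(prev_p) && p == prev_p) {
      rep_k <- rep_k + 1L
      cols[[j]] <- cols[[j - 1L]] * la
      nms[j] <- paste0(nms[j - 1L], "*ln")
    } else {
      rep_k <- 0L
      if (p == 0) {
        cols[[j]] <- la
        nms[j] <- "ln(age)"
      } else {
        cols[[j]] <- ages^p
        nms[j] <- paste0("age^", p)
      }
    }
    prev_p <- p
  }
  out <- do.call(cbind, cols)
  colnames(out) <- nms
  out
}

#' Label a power multiset
#' @param powers Power multiset.
#' @return A compact string such as `"(0,1,1)"`.
#' @export
fp_powers_label <- function(powers)
  paste0("(", paste(.canonical_powers(powers), collapse = ","), ")")
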