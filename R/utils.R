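#' @keywords internal
"_PACKAGE"

## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

#' Round half away from zero
#'
#' Report tables use conventional half-up rounding to 2 decimals; `round()`
#' in R rounds half to even, which disagrees on exact .005 boundaries.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions (up to label names), 0 is the expected
#' agreement of independent random partitions.
#'
#' @param a,b label vectors of equal length (any atomic type)
#' @return a single number in (-1, 1]
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop2("label vectors must have equal length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_i <- sum(ch2(rowSums(tab)))
  sum_j <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_i * sum_j / ch2(n)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Match estimated states to reference states
#'
#' Finds the permutation of estimated labels maximizing the diagonal of the
#' confusion matrix against reference labels, by exhaustive search (intended
#' for small K, here at most 8-10 states).
#'
#' @param est integer estimated labels in 1..K
#' @param ref integer reference labels in 1..K
#' @param K number of states
#' @return integer vector `perm` with `perm[est]` aligned to `ref`
#' @export
match_states <- function(est, ref, K) {
  tab <- matrix(0, K, K)
  tt <- table(factor(est, levels = 1:K), factor(ref, levels = 1:K))
  tab[seq_len(K), seq_len(K)] <- tt
  perms <- all_permutations(K)
  scores <- vapply(seq_len(nrow(perms)), function(i) {
    sum(tab[cbind(1:K, perms[i, ])])
  }, numeric(1))
  perms[which.max(scores), ]
}

all_permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(K - 1L)
  out <- matrix(0L, nrow(sub) * K, K)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in 1:K) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], K, after = pos - 1L)
    }
  }
  out
}

## per-person substream seeds: output for a person does not depend on how
## many other persons precede it in the cohort
substream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647
}
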