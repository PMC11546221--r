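# Kendall tau-a and its normal-approximation Z-value.
#
# tau_a = 2/(K(K-1)) * sum_{j<k} sgn(x_j - x_k) * sgn(y_j - y_k): the plain
# sign-sum coefficient in which tied pairs contribute zero. General-purpose
# routines default to the tie-corrected tau-b, which rescales by the tie
# counts; here the exact sign sum S is recovered from tau-b by multiplying
# the correction back:
#   S = tau_b * sqrt((n0 - T_x)(n0 - T_y)),  n0 = K(K-1)/2,
# with T the number of tied pairs in each argument. This keeps the O(K^2)
# pair scan in C while preserving tau-a exactly; the test suite checks it
# against a brute-force sign-sum enumeration.

.tied_pairs <- function(v) {
  r <- rle(sort(v))$lengths
  sum(r * (r - 1)) / 2
}

# Sign sums S_c for every column of P against y. Columns that are mostly
# zero (codon-pair frequencies) use a direct sparse identity instead of the
# dense scan: pairs of zero entries are ties and contribute nothing, a
# nonzero entry against a zero contributes sgn(y_i - y_k) (entries are
# non-negative), and the nonzero-nonzero block is enumerated directly.
.kendall_S_cols <- function(P, y, sparse_frac = 0.35) {
  K <- nrow(P)
  n0 <- K * (K - 1) / 2
  Ty <- .tied_pairs(y)
  nz_count <- colSums(P != 0)
  S <- numeric(ncol(P))
  sparse <- nz_count <= sparse_frac * K & colSums(P < 0) == 0
  if (any(!sparse)) {
    Pd <- P[, !sparse, drop = FALSE]
    tb <- suppressWarnings(stats::cor(Pd, y, method = "kendall"))[, 1L]
    Tx <- apply(Pd, 2L, .tied_pairs)
    Sd <- tb * sqrt((n0 - Tx) * (n0 - Ty))
    Sd[!is.finite(Sd)] <- 0
    S[!sparse] <- Sd
  }
  if (any(sparse)) {
    for (c in which(sparse)) {
      p <- P[, c]
      nz <- p != 0
      s <- 0
      m <- sum(nz)
      if (m >= 2L) {
        pn <- p[nz]; yn <- y[nz]
        s <- sum(sign(outer(pn, pn, "-")) * sign(outer(yn, yn, "-"))) / 2
      }
      if (m >= 1L && m < K) {
        yz <- sort(y[!nz])
        yn <- y[nz]
        less <- findInterval(yn, yz, left.open = TRUE)
        greater <- length(yz) - findInterval(yn, yz)
        s <- s + sum(less - greater)
      }
      S[c] <- s
    }
  }
  list(S = S, n0 = n0)
}

#' Kendall rank correlation, tau-a form
#'
#' The untied-pair sign-sum form of Kendall's rank correlation:
#' \deqn{\tau = \frac{2}{K(K-1)} \sum_{j<k} \mathrm{sgn}(x_j - x_k)\,
#'   \mathrm{sgn}(y_j - y_k),}
#' in which tied pairs contribute exactly zero (no tie correction is applied
#' to the denominator, unlike tau-b).
#'
#' @param x,y Numeric vectors of equal length K >= 2.
#' @return The tau-a coefficient, in \[-1, 1\].
#' @examples
#' kendall_tau_a(1:3, c(1, 3, 2))  # 1/3
#' @export
kendall_tau_a <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (!is.numeric(x) || !is.numeric(y)) stop("inputs must be numeric")
  ks <- .kendall_S_cols(matrix(x, ncol = 1L), y, sparse_frac = 0)
  ks$S / ks$n0
}

#' Z-value of a Kendall tau-a coefficient
#'
#' Converts tau-a into the number of standard deviations by which it departs
#' from the independence null:
#' \deqn{Z = \frac{3\,\tau\,\sqrt{K(K-1)}}{\sqrt{2(2K+5)}}.}
#' Under independence Z is approximately standard normal; |Z| > 3 is the
#' conventional significance boundary used for the Codon Expression Index.
#'
#' @param tau Tau-a coefficient(s).
#' @param K Number of observations the coefficient was computed from (>= 2).
#' @return Z-value(s), same length as `tau`.
#' @examples
#' kendall_z(1, 4)      # 3 * sqrt(12) / sqrt(26)
#' kendall_z(1 / 3, 3)  # ~0.522
#' @export
kendall_z <- function(tau, K) {
  if (any(K < 2L)) stop("'K' must be at least 2")
  3 * tau * sqrt(K * (K - 1)) / sqrt(2 * (2 * K + 5))
}
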