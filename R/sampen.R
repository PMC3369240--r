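# Sample entropy: -ln of the conditional probability that epochs matching
# for m points (Chebyshev distance <= r, self-matches excluded) also match
# for m + 1 points. Higher values = greater irregularity.

# population SD: r is a fraction of the spread of the exact sequence given
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

.sampen_from_counts <- function(counts, m, r_abs, r_frac, N) {
  denom <- counts$n_templates * (counts$n_templates - 1)
  b_m <- counts$matches_m / denom
  b_m1 <- counts$matches_m1 / denom
  defined <- counts$matches_m > 0 && counts$matches_m1 > 0
  structure(
    list(value = if (defined) -log(b_m1 / b_m) else NA_real_,
         defined = defined, b_m = b_m, b_m1 = b_m1,
         m = m, r_abs = r_abs, r_frac = r_frac, n_used = N),
    class = "sampen_result"
  )
}

#' Sample entropy of a numeric sequence
#'
#' Computes the sample entropy statistic `SampEn(m, r, N) =
#' -ln(B_{m+1}(r) / B_m(r))`, where `B_m(r)` is the probability that two
#' distinct length-`m` epochs of the sequence agree within tolerance `r` in
#' Chebyshev (maximum-coordinate) distance. Templates run over
#' `i = 1..N-m` for both lengths, self-matches are excluded, and ties at
#' exactly `r` count as matches.
#'
#' By default the tolerance is `r_frac` times the population standard
#' deviation of `x` itself, which makes the statistic invariant to scaling
#' and shifting of the input — subband coefficient sequences of very
#' different energies become comparable.
#'
#' When no length-`m` or length-`m+1` pair matches at all, the statistic is
#' undefined (a log of zero); the result carries `defined = FALSE` and an
#' `NA` value rather than an arbitrary cap, and downstream group statistics
#' drop such cells.
#'
#' @param x Numeric sequence, `length(x) >= m + 2`.
#' @param m Embedding dimension (template length), positive integer.
#' @param r_frac Tolerance as a fraction of the population SD of `x`.
#'   Ignored when `r_abs` is given.
#' @param r_abs Absolute tolerance; overrides `r_frac` scaling.
#' @return A `sampen_result`: list with `value`, `defined`, the match
#'   probabilities `b_m` and `b_m1`, and the resolved parameters.
#' @examples
#' sample_entropy(sin(1:400), m = 2, r_frac = 0.2)$value
#' sample_entropy(rep(1, 50), m = 2)$value   # 0: all epochs identical
#' @export
sample_entropy <- function(x, m = 2, r_frac = 0.2, r_abs = NULL) {
  x <- as.numeric(x)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (any(!is.finite(x))) stop("x contains non-finite values", call. = FALSE)
  N <- length(x)
  if (N < m + 2L) {
    stop("sequence too short (N = ", N, ") for m = ", m, call. = FALSE)
  }
  if (is.null(r_abs)) {
    if (!is.numeric(r_frac) || r_frac <= 0) {
      stop("r_frac must be positive", call. = FALSE)
    }
    r_abs <- r_frac * .pop_sd(x)
  } else {
    r_frac <- NA_real_
    if (r_abs < 0) stop("r_abs must be >= 0", call. = FALSE)
  }
  counts <- sampen_counts_cpp(x, m, r_abs)
  .sampen_from_counts(counts, m, r_abs, r_frac, N)
}

#' Brute-force sample entropy (reference implementation)
#'
#' Literal transcription of the defining double loop over template pairs,
#' kept deliberately independent of the optimised counting kernel so the
#' two can be checked against each other. Intended for validation at small
#' `N`; quadratic in `length(x)`.
#'
#' @inheritParams sample_entropy
#' @return A `sampen_result`, identical in structure to
#'   [sample_entropy()]'s.
#' @export
sample_entropy_brute <- function(x, m = 2, r_frac = 0.2, r_abs = NULL) {
  x <- as.numeric(x)
  N <- length(x)
  if (is.null(r_abs)) r_abs <- r_frac * .pop_sd(x) else r_frac <- NA_real_
  nt <- N - m
  if (nt < 2L) stop("sequence too short for m = ", m, call. = FALSE)
  count_pairs <- function(mm) {
    total <- 0
    for (i in seq_len(nt)) {
      # Chebyshev distance from template i to every template j, vectorised
      dmax <- rep(0, nt)
      for (k in 0:(mm - 1L)) {
        dmax <- pmax(dmax, abs(x[i + k] - x[seq_len(nt) + k]))
      }
      total <- total + sum(dmax <= r_abs) - 1L  # drop the self-match
    }
    total
  }
  counts <- list(matches_m = count_pairs(m), matches_m1 = count_pairs(m + 1L),
                 n_templates = nt)
  .sampen_from_counts(counts, m, r_abs, r_frac, N)
}

#' Sample-entropy sensitivity sweep over (m, r) parameter grids
#'
#' Evaluates [sample_entropy()] over the Cartesian grid of embedding
#' dimensions and tolerance fractions, the standard diagnostic for choosing
#' `m` and `r`: entropy is non-increasing in `r` (a wider tolerance admits
#' more matches), and the grid shows where between-group differences are
#' largest. Undefined cells propagate as `NA` without aborting the sweep.
#'
#' @param x Numeric sequence.
#' @param m_values Integer vector of embedding dimensions.
#' @param r_fracs Numeric vector of tolerance fractions of the SD.
#' @return A tibble with columns `m`, `r_frac`, `value`, `defined`.
#' @export
sampen_sweep <- function(x, m_values = 1:3, r_fracs = seq(0.1, 0.25, by = 0.05)) {
  grid <- tidyr::expand_grid(m = as.integer(m_values), r_frac = r_fracs)
  res <- purrr::pmap(grid, function(m, r_frac) {
    sample_entropy(x, m = m, r_frac = r_frac)
  })
  grid$value <- purrr::map_dbl(res, "value")
  grid$defined <- purrr::map_lgl(res, "defined")
  class(grid) <- c("tbl_sampen_sweep", class(grid))
  grid
}

#' @export
print.sampen_result <- function(x, ...) {
  cat("<sampen_result> SampEn(m=", x$m, ", r=",
      format(x$r_abs, digits = 4), ", N=", x$n_used, ") = ",
      if (x$defined) format(x$value, digits = 6) else "undefined (no matches)",
      "\n", sep = "")
  invisible(x)
}

#' @rdname sample_entropy
#' @param ... Unused.
#' @export
tidy.sampen_result <- function(x, ...) {
  tibble::tibble(value = x$value, defined = x$defined, b_m = x$b_m,
                 b_m1 = x$b_m1, m = x$m, r_abs = x$r_abs,
                 r_frac = x$r_frac, n_used = x$n_used)
}
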