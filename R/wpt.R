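# Wavelet-packet transform: full binary tree of periodised two-channel
# filter-bank splits. Periodisation keeps the transform orthogonal at every
# level (exact energy conservation, exact length halving for even lengths),
# which the subband-entropy features rely on.

# one analysis split: x -> list(a = low-pass child, d = high-pass child)
.wpt_split <- function(x, h, g) {
  n <- length(x)
  if (n %% 2L == 1L) {       # pad by repeating the final sample
    x <- c(x, x[n])
    n <- n + 1L
  }
  m <- n %/% 2L
  L <- length(h)
  a <- numeric(m)
  d <- numeric(m)
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_len(L)) {
    idx <- (base + (k - 1L)) %% n + 1L
    xk <- x[idx]
    a <- a + h[k] * xk
    d <- d + g[k] * xk
  }
  list(a = a, d = d)
}

# inverse of .wpt_split: children -> parent of length parent_len
.wpt_merge <- function(a, d, h, g, parent_len) {
  m <- length(a)
  n <- 2L * m
  L <- length(h)
  out <- numeric(n)
  base <- 2L * (seq_len(m) - 1L)
  for (k in seq_len(L)) {
    idx <- (base + (k - 1L)) %% n + 1L
    out[idx] <- out[idx] + h[k] * a + g[k] * d
  }
  out[seq_len(parent_len)]
}

#' Frequency (sequency) position of a wavelet-packet node
#'
#' Repeated filter-and-downsample splits place subbands in Paley (natural)
#' order, in which node index does not increase with physical frequency:
#' downsampling folds the spectrum, so every split below a high-pass branch
#' swaps its children's frequency roles. The inverse Gray code (prefix-XOR
#' of the index bits, most significant first) undoes this folding: a child
#' keeps low/high orientation under an even-frequency parent and swaps it
#' under an odd-frequency one.
#'
#' @param level Decomposition level `j >= 1`.
#' @param natural_index Node index in natural (Paley) order, in
#'   `[0, 2^level)`. Vectorised.
#' @return Integer frequency position(s) in `[0, 2^level)`: increasing
#'   `freq_order` corresponds to increasing physical frequency.
#' @examples
#' wpt_freq_order(3, 0:7)   # a permutation of 0..7
#' @export
wpt_freq_order <- function(level, natural_index) {
  stopifnot(length(level) == 1, level >= 1)
  n <- as.integer(natural_index)
  if (any(n < 0L | n >= 2L^level)) {
    stop("natural_index out of range [0, 2^level)", call. = FALSE)
  }
  out <- n
  shift <- n %/% 2L
  while (any(shift > 0L)) {
    out <- bitwXor(out, shift)
    shift <- shift %/% 2L
  }
  out
}

#' Frequency bands tiling [0, fs/2) at a decomposition level
#'
#' @param fs Sampling rate in Hz.
#' @param level Decomposition level `j >= 1`; the level has `2^j` bands of
#'   width `fs / 2^(j+1)`.
#' @return A tibble with columns `level`, `freq_index`, `band_lo`, `band_hi`
#'   (Hz), ordered by increasing frequency.
#' @export
wpt_bands <- function(fs, level) {
  nb <- 2L^level
  width <- fs / 2^(level + 1)
  tibble::tibble(
    level = level,
    freq_index = 0:(nb - 1L),
    band_lo = (0:(nb - 1L)) * width,
    band_hi = (1:nb) * width
  )
}

#' Wavelet-packet decomposition of a finite signal
#'
#' Recursively splits the signal into low- and high-frequency halves with an
#' orthogonal Daubechies filter pair, populating the full binary tree down
#' to `max_level`. At level `j` the `2^j` nodes tile `[0, fs/2)` in bands of
#' width `fs / 2^(j+1)`; with `fs = 16000` and `max_level = 5` the leaves
#' are 32 bands of 250 Hz.
#'
#' Boundaries are handled by periodisation, so the transform is orthogonal:
#' the coefficient energy at every full level equals the signal energy and
#' [wpt_reconstruct()] inverts it exactly (to rounding). Odd-length nodes
#' are padded by repeating their final sample before splitting; the pad is
#' removed again on reconstruction.
#'
#' @param x Numeric signal (finite values).
#' @param fs Sampling rate in Hz.
#' @param wavelet Wavelet name (see [qmf_filters()]) or a filter pair.
#' @param max_level Tree depth `>= 1`; requires `length(x) >= 2^max_level`.
#' @return An object of class `wpt_tree` with elements `fs`, `wavelet`,
#'   `max_level`, `original_length`, `level_lengths`, and `nodes` (per
#'   level, a list of coefficient vectors in natural order). Use
#'   [tidy.wpt_tree()] for a per-node tibble with physical bands.
#' @examples
#' x <- sin(2 * pi * 1000 * seq(0, 1, length.out = 16000))
#' tr <- wpt_decompose(x, fs = 16000, wavelet = "db4", max_level = 5)
#' nrow(dplyr::filter(tidy(tr), level == 5))  # 32 bands
#' @export
wpt_decompose <- function(x, fs, wavelet = "db4", max_level = 5) {
  fp <- qmf_filters(wavelet)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("signal contains NaN/Inf values", call. = FALSE)
  max_level <- as.integer(max_level)
  if (max_level < 1L) stop("max_level must be >= 1", call. = FALSE)
  if (length(x) < 2L^max_level) {
    stop("signal too short (", length(x), " samples) for ", max_level,
         "-level decomposition", call. = FALSE)
  }
  nodes <- vector("list", max_level)
  level_lengths <- integer(max_level + 1L)
  level_lengths[1L] <- length(x)
  current <- list(x)
  for (j in seq_len(max_level)) {
    children <- vector("list", 2L * length(current))
    for (i in seq_along(current)) {
      sp <- .wpt_split(current[[i]], fp$h, fp$g)
      children[[2L * i - 1L]] <- sp$a
      children[[2L * i]] <- sp$d
    }
    nodes[[j]] <- children
    level_lengths[j + 1L] <- length(children[[1L]])
    current <- children
  }
  structure(
    list(fs = fs, wavelet = fp, max_level = max_level,
         original_length = length(x), level_lengths = level_lengths,
         nodes = nodes),
    class = "wpt_tree"
  )
}

#' Reconstruct a signal from one full level of a wavelet-packet tree
#'
#' Inverse filter-bank synthesis from the `2^level` nodes of a full level,
#' trimmed to the original signal length.
#'
#' @param tree A `wpt_tree` from [wpt_decompose()].
#' @param level Level to synthesise from, `1 <= level <= tree$max_level`.
#' @return Numeric vector of length `tree$original_length`.
#' @export
wpt_reconstruct <- function(tree, level = tree$max_level) {
  stopifnot(inherits(tree, "wpt_tree"))
  level <- as.integer(level)
  if (level < 1L || level > tree$max_level) {
    stop("level ", level, " not populated in tree (max_level = ",
         tree$max_level, ")", call. = FALSE)
  }
  current <- tree$nodes[[level]]
  if (length(current) != 2L^level || any(vapply(current, is.null, logical(1)))) {
    stop("incomplete tree: level ", level, " is not fully populated",
         call. = FALSE)
  }
  fp <- tree$wavelet
  for (j in level:1L) {
    parent_len <- tree$level_lengths[j]
    parents <- vector("list", length(current) %/% 2L)
    for (i in seq_along(parents)) {
      parents[[i]] <- .wpt_merge(current[[2L * i - 1L]], current[[2L * i]],
                                 fp$h, fp$g, parent_len)
    }
    current <- parents
  }
  current[[1L]]
}

#' Tidy a wavelet-packet tree into a per-node tibble
#'
#' @param x A `wpt_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node at every populated level:
#'   `level`, `natural_index`, `freq_index`, `band_lo`, `band_hi` (Hz),
#'   `n_coeffs`, `energy`, and a `coeffs` list-column, ordered level-major
#'   then by ascending `band_lo`.
#' @export
tidy.wpt_tree <- function(x, ...) {
  out <- purrr::map_dfr(seq_len(x$max_level), function(j) {
    nat <- 0:(2L^j - 1L)
    fi <- wpt_freq_order(j, nat)
    width <- x$fs / 2^(j + 1)
    tibble::tibble(
      level = j,
      natural_index = nat,
      freq_index = fi,
      band_lo = fi * width,
      band_hi = (fi + 1) * width,
      n_coeffs = lengths(x$nodes[[j]]),
      energy = vapply(x$nodes[[j]], function(v) sum(v^2), numeric(1)),
      coeffs = x$nodes[[j]]
    )
  })
  dplyr::arrange(out, .data$level, .data$band_lo)
}

#' @export
print.wpt_tree <- function(x, ...) {
  cat("<wpt_tree> ", x$wavelet$name, ", ", x$max_level, " levels, ",
      x$original_length, " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  level ", x$max_level, ": ", 2L^x$max_level, " bands of ",
      x$fs / 2^(x$max_level + 1), " Hz\n", sep = "")
  invisible(x)
}
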