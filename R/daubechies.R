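# Orthogonal Daubechies scaling filters, indexed by vanishing moments.
# Stored as the synthesis low-pass h (sum = sqrt(2)); the analysis bank is
# derived from it, and the high-pass g by the alternating-flip rule.
.db_scaling <- list(
  db4 = rev(c(-1.0597401785069032e-02, 3.2883011666885197e-02,
              3.0841381835560764e-02, -1.8703481171909309e-01,
              -2.7983769416859854e-02, 6.3088076792985892e-01,
              7.1484657055291567e-01, 2.3037781330889651e-01)),
  db6 = rev(c(-1.0773010853084796e-03, 4.7772575109455108e-03,
              5.5384220116149613e-04, -3.1582039317486030e-02,
              2.7522865530305727e-02, 9.7501605587323043e-02,
              -1.2976686756726194e-01, -2.2626469396543983e-01,
              3.1525035170919763e-01, 7.5113390802109536e-01,
              4.9462389039845306e-01, 1.1154074335010947e-01)),
  db8 = rev(c(-1.1747678412476953e-04, 6.7544940645056933e-04,
              -3.9174037337694705e-04, -4.8703529934515741e-03,
              8.7460940474057766e-03, 1.3981027917398282e-02,
              -4.4088253930794755e-02, -1.7369301001807547e-02,
              1.2874742662047847e-01, 4.7248457391328279e-04,
              -2.8401554296154691e-01, -1.5829105256349306e-02,
              5.8535468365420673e-01, 6.7563073629728976e-01,
              3.1287159091429995e-01, 5.4415842243104008e-02)),
  db10 = rev(c(-1.3264202894521244e-05, 9.3588670320069592e-05,
               -1.1646685512928545e-04, -6.8585669495971162e-04,
               1.9924052951850561e-03, 1.3953517470529011e-03,
               -1.0733175483330575e-02, 3.6065535669561697e-03,
               3.3212674059341002e-02, -2.9457536821875813e-02,
               -7.1394147166397082e-02, 9.3057364603572348e-02,
               1.2736934033579325e-01, -1.9594627437737705e-01,
               -2.4984642432731538e-01, 2.8117234366057747e-01,
               6.8845903945360354e-01, 5.2720118893172563e-01,
               1.8817680007769150e-01, 2.6670057900555554e-02))
)

#' Orthogonal Daubechies quadrature-mirror filter pair
#'
#' Returns the low-pass scaling filter `h` and its quadrature-mirror
#' high-pass counterpart `g` for the Daubechies wavelets used by the
#' subband decomposition. The naming follows the vanishing-moment
#' convention: `db4` has 4 vanishing moments and 8 taps.
#'
#' `g` is derived from `h` by the alternating-flip rule
#' `g[k] = (-1)^(k-1) * h[L - k + 1]`, which guarantees orthogonality of
#' the two-channel filter bank. Both filters are normalised so that
#' `sum(h) == sqrt(2)`, the scaling under which the periodised transform
#' is an orthogonal map (energy preserving).
#'
#' @param name One of `"db4"`, `"db6"`, `"db8"`, `"db10"`.
#' @return An object of class `wavelet_filter_pair`: a list with elements
#'   `name`, `h` (low-pass) and `g` (high-pass), each of length `2 * N`
#'   for `dbN`.
#' @examples
#' fp <- qmf_filters("db4")
#' length(fp$h)      # 8 taps
#' sum(fp$h)         # sqrt(2)
#' @export
qmf_filters <- function(name) {
  if (inherits(name, "wavelet_filter_pair")) return(name)
  if (!is.character(name) || length(name) != 1 || !name %in% names(.db_scaling)) {
    stop("unsupported wavelet '", paste(name, collapse = ","),
         "'; available: ", paste(names(.db_scaling), collapse = ", "),
         call. = FALSE)
  }
  h <- .db_scaling[[name]]
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * h[L:1]
  structure(list(name = name, h = h, g = g), class = "wavelet_filter_pair")
}

#' @export
print.wavelet_filter_pair <- function(x, ...) {
  cat("<wavelet_filter_pair>", x$name, "-", length(x$h), "taps\n")
  invisible(x)
}
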