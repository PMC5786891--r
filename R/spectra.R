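# Voss indicator encoding and power spectral densities.
#
# A DNA string becomes a 4 x L binary matrix (channels A, G, C, T); the PSD
# is the sum over the four channels of the squared magnitude of the
# unnormalized DFT of the zero-padded channel.  The full two-sided spectrum
# of length n is kept, so spectra of sequences of different lengths are
# comparable once padded to a common n.

VOSS_CHANNELS <- c("A", "G", "C", "T")

#' Voss binary indicator encoding of a DNA sequence
#'
#' Maps a nucleotide string to a 4 x L binary matrix with one channel per
#' base, rows ordered A, G, C, T.  Channel `c` holds 1 exactly at positions
#' where base `c` occurs.  Positions carrying IUPAC ambiguity codes (or `N`)
#' are 0 in all four channels; their count is recorded in the
#' `n_ambiguous` attribute.
#'
#' @param seq Either a nucleotide string or a single-row subset of a
#'   [dna_set()].
#' @return Integer matrix of 0/1 with rownames `A`, `G`, `C`, `T` and
#'   attributes `source_id` (if known) and `n_ambiguous`.
#' @export
#' @examples
#' voss_encode("ATTCGCAT")
voss_encode <- function(seq) {
  source_id <- NA_character_
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    source_id <- seq$id[[1]]
    seq <- seq$residues[[1]]
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  if (nchar(seq) == 0L) stop("cannot encode an empty sequence", call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  x <- matrix(0L, nrow = 4L, ncol = length(chars),
              dimnames = list(VOSS_CHANNELS, NULL))
  for (b in VOSS_CHANNELS) x[b, chars == b] <- 1L
  attr(x, "source_id") <- source_id
  attr(x, "n_ambiguous") <- sum(colSums(x) == 0L)
  x
}

#' Power spectral density of a Voss signal
#'
#' Zero-pads each of the four indicator channels to length `n`, applies the
#' unnormalized DFT, and sums squared magnitudes across channels.  The
#' result is the full two-sided spectrum: `values[q+1] = sum_c |U_c[q]|^2`
#' for frequency bins `q = 0 ... n-1`.  Because the channels are real, the
#' spectrum is conjugate-symmetric: `values[q] == values[n-q]` (1-based
#' bins 2..n).
#'
#' @param signal A 4 x L matrix from [voss_encode()], or a string/`dna_set`
#'   row which is encoded first.
#' @param n Target spectrum length, `n >= L` (default: `L`, no padding).
#' @param drop_dc If `TRUE`, the DC bin (`values[1]`, pure base-composition
#'   energy) is zeroed.  Default `FALSE`.
#' @return Numeric vector of length `n` with attributes `orig_length`,
#'   `source_id` and `drop_dc`.
#' @export
#' @examples
#' psd(voss_encode("AAAA"))         # c(16, 0, 0, 0)
psd <- function(signal, n = NULL, drop_dc = FALSE) {
  if (!is.matrix(signal)) signal <- voss_encode(signal)
  stopifnot(nrow(signal) == 4L)
  L <- ncol(signal)
  if (is.null(n)) n <- L
  n <- as.integer(n)
  if (n < L) {
    stop("target spectrum length n = ", n, " is shorter than the sequence (",
         L, "); raise n to at least the longest sequence", call. = FALSE)
  }
  if (n < 2L) stop("spectrum length must be >= 2", call. = FALSE)
  padded <- matrix(0, nrow = n, ncol = 4L)
  padded[seq_len(L), ] <- t(signal)
  spec <- rowSums(Mod(stats::mvfft(padded))^2)
  if (drop_dc) spec[1L] <- 0
  attr(spec, "orig_length") <- L
  attr(spec, "source_id") <- attr(signal, "source_id")
  attr(spec, "drop_dc") <- drop_dc
  spec
}

#' Power spectra of a set of sequences at a common length
#'
#' Computes one PSD row per sequence, all at the same spectrum length `n`,
#' so that spectra are directly comparable with Euclidean distance.  With
#' `n = "auto"` the common length is the maximum sequence length; shorter
#' sequences are zero-padded, and an explicit `n` shorter than some sequence
#' is an error (sequences are never truncated).
#'
#' @param seqs A [dna_set()] (or character vector of sequences, optionally
#'   named by id).
#' @param n Common spectrum length: `"auto"` or an integer `>=` the longest
#'   sequence.
#' @param drop_dc Passed to [psd()] for every sequence.
#' @return An object of class `spectrum_set`: list with `spectra` (m x n
#'   matrix, rownames = ids), `ids`, `n`, `orig_lengths`, `drop_dc`.
#' @export
spectrum_set <- function(seqs, n = "auto", drop_dc = FALSE) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    residues <- seqs$residues
  } else {
    residues <- as.character(seqs)
    ids <- if (!is.null(names(seqs))) names(seqs) else
      paste0("seq", seq_along(seqs))
  }
  if (length(residues) == 0L) stop("no sequences given", call. = FALSE)
  if (anyDuplicated(ids)) stop("sequence ids must be unique", call. = FALSE)
  lens <- nchar(residues)
  if (any(lens == 0L)) stop("sequences must be non-empty", call. = FALSE)
  if (identical(n, "auto")) {
    n <- max(lens)
  } else {
    n <- as.integer(n)
    if (any(lens > n)) {
      too_long <- ids[lens > n][[1]]
      stop("sequence '", too_long, "' (length ", max(lens),
           ") exceeds requested spectrum length n = ", n,
           "; sequences are never truncated", call. = FALSE)
    }
  }
  n <- max(n, 2L)
  spectra <- matrix(0, nrow = length(residues), ncol = n,
                    dimnames = list(ids, NULL))
  for (i in seq_along(residues)) {
    spectra[i, ] <- psd(voss_encode(residues[[i]]), n = n, drop_dc = drop_dc)
  }
  structure(list(spectra = spectra, ids = ids, n = n,
                 orig_lengths = lens, drop_dc = drop_dc),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("spectrum_set:", nrow(x$spectra), "spectra of length", x$n,
      if (x$drop_dc) "(DC removed)" else "", "\n")
  invisible(x)
}

#' Euclidean distance between two power spectra
#'
#' @param a,b Numeric spectra of equal length (e.g. rows of a
#'   `spectrum_set`, or outputs of [psd()]).
#' @return Nonnegative scalar; 0 iff the spectra are identical.
#' @export
spectral_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("spectra have different lengths (", length(a), " vs ", length(b),
         ")", call. = FALSE)
  }
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Export a spectrum set as a CSV matrix
#'
#' Plain ids-by-bins CSV for external analysis; first column `id`, then one
#' column per frequency bin (`f0`, `f1`, ...).
#'
#' @param set A `spectrum_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(set, path) {
  df <- data.frame(id = set$ids, set$spectra, stringsAsFactors = FALSE)
  names(df) <- c("id", paste0("f", seq_len(set$n) - 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
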