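# Wavelet-native band phase, the non-default phase source.

#' Band-level phase from retained wavelet coefficients
#'
#' Sums the complex Morlet coefficients across the grid frequencies of
#' each band and takes the argument — the wavelet-native instantaneous
#' phase, usable as the `phases` argument of [extract_features()] in
#' place of the default Hilbert phase of the band-power series.
#'
#' @param tfr a `tf_power` from [morlet_transform()] run with
#'   `keep_phase = TRUE`.
#' @param bands named band list (see [default_bands()]).
#' @return phase array `trials x channels x bands x time` in
#'   `(-pi, pi]`.
#' @export
band_phase_from_coefs <- function(tfr, bands = default_bands()) {
  stopifnot(inherits(tfr, "tf_power"))
  abort_if(is.null(tfr$coefs),
           "no coefficients retained; rerun morlet_transform(keep_phase = TRUE)")
  d <- dim(tfr$coefs)
  nb <- length(bands)
  ph <- array(0, c(d[1], d[2], nb, d[4]))
  for (b in seq_len(nb)) {
    sel <- which(tfr$freqs_hz >= bands[[b]][1] & tfr$freqs_hz <= bands[[b]][2])
    abort_if(length(sel) == 0, "band '%s' contains no grid frequency",
             names(bands)[b])
    z <- tfr$coefs[, , sel, , drop = FALSE]
    ph[, , b, ] <- Arg(rowSums(aperm(z, c(1, 2, 4, 3)), dims = 3))
  }
  ph
}
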