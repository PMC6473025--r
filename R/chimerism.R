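#' Bone-marrow chimerism sample
#'
#' Per-image counts of GFP-positive versus total nucleated cells for one
#' bone-marrow preparation, plus the donor-positive reference fraction:
#' for a donor heterozygous for the GFP transgene only a fraction of
#' nucleated cells fluoresce (25% in the reference preparation), so the
#' observed positive fraction underestimates true donor chimerism by that
#' factor.
#'
#' @param sample_id Identifier string.
#' @param images Data frame with columns `image_id`, `n_positive`,
#'   `n_total` (counts, `n_positive <= n_total`).
#' @param donor_positive_fraction Fraction of the donor's nucleated cells
#'   that fluoresce, in (0, 1]; default 0.25 (heterozygous donor).
#' @return An object of class `chimerism_sample`.
#' @export
chimerism_sample <- function(sample_id, images,
                             donor_positive_fraction = 0.25) {
  stopifnot(is.data.frame(images),
            all(c("image_id", "n_positive", "n_total") %in% names(images)))
  if (any(images$n_positive < 0) || any(images$n_total < 0))
    stop("counts must be nonnegative")
  if (any(images$n_positive > images$n_total))
    stop("n_positive exceeds n_total in at least one image")
  if (donor_positive_fraction <= 0 || donor_positive_fraction > 1)
    stop("donor_positive_fraction must lie in (0, 1]")
  structure(list(sample_id = as.character(sample_id),
                 images = images[c("image_id", "n_positive", "n_total")],
                 donor_positive_fraction = donor_positive_fraction),
            class = "chimerism_sample")
}

#' Observed GFP-positive fraction of a chimerism sample
#'
#' @param sample A [chimerism_sample()] with at least one non-empty image.
#' @param mode `"mean_of_images"` (default; unweighted mean of per-image
#'   fractions, matching instrument-reported mean percentages) or
#'   `"pooled"` (total positives over total cells).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_positive <- function(sample,
                              mode = c("mean_of_images", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "chimerism_sample"))
  img <- sample$images[sample$images$n_total > 0, , drop = FALSE]
  if (nrow(img) == 0L) stop("all images empty: no cells counted")
  switch(mode,
         mean_of_images = mean(img$n_positive / img$n_total),
         pooled         = sum(img$n_positive) / sum(img$n_total))
}

#' Heterozygous-donor chimerism correction
#'
#' Converts an observed GFP-positive fraction into donor chimerism by
#' dividing by the donor-positive reference fraction: an observed 7% with
#' a 25% donor reference gives 7/25 = 28% chimerism.  An optional
#' background fraction (GFP-negative control autofluorescence, 0 in the
#' reference data) is subtracted first; results below 0 clamp to 0 and
#' results above 1 (inconsistent inputs) raise an error.
#'
#' @param observed_fraction Observed positive fraction, in `[0, 1]`.
#' @param donor_positive_fraction Donor reference fraction, in (0, 1].
#' @param background Background positive fraction subtracted before the
#'   correction; default 0.
#' @return Chimerism fraction in `[0, 1]`.
#' @export
chimerism_corrected <- function(observed_fraction, donor_positive_fraction,
                                background = 0) {
  stopifnot(observed_fraction >= 0, observed_fraction <= 1,
            background >= 0, background <= 1)
  if (donor_positive_fraction <= 0)
    stop("donor_positive_fraction must be positive")
  out <- (observed_fraction - background) / donor_positive_fraction
  if (out > 1 + 1e-9)
    stop("observed exceeds donor ceiling: inconsistent inputs")
  min(max(out, 0), 1)
}

#' One-step chimerism estimate for a sample
#'
#' [fraction_positive()] followed by [chimerism_corrected()] with the
#' sample's own donor reference fraction.
#'
#' @inheritParams fraction_positive
#' @inheritParams chimerism_corrected
#' @return Chimerism fraction in `[0, 1]`.
#' @export
estimate_chimerism <- function(sample, mode = "mean_of_images",
                               background = 0) {
  chimerism_corrected(fraction_positive(sample, mode),
                      sample$donor_positive_fraction, background)
}

#' Read per-image chimerism counts from CSV
#'
#' Expects columns `sample_id`, `image_id`, `n_positive`, `n_total`; rows
#' are grouped by `sample_id` into one [chimerism_sample()] each.
#'
#' @param path CSV file path.
#' @param donor_positive_fraction Donor reference fraction attached to
#'   every sample; default 0.25.
#' @return Named list of `chimerism_sample` objects.
#' @export
read_chimerism_csv <- function(path, donor_positive_fraction = 0.25) {
  raw <- utils::read.csv(path, colClasses = c(sample_id = "character",
                                              image_id = "character"))
  required <- c("sample_id", "image_id", "n_positive", "n_total")
  if (!all(required %in% names(raw)))
    stop("CSV header must contain: ", paste(required, collapse = ", "))
  out <- lapply(split(raw, raw$sample_id), function(d) {
    chimerism_sample(d$sample_id[1], d[c("image_id", "n_positive", "n_total")],
                     donor_positive_fraction)
  })
  out[order(names(out))]
}

#' Write per-image chimerism counts to CSV
#'
#' @param samples A list of [chimerism_sample()] objects.
#' @param path CSV file path.
#' @export
write_chimerism_csv <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s)
    cbind(sample_id = s$sample_id, s$images)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
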