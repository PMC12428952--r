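#' @title Snellen optotype rendering and PSF convolution
#' @name optotype
NULL

#' Render a Snellen-grid letter E
#'
#' Renders the standard 5x5-grid Snellen E (three horizontal bars joined by a
#' vertical spine; 17 of the 25 cells are ink). Letter height is five stroke
#' widths; a 20/x letter subtends 5 * (x/20) arcminutes of height, so the
#' 20/100 letter is 25 arcmin tall. Pixels are in `[0, 1]` with 1 = white
#' background and 0 = letter ink; margins of at least one letter height
#' surround the glyph.
#'
#' @param acuity_denominator Snellen denominator (e.g. 100 for 20/100).
#' @param sample_scale_arcmin angular size of one sample in arcminutes; must
#'   give at least 5 samples per stroke.
#' @param orientation one of "right" (default; bars open to the right... i.e.
#'   the standard E with spine on the left), "left", "up", "down".
#' @param margin_letter_heights margin width on each side, in letter heights.
#' @return object of class `optotype_image`: list with `pixels`,
#'   `sample_scale_arcmin`, `letter`, `acuity`.
#' @export
render_snellen_e <- function(acuity_denominator = 100, sample_scale_arcmin,
                             orientation = c("right", "left", "up", "down"),
                             margin_letter_heights = 1) {
  orientation <- match.arg(orientation)
  stopifnot(acuity_denominator > 0, sample_scale_arcmin > 0,
            margin_letter_heights >= 0)
  height_arcmin <- 5 * acuity_denominator / 20
  stroke_arcmin <- height_arcmin / 5
  if (stroke_arcmin / sample_scale_arcmin < 5 - 1e-9) {
    stop(sprintf(
      "sampling too coarse: %.3f arcmin/sample gives %.1f samples per %.1f-arcmin stroke (need >= 5)",
      sample_scale_arcmin, stroke_arcmin / sample_scale_arcmin, stroke_arcmin))
  }
  # 5x5 cell mask for the right-opening E: spine column 1, bars rows 1, 3, 5
  cells <- matrix(FALSE, 5, 5)
  cells[c(1, 3, 5), ] <- TRUE
  cells[, 1] <- TRUE
  cells <- switch(orientation,
    right = cells,
    left  = cells[, 5:1],
    up    = t(cells),           # spine on bottom row -> bars open upward
    down  = t(cells)[5:1, ])
  n_letter <- max(2L, round(height_arcmin / sample_scale_arcmin))
  margin <- ceiling(margin_letter_heights * n_letter)
  n_img <- n_letter + 2L * margin
  pixels <- matrix(1, n_img, n_img)
  # map letter pixels to 5x5 cells by pixel-center coordinates
  pos <- (seq_len(n_letter) - 0.5) / n_letter  # in (0,1)
  cell_idx <- pmin(5L, 1L + floor(pos * 5))
  ink <- cells[cell_idx, cell_idx, drop = FALSE]
  block <- matrix(1, n_letter, n_letter)
  block[ink] <- 0
  pixels[margin + seq_len(n_letter), margin + seq_len(n_letter)] <- block
  structure(list(pixels = pixels,
                 sample_scale_arcmin = sample_scale_arcmin,
                 letter = "E",
                 acuity = sprintf("20/%d", acuity_denominator)),
            class = "optotype_image")
}

# resample a PSF to a target angular pitch by bilinear interpolation,
# then renormalize to unit sum; optionally crop to a half-width of
# max_extent_arcmin (tails are reabsorbed by the renormalization)
resample_psf <- function(psf, target_scale_arcmin, max_extent_arcmin = NULL) {
  N <- nrow(psf$intensity)
  c0 <- N %/% 2 + 1
  extent <- (N / 2 - 1) * psf$sample_scale_arcmin
  if (!is.null(max_extent_arcmin)) extent <- min(extent, max_extent_arcmin)
  n_out <- 2L * floor(extent / target_scale_arcmin) + 1L
  coord_out <- (seq_len(n_out) - (n_out %/% 2 + 1L)) * target_scale_arcmin
  coord_in <- (seq_len(N) - c0) * psf$sample_scale_arcmin
  # intensity[i, j] = psf at (x_i, y_j); interp2 wants Z rows indexed by y
  vals <- pracma::interp2(coord_in, coord_in, t(psf$intensity),
                          xp = rep(coord_out, times = n_out),
                          yp = rep(coord_out, each = n_out),
                          method = "linear")
  out <- matrix(vals, n_out, n_out)  # out[i, j] = psf at (x_out_i, y_out_j)
  out[out < 0 | !is.finite(out)] <- 0
  out / sum(out)
}

#' Convolve an optotype image with a PSF
#'
#' Linear (zero-padded, FFT-based) convolution of the letter's ink intensity
#' (1 - pixels) with the PSF, returned in the original polarity. The full
#' linear-convolution support is returned, so with a unit-sum kernel the
#' total ink flux is conserved. If the PSF is sampled at a different angular
#' pitch than the image it is first resampled (bilinear) and renormalized.
#'
#' @param image an [render_snellen_e()] result.
#' @param psf a [compute_psf()] result.
#' @param kernel_extent_arcmin optional half-width at which to truncate the
#'   (resampled, renormalized) PSF kernel; NULL keeps the full support.
#' @return an `optotype_image` on the same angular scale (enlarged by the
#'   kernel support).
#' @export
convolve_with_psf <- function(image, psf, kernel_extent_arcmin = NULL) {
  stopifnot(inherits(image, "optotype_image"), inherits(psf, "psf"))
  if (abs(psf$sample_scale_arcmin - image$sample_scale_arcmin) >
      1e-9 * image$sample_scale_arcmin || !is.null(kernel_extent_arcmin)) {
    kernel <- resample_psf(psf, image$sample_scale_arcmin, kernel_extent_arcmin)
  } else {
    kernel <- psf$intensity
  }
  ink <- 1 - image$pixels
  n_i <- nrow(ink); n_k <- nrow(kernel)
  n_full <- n_i + n_k - 1L
  n_fft <- stats::nextn(n_full, factors = 2)
  A <- matrix(0, n_fft, n_fft); A[1:n_i, 1:n_i] <- ink
  B <- matrix(0, n_fft, n_fft); B[1:n_k, 1:n_k] <- kernel
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / n_fft^2
  conv <- conv[1:n_full, 1:n_full]
  conv[conv < 0 & conv > -1e-9] <- 0
  out <- 1 - conv
  structure(list(pixels = out,
                 sample_scale_arcmin = image$sample_scale_arcmin,
                 letter = image$letter,
                 acuity = image$acuity),
            class = "optotype_image")
}

#' Through-focus optotype panel with VSOTF annotations
#'
#' Builds the classic through-focus letter chart: rows are optical conditions,
#' columns are object vergences; each cell is the letter E convolved with that
#' condition's PSF at that vergence, and the accompanying table carries the
#' per-cell VSOTF. All cells are rendered at a common display pitch so the
#' panel assembles into one matrix.
#'
#' @param conditions list of [eye_model()] objects (rows).
#' @param vergences_D numeric vector of object vergences (columns), e.g.
#'   `seq(2, -2, by = -0.5)`.
#' @param acuity_denominator Snellen denominator for the letter (default 100).
#' @param display_scale_arcmin angular pitch of the panel pixels.
#' @param wavelength_nm,pupil_samples,padding_factor,csf optical pipeline
#'   settings (see [through_focus_curve()]).
#' @param gap_px white gap between cells in pixels.
#' @return list with `image` (matrix in `[0, 1]`, rows x cols of cells) and
#'   `table` (tibble: condition, vergence_D, vsotf, row, col).
#' @export
build_panel <- function(conditions, vergences_D,
                        acuity_denominator = 100,
                        display_scale_arcmin = 0.25,
                        wavelength_nm = 555, pupil_samples = 256,
                        padding_factor = 4, csf = neural_csf(),
                        gap_px = 4) {
  stopifnot(length(conditions) >= 1, length(vergences_D) >= 1)
  letter <- render_snellen_e(acuity_denominator, display_scale_arcmin,
                             margin_letter_heights = 0.5)
  cell_list <- list()
  rows <- list()
  for (i in seq_along(conditions)) {
    model <- conditions[[i]]
    wf0 <- compose_wavefront(pupil_diameter_mm = model$pupil_diameter_mm,
                             n_samples = pupil_samples)
    otf_dl <- compute_otf(compute_psf(build_pupil_function(wf0, wavelength_nm),
                                      padding_factor))
    for (j in seq_along(vergences_D)) {
      wf <- compose_wavefront(base = model$zernike,
                              vergence_D = vergences_D[j],
                              profile = model$profile,
                              pupil_diameter_mm = model$pupil_diameter_mm,
                              n_samples = pupil_samples)
      p <- compute_psf(build_pupil_function(wf, wavelength_nm), padding_factor)
      # truncate the kernel to the cell's own angular extent: tails beyond it
      # carry negligible energy and would only enlarge the convolution
      cell_extent <- nrow(letter$pixels) * display_scale_arcmin / 2
      cell <- convolve_with_psf(letter, p, kernel_extent_arcmin = cell_extent)
      cell_list[[length(cell_list) + 1L]] <- cell$pixels
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = model$label, vergence_D = vergences_D[j],
        vsotf = vsotf(compute_otf(p), otf_dl, csf), row = i, col = j)
    }
  }
  # crop/pad every cell to the common (max) size, centered
  sizes <- vapply(cell_list, nrow, integer(1))
  n_cell <- max(sizes)
  cell_list <- lapply(cell_list, function(px) {
    n <- nrow(px)
    if (n == n_cell) return(px)
    out <- matrix(1, n_cell, n_cell)
    o <- (n_cell - n) %/% 2
    out[o + seq_len(n), o + seq_len(n)] <- px
    out
  })
  nr <- length(conditions); nc <- length(vergences_D)
  H <- nr * n_cell + (nr - 1) * gap_px
  W <- nc * n_cell + (nc - 1) * gap_px
  img <- matrix(1, H, W)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r0 <- (i - 1) * (n_cell + gap_px)
    c0 <- (j - 1) * (n_cell + gap_px)
    img[r0 + seq_len(n_cell), c0 + seq_len(n_cell)] <-
      cell_list[[(i - 1) * nc + j]]
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, table = dplyr::bind_rows(rows))
}
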