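## Quantitative wet-lab readouts as pure computations: plaque/lawn grayscale
## intensity ratio and phage adsorption efficiency from PFU counts.

#' Plaque-to-lawn intensity ratio
#'
#' Mean grayscale intensity within the plaque mask divided by the mean within
#' the surrounding-lawn mask.  A ratio of 1 indicates near-complete defense
#' (no visible clearing: the plaque region is as opaque as the lawn); lower
#' values indicate successful phage infection and lysis.  Masks are
#' caller-supplied (regions are selected manually, as with ImageJ), must be
#' nonempty, disjoint, and match the image shape.  Mean intensity matches the
#' default region measurement of ImageJ.
#'
#' @param pixels numeric matrix of grayscale values (0-255 or normalised; the
#'   ratio is invariant to uniform rescaling).
#' @param plaqueMask,lawnMask logical matrices of the same shape.
#' @param fun summary statistic within a mask (default \code{mean}).
#' @return the intensity ratio.
#' @examples
#' img <- matrix(200, 10, 10); img[4:6, 4:6] <- 50
#' pm <- lm <- matrix(FALSE, 10, 10); pm[4:6, 4:6] <- TRUE; lm[1:2, ] <- TRUE
#' plaqueLawnRatio(img, pm, lm) # 0.25
#' @export
plaqueLawnRatio <- function(pixels, plaqueMask, lawnMask, fun = mean) {
    pixels <- as.matrix(pixels)
    if (!identical(dim(pixels), dim(plaqueMask)) ||
        !identical(dim(pixels), dim(lawnMask)))
        stop("mask shapes must match the image")
    if (!any(plaqueMask) || !any(lawnMask))
        stop("masks must be nonempty")
    if (any(plaqueMask & lawnMask))
        stop("plaque and lawn masks must be disjoint")
    lawn <- fun(pixels[lawnMask])
    if (lawn == 0) stop("zero lawn intensity: ratio undefined")
    fun(pixels[plaqueMask]) / lawn
}

#' Aggregate replicate plaque/lawn ratios
#'
#' @param ratios numeric vector of per-replicate ratios (e.g. three plaques).
#' @return list with mean and sample SD (SD is 0 for a single replicate set of
#'   identical values, NA for n = 1).
#' @examples
#' summarizeRatios(c(0.8, 1.0, 1.2)) # mean 1, sd 0.2
#' @export
summarizeRatios <- function(ratios) {
    list(mean = mean(ratios), sd = stats::sd(ratios), n = length(ratios))
}

#' Phage adsorption efficiency from PFU counts
#'
#' (PFU_control - PFU_sample) / PFU_control x 100%.  Values may be negative
#' when the sample exceeds the control; they are reported as-is and flagged
#' with a warning.
#'
#' @param pfuControl PFU counts of the no-cell (or control) titration (> 0).
#' @param pfuSample free-phage PFU counts after incubation with cells (>= 0).
#' @return percent of phage adsorbed (vectorised).
#' @examples
#' adsorptionEfficiency(100, 25) # 75
#' @export
adsorptionEfficiency <- function(pfuControl, pfuSample) {
    if (any(pfuControl <= 0))
        stop("'pfuControl' must be > 0")
    if (any(pfuSample < 0))
        stop("'pfuSample' must be >= 0")
    out <- (pfuControl - pfuSample) / pfuControl * 100
    if (any(out < 0))
        warning("negative adsorption efficiency: sample exceeds control")
    out
}

#' Adsorption timecourse
#'
#' Applies [adsorptionEfficiency()] per timepoint and reports both the percent
#' adsorbed and the percent of free phage remaining (their sum is exactly
#' 100).
#'
#' @param timepoints timepoints in minutes.
#' @param pfuControl,pfuSample PFU counts per timepoint.
#' @return data.frame with columns time, adsorbed_pct, remaining_pct.
#' @export
adsorptionTimecourse <- function(timepoints, pfuControl, pfuSample) {
    stopifnot(length(timepoints) == length(pfuControl),
              length(timepoints) == length(pfuSample))
    ads <- adsorptionEfficiency(pfuControl, pfuSample)
    data.frame(time = timepoints, adsorbed_pct = ads,
               remaining_pct = 100 - ads)
}

#' Read a grayscale intensity image
#'
#' Reads PNG or TIFF (via the optional png/tiff packages) or a plain numeric
#' text grid (whitespace-separated).  Multi-channel images are averaged to
#' grayscale.
#'
#' @param path image path (.png, .tif/.tiff, or text grid).
#' @return numeric matrix.
#' @export
readIntensityImage <- function(path) {
    ext <- tolower(tools::file_ext(path))
    img <- if (ext == "png") {
        if (!requireNamespace("png", quietly = TRUE))
            stop("reading PNG requires the 'png' package")
        png::readPNG(path)
    } else if (ext %in% c("tif", "tiff")) {
        if (!requireNamespace("tiff", quietly = TRUE))
            stop("reading TIFF requires the 'tiff' package")
        tiff::readTIFF(path)
    } else {
        as.matrix(read.delim(path, header = FALSE, sep = ""))
    }
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    unname(as.matrix(img))
}
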