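## Physical observable utilities used alongside nanostructure
## characterization: DLS weighting conversion and tetrahedron geometry.

#' Construct a size distribution
#'
#' @param diameter bin diameters, nm.
#' @param weight bin weights; normalized to sum to 1.
#' @param weighting \code{"intensity"} or \code{"number"}.
#' @return a [SizeDistribution-class].
#' @export
sizeDistribution <- function(diameter, weight, weighting = "intensity") {
    if (any(diameter <= 0)) stop("diameters must be positive")
    if (any(weight < 0)) stop("weights must be non-negative")
    s <- sum(weight)
    if (s <= 0) stop("weights must not all be zero")
    new("SizeDistribution", diameter = as.numeric(diameter),
        weight = as.numeric(weight / s), weighting = weighting)
}

setMethod("show", "SizeDistribution", function(object) {
    cat(sprintf("SizeDistribution (%s-weighted), %d bins\n",
        object@weighting, length(object@diameter)))
    invisible(object)
})

#' Convert an intensity-weighted distribution to number weighting
#'
#' Scattering intensity grows with the sixth power of particle radius, so
#' large particles dominate intensity-weighted DLS distributions. The
#' number-weighted distribution is recovered as
#' \eqn{w_{num} \propto w_{int} / d^6}, renormalized. Scale-invariant in the
#' input weights; a single-bin distribution is unchanged.
#'
#' @param dist an intensity-weighted [SizeDistribution-class].
#' @return a number-weighted [SizeDistribution-class].
#' @examples
#' d <- sizeDistribution(c(10, 20), c(0.5, 0.5))
#' intensityToNumber(d)@weight  # 64:1
#' @export
intensityToNumber <- function(dist) {
    if (dist@weighting != "intensity")
        stop("input must be intensity-weighted")
    w <- dist@weight / dist@diameter^6
    sizeDistribution(dist@diameter, w, weighting = "number")
}

#' Convert a number-weighted distribution back to intensity weighting
#'
#' @param dist a number-weighted [SizeDistribution-class].
#' @return an intensity-weighted [SizeDistribution-class].
#' @export
numberToIntensity <- function(dist) {
    if (dist@weighting != "number")
        stop("input must be number-weighted")
    sizeDistribution(dist@diameter, dist@weight * dist@diameter^6,
                     weighting = "intensity")
}

#' Read a DLS distribution from a two-column TSV
#'
#' Expected columns: diameter (nm) and intensity weight.
#'
#' @param file path to the TSV.
#' @return an intensity-weighted [SizeDistribution-class].
#' @export
readDLS <- function(file) {
    tab <- utils::read.table(file, header = TRUE, sep = "\t")
    sizeDistribution(tab[[1L]], tab[[2L]], weighting = "intensity")
}

#' Height of a regular DNA tetrahedron
#'
#' Edge length is \code{edgeBP} base pairs times the helical rise; the
#' height of a regular tetrahedron with edge \eqn{a} is
#' \eqn{a \sqrt{2/3}}. The helix diameter is deliberately not added (the
#' estimate is the vertex-to-face distance of the edge skeleton).
#'
#' @param edgeBP base pairs per edge (>= 1).
#' @param riseNmPerBP helical rise, nm per bp (B-form default 0.34).
#' @return height in nm.
#' @examples
#' tetrahedronHeight(20)  # ~5.55 nm
#' @export
tetrahedronHeight <- function(edgeBP, riseNmPerBP = 0.34) {
    if (any(edgeBP < 1)) stop("edgeBP must be at least 1")
    edgeBP * riseNmPerBP * sqrt(2 / 3)
}
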