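#' Round half away from zero
#'
#' Commercial rounding used throughout for display and copy-number
#' conversion: 2.5 -> 3, -2.5 -> -3, 5.28 -> 5, 2.83 -> 3. Base R's
#' \code{round()} rounds half to even and would not reproduce these
#' conversions at the .5 boundary.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' roundHalfAwayFromZero(c(2.5, -2.5, 5.28, 2.83))
roundHalfAwayFromZero <- function(x) {
    sign(x) * floor(abs(x) + 0.5)
}

## canonical variant key: one string per (chrom, pos, ref, alt)
variantKey <- function(chrom, pos, ref, alt) {
    paste(chrom, pos, ref, alt, sep = ":")
}

#' Closed vocabulary of variant classes
#'
#' Variant consequence classes used by the somatic and catalog filters.
#' The coding classes (missense, nonsense, insertion, deletion, silent)
#' are the ones the catalog competence filter retains; splice, UTR and RNA
#' variants are excluded from per-gene silent-fraction statistics.
#'
#' @return character vector of recognized classes.
#' @export
variantClasses <- function() {
    c("missense", "nonsense", "insertion", "deletion", "silent",
      "splice", "UTR", "RNA", "other")
}

codingClasses <- function() {
    c("missense", "nonsense", "insertion", "deletion", "silent")
}

#' Normalize MAF Variant_Classification strings
#'
#' Maps standard MAF \code{Variant_Classification} values (e.g.
#' \code{Missense_Mutation}, \code{Frame_Shift_Del}, \code{Silent},
#' \code{3'UTR}) onto the package's closed vocabulary. Values already in
#' the vocabulary pass through; anything unrecognized becomes
#' \code{"other"}.
#'
#' @param x character vector of classification strings.
#' @return character vector over [variantClasses()].
#' @export
#' @examples
#' normalizeVariantClass(c("Missense_Mutation", "Silent", "Frame_Shift_Ins"))
normalizeVariantClass <- function(x) {
    x <- as.character(x)
    out <- rep("other", length(x))
    out[x %in% variantClasses()] <- x[x %in% variantClasses()]
    map <- c(
        Missense_Mutation = "missense",
        Nonsense_Mutation = "nonsense",
        Nonstop_Mutation  = "nonsense",
        Silent            = "silent",
        Frame_Shift_Ins   = "insertion",
        In_Frame_Ins      = "insertion",
        Frame_Shift_Del   = "deletion",
        In_Frame_Del      = "deletion",
        Splice_Site       = "splice",
        Splice_Region     = "splice",
        RNA               = "RNA",
        lincRNA           = "RNA"
    )
    hit <- x %in% names(map)
    out[hit] <- unname(map[x[hit]])
    utr <- grepl("UTR", x, fixed = TRUE)
    out[utr] <- "UTR"
    out
}

stopIfNot1 <- function(cond, msg, ...) {
    if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
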