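#' Round half away from zero
#'
#' Decimal rounding in the convention of clinical reporting (0.125 -> 0.13
#' at 2 digits), unlike base `round()`'s round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# report formatting: volumes to 3 significant figures, CoV/fractions to
# 2 decimals, half away from zero; NA renders blank.
fmtVolume <- function(x) ifelse(is.na(x), "", signif(x, 3))
fmtCov <- function(x) ifelse(is.na(x), "", sprintf("%.2f", roundHalfUp(x, 2)))

iovLog <- function(config, ...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    if (!is.null(config$logFile))
        cat(msg, "\n", file = config$logFile, append = TRUE, sep = "")
    if (is.null(config$quiet) || !isTRUE(config$quiet)) message(msg)
    invisible(NULL)
}
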