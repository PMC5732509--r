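#' Age bands and stock layout
#'
#' The population aged 20+ is stratified into six ten-year age bands
#' (the last one open-ended) and three health states: `NDM` (no diabetes),
#' `DM` (diabetes, not on dialysis) and `DMDi` (on dialysis due to diabetic
#' nephropathy).  Dialysis stocks exist only from age 40 upward; dialysis
#' patients under 40 are outside the model and enter it as an exogenous
#' inflow at age 40.  The per-sex state vector therefore has 16 stocks.
#'
#' @return `age_bands()` returns the six band labels in order;
#'   `stock_names()` returns the 16 stock names in canonical order
#'   (6 NDM, 6 DM, 4 DMDi).
#' @examples
#' age_bands()
#' stock_names()
#' @export
age_bands <- function() c("2029", "3039", "4049", "5059", "6069", "over70")

#' @rdname age_bands
#' @export
stock_names <- function() {
  b <- age_bands()
  c(paste0("NDM", b), paste0("DM", b), paste0("DMDi", b[3:6]))
}

# index helpers for the canonical 16-vector
.idx_ndm  <- 1:6
.idx_dm   <- 7:12
.idx_dmdi <- 13:16
# DM bands >= 4049 (sources of dialysis initiation)
.idx_dm40 <- 9:12

# band width in years; over70 is terminal (no aging outflow)
.BAND_WIDTH <- 10

# per-stock aging outflow rate (1/yr): stock/width for closed bands, 0 for
# the terminal band of each chain
.aging_rates <- function() {
  r <- rep(1 / .BAND_WIDTH, 16)
  r[c(6, 12, 16)] <- 0
  r
}

.SEXES <- c("male", "female")

.check_sex <- function(sex) {
  if (!is.character(sex) || length(sex) != 1L || !sex %in% .SEXES)
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  sex
}
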