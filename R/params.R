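#' Model parameters of the aging chain
#'
#' The unknowns estimated by calibration: sex-specific constant
#' diabetes-incidence rates (one per age band, hazard of NDM -> DM),
#' dialysis-initiation rates (one per band from 40-49 up, hazard of
#' DM -> DMDi), and the initial stock vector at the start year.
#'
#' @param sex `"male"` or `"female"`.
#' @param ir_dm Numeric length 6, diabetes incidence per band (1/yr), in
#'   [age_bands()] order. Conventional names `DM2029ir` ... `DMover70ir`.
#' @param ir_di Numeric length 4, dialysis-initiation rate for bands 4049,
#'   5059, 6069, over70 (1/yr). Names `DMDi4049ir` ... `DMDiover70ir`.
#' @param init Numeric length 16 in [stock_names()] order: stock values
#'   (persons) at `start_year`.
#' @param start_year First simulated calendar year (default 2000).
#' @return An object of class `dmchain_params`.
#' @export
dmchain_params <- function(sex, ir_dm, ir_di, init, start_year = 2000) {
  .check_sex(sex)
  stopifnot(length(ir_dm) == 6L, length(ir_di) == 4L, length(init) == 16L)
  if (any(ir_dm < 0) || any(ir_di < 0))
    stop("incidence rates must be non-negative", call. = FALSE)
  if (any(init < 0))
    stop("initial stocks must be non-negative", call. = FALSE)
  ir_dm <- stats::setNames(as.numeric(ir_dm), rate_names()$dm)
  ir_di <- stats::setNames(as.numeric(ir_di), rate_names()$di)
  init  <- stats::setNames(as.numeric(init), stock_names())
  structure(list(sex = sex, ir_dm = ir_dm, ir_di = ir_di, init = init,
                 start_year = as.integer(start_year)),
            class = "dmchain_params")
}

#' @rdname dmchain_params
#' @return `rate_names()` returns the conventional names of the ten
#'   calibrated rates, split into the `dm` and `di` families.
#' @export
rate_names <- function() {
  b <- age_bands()
  list(dm = paste0("DM", b, "ir"), di = paste0("DMDi", b[3:6], "ir"))
}

# calibration bounds on the rate families (1/yr)
.RATE_BOUNDS <- list(dm = c(0, 0.05), di = c(0, 0.02))
# initial stocks searched within +/- 20% of the start-year observations
.INIT_BOUNDS <- c(0.8, 1.2)

#' @export
print.dmchain_params <- function(x, ...) {
  cat("Aging-chain parameters (", x$sex, "), start year ", x$start_year,
      "\n", sep = "")
  cat("  diabetes incidence (1/yr):\n")
  print(signif(x$ir_dm, 4))
  cat("  dialysis initiation (1/yr):\n")
  print(signif(x$ir_di, 4))
  cat("  initial population 20+:", format(round(sum(x$init)), big.mark = ","),
      "persons\n")
  invisible(x)
}
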