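#' Observation cross-table for calibration
#'
#' Holds, per sex, the annual sex- and age-band-specific observation
#' series the model is calibrated against — population, diabetics not on
#' dialysis, and dialysis patients due to diabetic nephropathy (bands
#' 40-49 and older only) — together with the exogenous inputs
#' ([dmchain_exog]) that drive the simulation.
#'
#' @param ... One or two per-sex components, each a list with elements
#'   `sex`, `years`, `pop` (years x 6 matrix), `dm` (years x 6),
#'   `di` (years x 4), `exog` (a [dmchain_exog]).  Usually constructed by
#'   [generate_synthetic_country()] or [build_japan_like_fixture()] rather
#'   than by hand.
#' @return An object of class `dmchain_data`, a list keyed by sex.
#' @export
dmchain_data <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.null(parts[[1L]]$sex)) parts <- parts[[1L]]
  out <- list()
  for (p in parts) {
    .validate_sex_block(p)
    out[[p$sex]] <- p
  }
  if (!length(out)) stop("no per-sex data supplied", call. = FALSE)
  structure(out, class = "dmchain_data")
}

.validate_sex_block <- function(p) {
  .check_sex(p$sex)
  bad <- character()
  b <- age_bands()
  ny <- length(p$years)
  for (nm in c("pop", "dm")) {
    m <- p[[nm]]
    if (!is.matrix(m) || nrow(m) != ny || ncol(m) != 6L)
      bad <- c(bad, sprintf("%s must be a %d x 6 matrix", nm, ny))
  }
  if (!is.matrix(p$di) || nrow(p$di) != ny || ncol(p$di) != 4L)
    bad <- c(bad, sprintf("di must be a %d x 4 matrix (bands >= 4049)", ny))
  if (!length(bad)) {
    if (any(p$pop < 0) || any(p$dm < 0) || any(p$di < 0))
      bad <- c(bad, "negative counts present")
    di6 <- cbind(matrix(0, ny, 2L), p$di)
    viol <- which(p$dm + di6 > p$pop * (1 + 1e-9), arr.ind = TRUE)
    if (nrow(viol))
      bad <- c(bad, paste0("dm + dialysis exceeds pop at (",
                           paste(p$years[viol[, 1L]], b[viol[, 2L]],
                                 sep = ", ", collapse = "), ("), ")"))
  }
  if (!inherits(p$exog, "dmchain_exog"))
    bad <- c(bad, "exog must be a dmchain_exog object")
  if (length(bad))
    stop("invalid observation data (", p$sex, "):\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(p)
}

#' @export
print.dmchain_data <- function(x, ...) {
  for (p in x) {
    yr <- range(p$years)
    cat(sprintf(
      "%s: %d-%d | pop20+ %.1fM -> %.1fM | DM %.2fM -> %.2fM | dialysis %s -> %s\n",
      p$sex, yr[1L], yr[2L],
      sum(p$pop[1L, ]) / 1e6, sum(p$pop[nrow(p$pop), ]) / 1e6,
      (sum(p$dm[1L, ]) + sum(p$di[1L, ])) / 1e6,
      (sum(p$dm[nrow(p$dm), ]) + sum(p$di[nrow(p$di), ])) / 1e6,
      format(round(sum(p$di[1L, ])), big.mark = ","),
      format(round(sum(p$di[nrow(p$di), ])), big.mark = ",")))
  }
  invisible(x)
}

# ---- tidy CSV dialect: (year, sex, age_band, variable, value) ------------

#' @describeIn dmchain_data Long-format view in the package's CSV dialect.
#' @param x A `dmchain_data` object.
#' @param row.names,optional Passed for S3 compatibility; unused.
#' @export
as.data.frame.dmchain_data <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  b <- age_bands()
  rows <- list()
  for (p in x) {
    ny <- length(p$years)
    wide <- function(mat, bands, var) data.frame(
      year = rep(p$years, length(bands)), sex = p$sex,
      age_band = rep(bands, each = ny), variable = var,
      value = as.vector(mat))
    e <- p$exog
    mort_n <- t(e$mort[.idx_ndm, , drop = FALSE])
    mort_d <- t(e$mort[.idx_dm, , drop = FALSE])
    mort_i <- t(e$mort[.idx_dmdi, , drop = FALSE])
    rows[[p$sex]] <- rbind(
      wide(p$pop, b, "pop"),
      wide(p$dm, b, "dm"),
      wide(p$di, b[3:6], "dialysis_dn"),
      data.frame(year = as.integer(names(e$entry20)), sex = p$sex,
                 age_band = "all", variable = "entry20",
                 value = unname(e$entry20)),
      data.frame(year = e$years, sex = p$sex, age_band = "all",
                 variable = "dialysis_entry40",
                 value = unname(e$dial_entry40)),
      wide(mort_n, b, "mort_ndm"),
      wide(mort_d, b, "mort_dm"),
      wide(mort_i, b[3:6], "mort_dmdi"),
      data.frame(year = e$years[1L], sex = p$sex, age_band = "all",
                 variable = "entry_dm_prev", value = e$entry_dm_prev))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the observation cross-table
#'
#' Serializes a [dmchain_data] object to the package's tidy CSV dialect
#' with columns `(year, sex, age_band, variable, value)` and reads it back
#' with full invariant checking. `validate_dataset()` is the reader: every
#' violation found (unknown band or variable, negative counts, dm +
#' dialysis exceeding the population, missing years, dialysis counts in an
#' under-40 band) is collected and reported together with row context.
#'
#' @param data A `dmchain_data` object.
#' @param path CSV file path.
#' @return `validate_dataset()` returns the parsed `dmchain_data`.
#' @export
write_dmchain_data <- function(data, path) {
  stopifnot(inherits(data, "dmchain_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dmchain_data
#' @export
validate_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "sex", "age_band", "variable", "value")
  if (!all(need %in% names(df)))
    stop("CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  problems <- character()
  b <- age_bands()
  vars_band <- c("pop", "dm", "dialysis_dn", "mort_ndm", "mort_dm",
                 "mort_dmdi")
  vars_all <- c("entry20", "dialysis_entry40", "entry_dm_prev")
  bad_var <- !df$variable %in% c(vars_band, vars_all)
  if (any(bad_var))
    problems <- c(problems, paste0("unknown variable(s): ",
                                   paste(unique(df$variable[bad_var]),
                                         collapse = ", ")))
  bad_band <- df$variable %in% vars_band & !df$age_band %in% b
  if (any(bad_band))
    problems <- c(problems,
                  paste0("unknown age_band in rows ",
                         paste(utils::head(which(bad_band), 5), collapse = ", ")))
  young_di <- df$variable %in% c("dialysis_dn", "mort_dmdi") &
    df$age_band %in% b[1:2]
  if (any(young_di))
    problems <- c(problems, paste0(
      "dialysis variables are undefined for bands 2029/3039 (rows ",
      paste(utils::head(which(young_di), 5), collapse = ", "), ")"))
  cnt <- df$variable %in% c("pop", "dm", "dialysis_dn")
  if (any(df$value[cnt] < 0, na.rm = TRUE))
    problems <- c(problems, "negative counts present")
  if (length(problems))
    stop("invalid dataset:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)

  parts <- lapply(split(df, df$sex), .parse_sex_block)
  do.call(dmchain_data, unname(parts))
}

.parse_sex_block <- function(df) {
  sex <- df$sex[1L]
  b <- age_bands()
  yrs <- sort(unique(df$year[df$variable == "pop"]))
  grab <- function(var, bands) {
    m <- matrix(NA_real_, length(yrs), length(bands),
                dimnames = list(yrs, bands))
    sub <- df[df$variable == var, ]
    idx <- cbind(match(sub$year, yrs), match(sub$age_band, bands))
    ok <- stats::complete.cases(idx)
    m[idx[ok, , drop = FALSE]] <- sub$value[ok]
    if (anyNA(m)) {
      miss <- which(is.na(m), arr.ind = TRUE)
      stop("missing ", var, " (", sex, ") for year/band: ",
           paste(paste(yrs[miss[, 1L]], bands[miss[, 2L]], sep = "/"),
                 collapse = ", "), call. = FALSE)
    }
    m
  }
  series <- function(var) {
    sub <- df[df$variable == var, ]
    stats::setNames(sub$value, sub$year)[order(sub$year)]
  }
  mort <- rbind(t(grab("mort_ndm", b)), t(grab("mort_dm", b)),
                t(grab("mort_dmdi", b[3:6])))
  exog <- dmchain_exog(
    sex, yrs, entry20 = series("entry20"),
    dial_entry40 = series("dialysis_entry40")[as.character(yrs)],
    mort = mort,
    entry_dm_prev = unname(series("entry_dm_prev")[1L]))
  list(sex = sex, years = yrs, pop = grab("pop", b), dm = grab("dm", b),
       di = grab("dialysis_dn", b[3:6]), exog = exog)
}
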