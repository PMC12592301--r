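#' Productivity constants for unimproved cattle
#'
#' Ethnographic per-animal productivity parameters. Defaults are averages
#' for modern unimproved African herds: 42.3 kg milk per month while calves
#' suckle, a 9.18-month suckling period within an 18.36-month calving
#' interval, first calving at 42 months, 68.4% of milk consumed by the
#' calf, meat-and-offal weight (MOW) 49.95% of live weight, dry-matter feed
#' intake 2.475% of live weight per day, and USDA nutrient densities for
#' milk (0.0333 kg protein, 0.0375 kg fat, 670 kcal per kg) and MOW
#' (0.1942 kg protein, 0.1273 kg fat, 1980 kcal per kg).
#'
#' @param milk_suckling kg milk produced per month while the calf suckles.
#' @param suckling_months length of the suckling period, months.
#' @param calving_interval mean months between calvings.
#' @param age_first_calving age at first calving, months.
#' @param calf_milk_fraction proportion of milk consumed by the calf.
#' @param mow_fraction_of_liveweight MOW as a proportion of live weight.
#' @param feed_daily_fraction dry-matter feed intake as a proportion of live
#'   weight per day.
#' @param milk_protein,milk_fat kg per kg of milk.
#' @param milk_kcal kcal per kg of milk.
#' @param mow_protein,mow_fat kg per kg of MOW.
#' @param mow_kcal kcal per kg of MOW.
#' @return An object of class `productivity_constants` (a validated list).
#' @export
productivity_constants <- function(milk_suckling = 42.3,
                                   suckling_months = 9.18,
                                   calving_interval = 18.36,
                                   age_first_calving = 42,
                                   calf_milk_fraction = 0.684,
                                   mow_fraction_of_liveweight = 0.4995,
                                   feed_daily_fraction = 0.02475,
                                   milk_protein = 0.0333,
                                   milk_fat = 0.0375,
                                   milk_kcal = 670,
                                   mow_protein = 0.1942,
                                   mow_fat = 0.1273,
                                   mow_kcal = 1980) {
  out <- list(milk_suckling = milk_suckling, suckling_months = suckling_months,
              calving_interval = calving_interval,
              age_first_calving = age_first_calving,
              calf_milk_fraction = calf_milk_fraction,
              mow_fraction_of_liveweight = mow_fraction_of_liveweight,
              feed_daily_fraction = feed_daily_fraction,
              milk_protein = milk_protein, milk_fat = milk_fat,
              milk_kcal = milk_kcal, mow_protein = mow_protein,
              mow_fat = mow_fat, mow_kcal = mow_kcal)
  vals <- unlist(out)
  if (anyNA(vals) || any(vals <= 0))
    stop("all productivity constants must be strictly positive")
  fracs <- c("calf_milk_fraction", "mow_fraction_of_liveweight",
             "feed_daily_fraction")
  for (f in fracs) if (out[[f]] >= 1)
    stop("'", f, "' must lie in (0, 1)")
  class(out) <- "productivity_constants"
  out
}

#' Read productivity constants from a structured text file
#'
#' One `name: value` line per constant; names as in
#' [productivity_constants()]. Missing names keep their defaults.
#'
#' @param path file path.
#' @return a [productivity_constants()].
#' @export
read_constants <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  args <- list()
  valid <- names(formals(productivity_constants))
  for (p in kv) {
    if (length(p) != 2L) stop("malformed constants line: ", paste(p, collapse = ":"))
    key <- trimws(p[[1L]])
    if (!key %in% valid) stop("unknown constant: ", key)
    args[[key]] <- as.numeric(trimws(p[[2L]]))
  }
  do.call(productivity_constants, args)
}

#' Derived productivity quantities
#'
#' Collapses the calving-cycle structure into steady-state monthly rates:
#' milk produced per cow-month (`milk_suckling * suckling_months /
#' calving_interval`), milk available for humans after calf consumption,
#' the monthly birth probability `1 / calving_interval` for cows past first
#' calving, and the monthly feed fraction (daily fraction times 365.25/12
#' days per month).
#'
#' @param constants a [productivity_constants()].
#' @return list with `milk_per_cow_month` (kg), `milk_available` (kg/month),
#'   `birth_prob` (per month), `feed_monthly_fraction` (proportion of live
#'   weight per month).
#' @examples
#' derive_constants(productivity_constants())
#' @export
derive_constants <- function(constants) {
  stopifnot(inherits(constants, "productivity_constants"))
  milk_per_cow_month <- constants$milk_suckling * constants$suckling_months /
    constants$calving_interval
  list(
    milk_per_cow_month = milk_per_cow_month,
    milk_available = milk_per_cow_month * (1 - constants$calf_milk_fraction),
    birth_prob = 1 / constants$calving_interval,
    feed_monthly_fraction = constants$feed_daily_fraction * 365.25 / 12)
}
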