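# Area-proportional production and output-value projection for named
# producing regions.

#' Scale regional production by habitat-area change
#'
#' Under the area-proportionality assumption,
#' `deltaProduction = production * deltaArea / area` (tons) and
#' `deltaValue = deltaProduction * 1000 * price` (currency, price per kg).
#' The relative production change therefore equals the relative area change
#' exactly, and the sign of the production change follows the sign of the
#' area change. Production deltas are also reported rounded to 1 decimal
#' ton, matching how such projections are usually tabulated.
#'
#' @param table data frame with columns `region`, `productionTons`,
#'   `areaKm2`, and optionally `pricePerKg`
#' @param areaChanges data frame with columns `region`, `scenario`,
#'   `period`, `deltaAreaKm2`
#' @return completed data frame with `deltaProductionTons`,
#'   `deltaProductionTonsRounded` and (if prices given) `deltaValue`
#' @examples
#' tab <- data.frame(region = "Qinghai", productionTons = 150,
#'                   areaKm2 = 14.39e4)
#' chg <- data.frame(region = "Qinghai", scenario = "SSP1-2.6",
#'                   period = "2100s", deltaAreaKm2 = 7410)
#' scaleProduction(tab, chg)$deltaProductionTonsRounded  # 7.7
#' @export
scaleProduction <- function(table, areaChanges) {
  stopifnot(all(c("region", "productionTons", "areaKm2") %in% names(table)),
            all(c("region", "deltaAreaKm2") %in% names(areaChanges)))
  if (any(table$productionTons < 0)) stop("production must be >= 0")
  bad <- table$areaKm2 <= 0 & table$productionTons > 0
  if (any(bad))
    stop("zero current area with nonzero production for region(s): ",
         paste(table$region[bad], collapse = ", "))
  out <- merge(areaChanges, table, by = "region", sort = FALSE)
  out$deltaProductionTons <-
    out$productionTons * out$deltaAreaKm2 / out$areaKm2
  out$deltaProductionTonsRounded <- round(out$deltaProductionTons, 1)
  if ("pricePerKg" %in% names(out))
    out$deltaValue <- out$deltaProductionTons * 1000 * out$pricePerKg
  out
}
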