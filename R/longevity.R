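#' Expected maximum longevity from body mass
#'
#' Mammalian allometric expectation `tmax = 4.88 * M^0.153` with adult body
#' mass `M` in grams (the AnAge convention; pass masses in grams or adjust
#' the coefficient for other units).
#'
#' @param mass Adult body mass in grams (> 0).
#' @return Expected maximum longevity in years.
#' @export
expected_tmax <- function(mass) {
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("mass must be positive")
  4.88 * mass^0.153
}

#' Longevity residual table
#'
#' For each species, computes the allometric expected maximum longevity and
#' the longevity residual (observed as a percentage of expected). Rows with
#' missing or non-numeric fields produce per-row error entries rather than
#' failing the table.
#'
#' @param attributes Data frame (or TSV path) with columns `species`,
#'   `mass_g`, `max_longevity_yr`.
#' @return Data frame sorted by descending residual: species, mass_g,
#'   max_longevity_yr, expected_tmax, residual_pct, error.
#' @export
longevity_table <- function(attributes) {
  if (is.character(attributes)) {
    attributes <- read.delim(attributes, comment.char = "#")
  }
  need <- c("species", "mass_g", "max_longevity_yr")
  if (!all(need %in% names(attributes))) {
    stop("attributes need columns: ", paste(need, collapse = ", "))
  }
  if (nrow(attributes) == 0) {
    out <- attributes[, need]
    out$expected_tmax <- out$residual_pct <- numeric(0)
    out$error <- character(0)
    return(out)
  }
  mass <- suppressWarnings(as.numeric(attributes$mass_g))
  lon <- suppressWarnings(as.numeric(attributes$max_longevity_yr))
  err <- rep("", nrow(attributes))
  bad <- is.na(mass) | is.na(lon) | mass <= 0
  err[bad] <- "missing or non-numeric mass/longevity"
  exp_t <- rep(NA_real_, nrow(attributes))
  exp_t[!bad] <- expected_tmax(mass[!bad])
  out <- data.frame(species = attributes$species, mass_g = mass,
                    max_longevity_yr = lon, expected_tmax = exp_t,
                    residual_pct = lon / exp_t * 100, error = err)
  out[order(-out$residual_pct, na.last = TRUE), ]
}
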