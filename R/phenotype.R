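#' Standardize lamb weight gain to a 60-day reference
#'
#' From body mass (grams) measured at an age of 30-80 days, computes the
#' 60-day standardized weight `std_weight_60d_g = 60 * body_mass_g /
#' age_days` and the daily gain `daily_gain_g = body_mass_g / age_days`
#' (the standardized weight divided by 60, in grams per day). Daily gain is
#' the association-scan response. Records with age outside 30-80 days or
#' non-positive mass are rejected with a reason, not dropped silently.
#'
#' @param phenotypes data frame with columns `id`, `body_mass_g`, `age_days`.
#' @param age_range permissible measurement ages in days. Default `c(30, 80)`.
#' @return The input as a tibble with added columns `std_weight_60d_g`,
#'   `daily_gain_g` (`NA` for rejected rows), `accepted` (logical) and
#'   `reject_reason`.
#' @export
standardize_daily_gain <- function(phenotypes, age_range = c(30, 80)) {
  ph <- tibble::as_tibble(phenotypes)
  need <- c("id", "body_mass_g", "age_days")
  miss <- setdiff(need, names(ph))
  if (length(miss) > 0) {
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  ph <- dplyr::mutate(
    ph,
    reject_reason = dplyr::case_when(
      is.na(.data$body_mass_g) | is.na(.data$age_days) ~ "missing value",
      .data$age_days < age_range[1] | .data$age_days > age_range[2] ~
        sprintf("age outside [%g, %g] days", age_range[1], age_range[2]),
      .data$body_mass_g <= 0 ~ "non-positive body mass",
      TRUE ~ NA_character_
    ),
    accepted = is.na(.data$reject_reason),
    std_weight_60d_g = ifelse(.data$accepted,
                              60 * .data$body_mass_g / .data$age_days,
                              NA_real_),
    daily_gain_g = ifelse(.data$accepted,
                          .data$body_mass_g / .data$age_days, NA_real_)
  )
  dplyr::relocate(ph, "std_weight_60d_g", "daily_gain_g", "accepted",
                  "reject_reason", .after = "age_days")
}
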