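# State space and age-band helpers shared by every module.

#' Health states of the lung cancer screening model
#'
#' The cohort model tracks twelve mutually exclusive health states: a
#' disease-free state (`Normal`), carcinoma in situ (`CIS`) and four invasive
#' stages (`StageI`--`StageIV`), one post-treatment maintenance state per
#' cancer stage (periodic follow-up after the main treatment), and `Death`,
#' the unique absorbing state. All transition matrices and cohort traces use
#' the order returned here.
#'
#' @return Character vector of the twelve state labels.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("Normal", "CIS", "StageI", "StageII", "StageIII", "StageIV",
    "MaintCIS", "MaintI", "MaintII", "MaintIII", "MaintIV", "Death")
}

#' @rdname health_states
#' @export
cancer_stages <- function() {
  c("CIS", "StageI", "StageII", "StageIII", "StageIV")
}

#' @rdname health_states
#' @export
maintenance_states <- function() {
  c("MaintCIS", "MaintI", "MaintII", "MaintIII", "MaintIV")
}

#' Maintenance partner of a cancer stage
#'
#' Each cancer stage has exactly one maintenance state entered after the
#' main treatment.
#'
#' @param stage one of [cancer_stages()].
#' @return The label of the partner maintenance state.
#' @export
maintenance_partner <- function(stage) {
  map <- c(CIS = "MaintCIS", StageI = "MaintI", StageII = "MaintII",
           StageIII = "MaintIII", StageIV = "MaintIV")
  if (length(stage) != 1L || !stage %in% names(map)) {
    stop("not a cancer stage: ", paste(stage, collapse = ", "))
  }
  unname(map[[stage]])
}

# Age bands as printed in the input table. Incidence (and lung-cancer
# mortality) bands stop at 74; all-cause mortality extends to 79.
incidence_age_bands <- function() c("50-54", "55-59", "60-64", "65-69", "70-74")
mortality_age_bands <- function() c(incidence_age_bands(), "75-79")

# Return the enclosing band label for an integer age, or error if outside.
age_band_label <- function(age, bands) {
  stopifnot(length(age) == 1L, is.finite(age))
  lower <- as.integer(sub("-.*", "", bands))
  upper <- as.integer(sub(".*-", "", bands))
  if (age < lower[1L] || age > upper[length(upper)]) {
    stop("age ", age, " outside banded range [", lower[1L], ", ",
         upper[length(upper)], "]")
  }
  bands[findInterval(age, lower)]
}
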