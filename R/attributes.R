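#' Default patient-attribute rates
#'
#' Class-conditional probabilities used by [assign_attributes()]. Defaults
#' encode the study clinic's observed composition:
#'
#' * public patients split obstetrics:gynaecology 180:177 (the observed
#'   clinic-process sample sizes);
#' * laboratory visit: 51/180 for public obstetrics, 0 for gynaecology
#'   (the two observed gynaecology laboratory cases were excluded from the
#'   source analysis), 21/32 for private patients;
#' * 10% of public patients seen by a doctor need a specialist
#'   discussion; private patients never do (they are seen by specialists
#'   directly);
#' * elderly share and new-case share are carried as entity attributes for
#'   extensibility but do not alter routing or service draws; walk-ins
#'   default to 0.
#'
#' @param obs_split probability a public patient is obstetrics.
#' @param lab_obs,lab_gyn,lab_private probability of needing the laboratory.
#' @param specialist_discussion probability a public patient needs a
#'   specialist discussion during consultation.
#' @param elderly probability of the `elderly` age group.
#' @param new_case probability an appointment is a new case (else follow-up).
#' @param walk_in probability of a walk-in (else appointment).
#' @return a named list of rates.
#' @export
attribute_rates <- function(obs_split = 180 / 357,
                            lab_obs = 51 / 180,
                            lab_gyn = 0,
                            lab_private = 21 / 32,
                            specialist_discussion = 0.10,
                            elderly = 0.2,
                            new_case = 0.2,
                            walk_in = 0) {
  rates <- list(obs_split = obs_split, lab_obs = lab_obs, lab_gyn = lab_gyn,
                lab_private = lab_private,
                specialist_discussion = specialist_discussion,
                elderly = elderly, new_case = new_case, walk_in = walk_in)
  bad <- vapply(rates, function(p) !is.numeric(p) || p < 0 || p > 1, TRUE)
  if (any(bad)) stop("rates must be probabilities in [0, 1]: ",
                     paste(names(rates)[bad], collapse = ", "))
  rates
}

#' Assign per-patient attributes
#'
#' Draws the attribute vector for `n` patients of one class: the
#' obstetrics/gynaecology subclass (public only), age group, appointment
#' type, laboratory need, and the specialist-discussion flag. The
#' specialist-discussion flag is forced `FALSE` for private patients, who
#' are seen by specialists directly.
#'
#' @param patient_class `"PUBLIC"`, `"PRIVATE"` or `"GENERAL"`.
#' @param n number of patients.
#' @param rates a list from [attribute_rates()].
#' @param seed optional integer seed (the caller's RNG is untouched when
#'   supplied).
#' @return a data frame with columns `class` (`OBS`, `GYN`, `PRIVATE` or
#'   `GENERAL`), `age_group`, `appointment_type`, `needs_lab`,
#'   `needs_specialist`.
#' @examples
#' a <- assign_attributes("PUBLIC", 1000, seed = 1)
#' mean(a$needs_specialist)  # ~0.10
#' @export
assign_attributes <- function(patient_class, n, rates = attribute_rates(),
                              seed = NULL) {
  if (!patient_class %in% c("PUBLIC", "PRIVATE", "GENERAL"))
    stop("unknown patient class: ", patient_class)
  draw <- function() {
    if (n == 0)
      return(data.frame(class = character(), age_group = character(),
                        appointment_type = character(), needs_lab = logical(),
                        needs_specialist = logical()))
    cls <- switch(patient_class,
      PUBLIC = ifelse(stats::runif(n) < rates$obs_split, "OBS", "GYN"),
      PRIVATE = rep("PRIVATE", n),
      GENERAL = rep("GENERAL", n))
    age <- ifelse(stats::runif(n) < rates$elderly, "elderly", "non_elderly")
    u <- stats::runif(n)
    appt <- ifelse(u < rates$walk_in, "walk_in",
                   ifelse(stats::runif(n) < rates$new_case, "new", "follow_up"))
    lab_p <- switch(patient_class,
      PUBLIC = ifelse(cls == "OBS", rates$lab_obs, rates$lab_gyn),
      PRIVATE = rates$lab_private,
      GENERAL = 0)
    needs_lab <- stats::runif(n) < lab_p
    needs_spec <- if (patient_class == "PUBLIC")
      stats::runif(n) < rates$specialist_discussion
    else rep(FALSE, n)
    data.frame(class = cls, age_group = age, appointment_type = appt,
               needs_lab = needs_lab, needs_specialist = needs_spec)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
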