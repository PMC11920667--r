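#' Role policies
#'
#' Policies operationalise how each role chooses among the legal responses
#' at its turn; given a session and the set of legal next acts, a policy
#' always selects a member of that set (or declines, ending the session
#' without agreement).
#'
#' The doctor policy is fixed by clinical role: open with the
#' guideline-recommended plan, answer every question with the supporting
#' arguments from the knowledge base, persuade a rebuttal at most
#' `persuade_budget` times per intervention, and on refusal retract and
#' substitute the rejected component with the best untried alternative
#' (dropping it instead when the component is optional and the alternatives
#' are exhausted).
#'
#' @param persuade_budget how many times the doctor will persuade per
#'   contested intervention before conceding (default 1).
#' @return A `codel_policy` object.
#' @export
doctor_policy <- function(persuade_budget = 1L) {
  stopifnot(persuade_budget >= 0)
  structure(list(role = "doctor",
                 persuade_budget = as.integer(persuade_budget)),
            class = "codel_policy")
}

#' @rdname doctor_policy
#' @param question_budget how many clarification questions the patient asks
#'   before settling (spent on asserts and justifications).
#' @param oppose character vector of intervention names the patient enters
#'   the consultation opposed to.
#' @param rebut_budget how many rebuttals the patient will raise in one
#'   session; once spent, an opposed intervention is refused outright.
#' @param profile a [personality_profile()] (or preset name) governing
#'   whether persuasion flips the patient's stance.
#' @export
patient_policy <- function(question_budget = 1L,
                           oppose = character(),
                           rebut_budget = 1L,
                           profile = personality_preset("open")) {
  if (is.character(profile)) profile <- personality_preset(profile)
  stopifnot(inherits(profile, "codel_personality"),
            question_budget >= 0, rebut_budget >= 0)
  structure(list(role = "patient",
                 question_budget = as.integer(question_budget),
                 oppose = as.character(oppose),
                 rebut_budget = as.integer(rebut_budget),
                 profile = profile),
            class = "codel_policy")
}

#' @export
print.codel_policy <- function(x, ...) {
  cat(sprintf("<codel_policy> role: %s\n", x$role))
  for (nm in setdiff(names(x), c("role", "profile"))) {
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  if (!is.null(x$profile)) {
    cat(sprintf("  profile: K=%g K1=%g K2=%g K3=%g\n", x$profile$K,
                x$profile$K1, x$profile$K2, x$profile$K3))
  }
  invisible(x)
}
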