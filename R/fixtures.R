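#' Bundled case fixtures
#'
#' `build_af_fixture()` assembles the atrial-fibrillation consultation case:
#' a 53-year-old patient with diabetes and heart disease whose guideline
#' plan is cardiac angiography plus surgical ablation, with cardiac
#' ultrasound as the authored alternative to angiography. Three named
#' scenario configurations reproduce the canonical walkthroughs:
#' \describe{
#'   \item{scenario1}{compliant patient: asks one clarification question,
#'     then accepts (mode A).}
#'   \item{scenario2}{hesitant patient: rebuts the angiography out of a
#'     painful past experience but, being open-minded, is persuaded
#'     (mode B).}
#'   \item{scenario3}{firm patient: persistent personality, refuses the
#'     angiography even after persuasion; the plan is revised to cardiac
#'     ultrasound plus surgical ablation (mode C).}
#' }
#'
#' `build_depression_fixture()` assembles the major-depression case: the
#' plan is cognitive behavioural therapy plus an (optional) antidepressant;
#' the patient questions the plan, rebuts the antidepressant over side
#' effects, stays unpersuaded, declines the SSRI alternative, and finally
#' agrees to proceed with CBT alone.
#'
#' @return A list with elements `kb` (the `codel_kb`), `doctor_ast` and
#'   `patient_ast` (the bundled protocols), and `configs`, a named list of
#'   run configurations (each with `doctor_pol`, `patient_pol`, `max_turns`,
#'   `seed`).
#' @export
#' @examples
#' fx <- build_af_fixture()
#' names(fx$configs)
build_af_fixture <- function() {
  kb <- load_kb(system.file("extdata", "af_kb.yaml", package = "codel"))
  list(
    kb = kb,
    doctor_ast = read_protocol(system.file("extdata", "doctor.codel",
                                           package = "codel")),
    patient_ast = read_protocol(system.file("extdata", "patient.codel",
                                            package = "codel")),
    configs = list(
      scenario1 = list(
        doctor_pol = doctor_policy(),
        patient_pol = patient_policy(question_budget = 1L,
                                     profile = "open"),
        max_turns = 50L, seed = 1L),
      scenario2 = list(
        doctor_pol = doctor_policy(),
        patient_pol = patient_policy(question_budget = 0L,
                                     oppose = "cardiac_angiography",
                                     rebut_budget = 1L,
                                     profile = "open"),
        max_turns = 50L, seed = 1L),
      scenario3 = list(
        doctor_pol = doctor_policy(),
        patient_pol = patient_policy(question_budget = 0L,
                                     oppose = "cardiac_angiography",
                                     rebut_budget = 1L,
                                     profile = "persistent"),
        max_turns = 50L, seed = 1L)))
}

#' @rdname build_af_fixture
#' @export
build_depression_fixture <- function() {
  kb <- load_kb(system.file("extdata", "depression_kb.yaml",
                            package = "codel"))
  list(
    kb = kb,
    doctor_ast = read_protocol(system.file("extdata", "doctor.codel",
                                           package = "codel")),
    patient_ast = read_protocol(system.file("extdata", "patient.codel",
                                            package = "codel")),
    configs = list(
      emily = list(
        doctor_pol = doctor_policy(),
        patient_pol = patient_policy(question_budget = 1L,
                                     oppose = c("antidepressant", "ssri"),
                                     rebut_budget = 1L,
                                     profile = "persistent"),
        max_turns = 50L, seed = 1L)))
}

#' @rdname build_af_fixture
#' @param fixture a fixture list from `build_af_fixture()` /
#'   `build_depression_fixture()`.
#' @param scenario name of a configuration in `fixture$configs`.
#' @param seed overrides the configuration's recorded seed if given.
#' @return `run_fixture_scenario` returns the scenario's [transcript()].
#' @export
run_fixture_scenario <- function(fixture, scenario, seed = NULL) {
  cfg <- fixture$configs[[scenario]]
  if (is.null(cfg)) {
    stop(sprintf("unknown scenario `%s`; available: %s", scenario,
                 paste(names(fixture$configs), collapse = ", ")),
         call. = FALSE)
  }
  run_session(fixture$doctor_ast, fixture$patient_ast, fixture$kb,
              doctor_pol = cfg$doctor_pol, patient_pol = cfg$patient_pol,
              max_turns = cfg$max_turns, seed = seed %||% cfg$seed)
}

#' Sweep personality parameters over a scenario
#'
#' Runs one scenario configuration across a grid of personality gains,
#' recording for each profile whether the patient's stance flipped, the
#' session outcome and the decision mode. The grid makes the qualitative
#' trait claims inspectable: along K1 (persistence) the flip indicator is
#' monotone non-increasing, along K2 (openness) monotone non-decreasing.
#'
#' @param fixture a fixture list, e.g. from [build_af_fixture()].
#' @param scenario a configuration name in `fixture$configs` whose patient
#'   opposes an intervention (the persuasion branch must be exercised).
#' @param K1,K2,K3 numeric grids of trait gains.
#' @param K baseline belief degree (scalar).
#' @param seed integer seed recorded in each run.
#' @return A data.frame with columns `K`, `K1`, `K2`, `K3`, `decision`
#'   (`"accept"` or `"refuse"`, the patient's reply to persuasion),
#'   `flipped` (logical), `status`, `mode` and `n_acts`. The
#'   `"boundaries"` attribute summarises the monotone flip boundaries:
#'   the largest still-flipping K1 per (K2, K3) and the smallest flipping
#'   K2 per (K1, K3) (`-Inf`/`Inf` where no grid point flips).
#' @export
#' @examples
#' fx <- build_af_fixture()
#' sw <- personality_sweep(fx, "scenario2", K1 = c(0, 5), K2 = c(0, 5),
#'                         K3 = 0.5)
#' table(sw$mode)
personality_sweep <- function(fixture, scenario = "scenario2",
                              K1 = seq(0, 4.5, by = 0.5),
                              K2 = seq(0, 4.5, by = 0.5),
                              K3 = c(0, 1, 2), K = 1, seed = 1L) {
  cfg <- fixture$configs[[scenario]]
  stopifnot(!is.null(cfg), length(K) == 1L)
  grid <- expand.grid(K1 = K1, K2 = K2, K3 = K3,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pol <- cfg$patient_pol
    pol$profile <- personality_profile(K = K, K1 = grid$K1[i],
                                       K2 = grid$K2[i], K3 = grid$K3[i])
    t <- run_session(fixture$doctor_ast, fixture$patient_ast, fixture$kb,
                     doctor_pol = cfg$doctor_pol, patient_pol = pol,
                     max_turns = cfg$max_turns, seed = seed)
    acts <- transcript_acts(t)
    after <- which(acts == "persuade")[1L] + 1L
    decision <- if (!is.na(after) && after <= length(acts)) {
      acts[after]
    } else {
      NA_character_
    }
    data.frame(K = K, K1 = grid$K1[i], K2 = grid$K2[i], K3 = grid$K3[i],
               decision = decision,
               flipped = identical(decision, "accept"),
               status = t$final_status,
               mode = classify_mode(t)$label,
               n_acts = length(acts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # monotone boundary summaries: per fixed (K2, K3) the largest K1 still
  # flipping, and per fixed (K1, K3) the smallest K2 that flips
  b1 <- do.call(rbind, lapply(split(out, list(out$K2, out$K3), drop = TRUE),
    function(g) data.frame(K2 = g$K2[1], K3 = g$K3[1],
                           max_flipping_K1 = suppressWarnings(
                             max(g$K1[g$flipped])))))
  b2 <- do.call(rbind, lapply(split(out, list(out$K1, out$K3), drop = TRUE),
    function(g) data.frame(K1 = g$K1[1], K3 = g$K3[1],
                           min_flipping_K2 = suppressWarnings(
                             min(g$K2[g$flipped])))))
  rownames(b1) <- rownames(b2) <- NULL
  attr(out, "boundaries") <- list(persistence = b1, openness = b2)
  out
}
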