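#' Start a dialogue session
#'
#' Binds the two role protocols, a guideline knowledge base and the two
#' policies into a runnable session. The protocol bundle must pass the
#' static checker ([check_protocol()]) with no errors, and every
#' intervention a policy references must be defined in the KB.
#'
#' @param doctor_ast,patient_ast `codel_protocol` ASTs.
#' @param kb a `codel_kb`.
#' @param doctor_pol,patient_pol policies from [doctor_policy()] /
#'   [patient_policy()].
#' @param max_turns hard bound on the number of messages (the loop guard for
#'   question-justify and rebuttal-persuade cycles); default 50.
#' @param seed integer recorded in the transcript metadata and used for any
#'   stochastic policy choice.
#' @param subject proposition subject; defaults to the KB condition.
#' @return A `codel_session` with status `"running"`.
#' @export
session_start <- function(doctor_ast, patient_ast, kb,
                          doctor_pol = doctor_policy(),
                          patient_pol = patient_policy(),
                          max_turns = 50L, seed = 1L,
                          subject = kb$condition) {
  stopifnot(inherits(kb, "codel_kb"),
            inherits(doctor_pol, "codel_policy"),
            inherits(patient_pol, "codel_policy"),
            max_turns >= 1L)
  viol <- check_protocol(doctor_ast, patient_ast)
  viol <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(viol)) {
    codel_stop("codel_protocol_violation",
               "protocol bundle fails static checks:\n%s",
               paste("-", viol$detail, collapse = "\n"))
  }
  unknown <- setdiff(patient_pol$oppose, names(kb$interventions))
  if (length(unknown)) {
    codel_stop("codel_unknown_intervention",
               "patient policy opposes intervention(s) not in the KB: %s",
               paste(unknown, collapse = ", "))
  }
  slots <- lapply(kb$recommended_plan, function(nm)
    list(original = nm, current = nm, tried = character()))
  structure(list(
    kb = kb, subject = subject,
    doctor_ast = doctor_ast, patient_ast = patient_ast,
    doctor_state = list(policy = doctor_pol, slots = slots,
                        persuaded = character(), contested = NULL,
                        pending_assert = FALSE),
    patient_state = list(policy = patient_pol,
                         question_budget = patient_pol$question_budget,
                         rebut_budget = patient_pol$rebut_budget,
                         belief = NULL, contested = NULL,
                         current_plan = character()),
    history = list(), status = "running", turn_count = 0L,
    max_turns = as.integer(max_turns), rng_seed = as.integer(seed)),
    class = "codel_session")
}

.current_plan <- function(session) {
  vapply(session$doctor_state$slots, `[[`, character(1), "current")
}

#' Whose turn is it?
#'
#' Turn-taking is strictly alternating with one message in flight; the only
#' sanctioned exception is the compound retract-then-assert, where the
#' retracting speaker immediately speaks again to propose the alternative
#' plan.
#'
#' @param session a `codel_session`.
#' @return `"doctor"` or `"patient"`.
#' @export
whose_turn <- function(session) {
  stopifnot(inherits(session, "codel_session"))
  n <- length(session$history)
  if (n == 0L) return("doctor")
  last <- session$history[[n]]
  if (last$act == "retract") last$sender_role else last$receiver_role
}

#' Advance a session by one message
#'
#' Validates and appends one speech-act message: the session must be
#' running, the sender must hold the turn, and the act must form a legal
#' interaction pair with the previous act (a `retract` may only be followed
#' by an `assert` from the same speaker). Status becomes `"agreed"` when an
#' `accept` lands; exceeding `max_turns` raises a turn-limit error.
#'
#' @param session a running `codel_session`.
#' @param msg a [speech_act_message()] from the agent whose turn it is.
#' @return The updated session.
#' @export
session_step <- function(session, msg) {
  stopifnot(inherits(session, "codel_session"),
            inherits(msg, "codel_message"))
  if (session$status != "running") {
    codel_stop("codel_session_over", "session already ended with status '%s'",
               session$status)
  }
  turn <- whose_turn(session)
  if (msg$sender_role != turn) {
    codel_stop("codel_not_your_turn",
               "it is the %s's turn, but %s attempted to speak",
               turn, msg$sender_role)
  }
  n <- length(session$history)
  if (n > 0L) {
    prev <- session$history[[n]]
    v <- validate_pair(prev$act, msg$act)
    if (!v$legal) {
      codel_stop("codel_illegal_pair", "illegal interaction pair (%s, %s): %s",
                 prev$act, msg$act, v$rationale)
    }
    if (prev$act == "retract" && msg$sender_role != prev$sender_role) {
      codel_stop("codel_illegal_pair",
                 "only the retracting speaker may follow a retract with a new assert")
    }
  } else if (msg$act != "assert" || msg$sender_role != "doctor") {
    codel_stop("codel_protocol_violation",
               "a session must open with an assert by the doctor")
  }
  if (session$turn_count + 1L > session$max_turns) {
    codel_stop("codel_turn_limit", "turn limit of %d messages exceeded",
               session$max_turns)
  }
  session$history[[n + 1L]] <- msg
  session$turn_count <- session$turn_count + 1L
  if (msg$act == "accept") session$status <- "agreed"
  session
}

# ---- doctor behaviour -----------------------------------------------------

.support_ids <- function(kb, interventions) {
  unlist(lapply(interventions, function(iv)
    vapply(find_arguments(kb, iv, "support"), `[[`, character(1), "id")))
}

.against_ids <- function(kb, intervention) {
  vapply(find_arguments(kb, intervention, "against"), `[[`, character(1), "id")
}

# Default text realization: the verbatim KB prose of the cited arguments.
# (The hook point for richer realization is the surface_text field itself.)
.realize <- function(kb, ids) {
  all_args <- do.call(c, lapply(names(kb$interventions), function(iv)
    c(find_arguments(kb, iv, "support"), find_arguments(kb, iv, "against"))))
  texts <- vapply(ids, function(id) {
    hit <- Filter(function(a) a$id == id, all_args)
    if (length(hit)) hit[[1L]]$text else ""
  }, character(1))
  txt <- paste(texts[nzchar(texts)], collapse = " ")
  if (nzchar(txt)) txt else NULL
}

# Decide the doctor's next message. Returns list(msg = codel_message | NULL,
# state = updated doctor_state); NULL msg declines, ending no_agreement.
.doctor_act <- function(session) {
  st <- session$doctor_state
  kb <- session$kb
  plan <- .current_plan(session)
  n <- length(session$history)

  if (n == 0L || st$pending_assert) {
    st$pending_assert <- FALSE
    msg <- speech_act_message(
      "assert", proposition(session$subject, plan),
      sender_role = "doctor", receiver_role = "patient")
    return(list(msg = msg, state = st))
  }

  last <- session$history[[n]]
  if (last$act == "question") {
    ids <- .support_ids(kb, intersect(last$content$plan, plan))
    if (!length(ids)) ids <- .support_ids(kb, plan)
    msg <- speech_act_message(
      "justify", proposition(session$subject, plan),
      sender_role = "doctor", receiver_role = "patient",
      argument_ids = ids, surface_text = .realize(kb, ids))
    return(list(msg = msg, state = st))
  }

  if (last$act == "rebuttal") {
    contested <- intersect(last$content$plan, plan)[1L]
    if (is.na(contested)) contested <- plan[1L]
    st$contested <- contested
    n_persuaded <- sum(st$persuaded == contested)
    if (n_persuaded < st$policy$persuade_budget) {
      st$persuaded <- c(st$persuaded, contested)
      ids <- .support_ids(kb, contested)
      msg <- speech_act_message(
        "persuade", proposition(session$subject, contested),
        sender_role = "doctor", receiver_role = "patient",
        argument_ids = ids, surface_text = .realize(kb, ids))
      return(list(msg = msg, state = st))
    }
    # persuasion budget spent: concede as if refused
    return(.doctor_retract(session, st, contested))
  }

  if (last$act == "refuse") {
    contested <- intersect(last$content$plan, plan)[1L]
    if (is.na(contested)) contested <- st$contested %||% plan[1L]
    return(.doctor_retract(session, st, contested))
  }

  list(msg = NULL, state = st)
}

# Plan substitution after a refusal: retract only if a replacement (or an
# optional drop) exists, otherwise decline so the refusal stands terminal.
.doctor_retract <- function(session, st, contested) {
  kb <- session$kb
  plan <- .current_plan(session)
  idx <- which(vapply(st$slots, function(s) s$current == contested,
                      logical(1)))[1L]
  if (is.na(idx)) return(list(msg = NULL, state = st))
  slot <- st$slots[[idx]]
  rejected_set <- slot$tried
  if (slot$current != slot$original) {
    rejected_set <- union(rejected_set, slot$current)
  }
  alt <- propose_alternative(kb, slot$original, rejected_set)
  if (!is.null(alt)) {
    slot$tried <- union(rejected_set, alt)
    slot$current <- alt
    st$slots[[idx]] <- slot
  } else if (kb$interventions[[slot$original]]$optional) {
    st$slots[[idx]] <- NULL
  } else {
    return(list(msg = NULL, state = st))
  }
  if (length(st$slots) == 0L) return(list(msg = NULL, state = st))
  st$pending_assert <- TRUE
  msg <- speech_act_message(
    "retract", proposition(session$subject, plan),
    sender_role = "doctor", receiver_role = "patient")
  list(msg = msg, state = st)
}

# ---- patient behaviour ----------------------------------------------------

# The patient cascade on receiving an assert or justify: clarify while the
# question budget lasts, then rebut an opposed intervention once, refuse an
# opposed intervention after the rebuttal budget is spent, otherwise accept.
.patient_consider <- function(session, st, plan) {
  kb <- session$kb
  opposed <- intersect(plan, st$policy$oppose)
  if (st$question_budget > 0L) {
    st$question_budget <- st$question_budget - 1L
    msg <- speech_act_message(
      "question", proposition(session$subject, plan),
      sender_role = "patient", receiver_role = "doctor")
    return(list(msg = msg, state = st))
  }
  if (length(opposed) && st$rebut_budget > 0L) {
    contested <- opposed[[1L]]
    st$rebut_budget <- st$rebut_budget - 1L
    st$contested <- contested
    st$belief <- belief_state(
      "oppose",
      aligned_mass = argument_weight_sum(kb, contested, "against"))
    ids <- .against_ids(kb, contested)
    msg <- speech_act_message(
      "rebuttal", proposition(session$subject, contested),
      sender_role = "patient", receiver_role = "doctor",
      argument_ids = ids, surface_text = .realize(kb, ids))
    return(list(msg = msg, state = st))
  }
  if (length(opposed)) {
    msg <- speech_act_message(
      "refuse", proposition(session$subject, opposed),
      sender_role = "patient", receiver_role = "doctor")
    return(list(msg = msg, state = st))
  }
  msg <- speech_act_message(
    "accept", proposition(session$subject, plan),
    sender_role = "patient", receiver_role = "doctor")
  list(msg = msg, state = st)
}

.patient_act <- function(session) {
  st <- session$patient_state
  kb <- session$kb
  n <- length(session$history)
  last <- session$history[[n]]

  if (last$act %in% c("assert", "justify")) {
    if (last$act == "assert") st$current_plan <- last$content$plan
    return(.patient_consider(session, st, st$current_plan))
  }

  if (last$act == "persuade") {
    weights <- vapply(last$argument_ids, function(id) {
      args <- c(find_arguments(kb, st$contested, "support"),
                find_arguments(kb, st$contested, "against"))
      hit <- Filter(function(a) a$id == id, args)
      if (length(hit)) hit[[1L]]$weight else 1
    }, numeric(1))
    st$belief <- apply_arguments(st$belief, weights, "opposing")
    if (decide(st$belief, st$policy$profile) == "flip_stance") {
      st$belief$stance <- "support"
      msg <- speech_act_message(
        "accept", proposition(session$subject, st$current_plan),
        sender_role = "patient", receiver_role = "doctor")
    } else {
      msg <- speech_act_message(
        "refuse", proposition(session$subject, st$contested),
        sender_role = "patient", receiver_role = "doctor")
    }
    return(list(msg = msg, state = st))
  }

  list(msg = NULL, state = st)
}

# ---- session loop ---------------------------------------------------------

#' Run a doctor-patient session to completion
#'
#' Executes the two policies in lockstep under the interaction-pair
#' constraints until the patient accepts (status `agreed`), a party declines
#' to continue (status `no_agreement`), or the turn limit trips. The result
#' is deterministic given the inputs and seed.
#'
#' @inheritParams session_start
#' @return A [transcript()] whose adjacent act pairs are all legal; its
#'   metadata records the seed, the KB condition, the patient profile and
#'   the final plan.
#' @export
#' @examples
#' fx <- build_af_fixture()
#' t1 <- run_session(fx$doctor_ast, fx$patient_ast, fx$kb,
#'                   patient_pol = fx$configs$scenario1$patient_pol)
#' transcript_acts(t1)  # assert question justify accept
run_session <- function(doctor_ast, patient_ast, kb,
                        doctor_pol = doctor_policy(),
                        patient_pol = patient_policy(),
                        max_turns = 50L, seed = 1L,
                        subject = kb$condition) {
  session <- session_start(doctor_ast, patient_ast, kb, doctor_pol,
                           patient_pol, max_turns = max_turns, seed = seed,
                           subject = subject)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  while (session$status == "running") {
    who <- whose_turn(session)
    res <- if (who == "doctor") .doctor_act(session) else .patient_act(session)
    if (is.null(res$msg)) {
      session$status <- "no_agreement"
      break
    }
    session[[paste0(who, "_state")]] <- res$state
    session <- session_step(session, res$msg)
  }

  final_plan <- if (session$status == "agreed") {
    .current_plan(session)
  } else {
    character()
  }
  transcript(
    session$history, session$status,
    metadata = list(
      condition = kb$condition,
      roles = c("doctor", "patient"),
      seed = session$rng_seed,
      max_turns = session$max_turns,
      patient_profile = unclass(session$patient_state$policy$profile),
      patient_policy = list(
        question_budget = patient_pol$question_budget,
        rebut_budget = patient_pol$rebut_budget,
        oppose = patient_pol$oppose),
      final_plan = final_plan))
}

#' Substitute an alternative for a rejected plan component
#'
#' Replaces the rejected intervention, in place, with the highest-priority
#' alternative from the KB that has not already been rejected in this
#' session. When the alternatives are exhausted and the component is flagged
#' optional, the component is dropped; when it is mandatory, a
#' no-alternative error is raised (the session then ends without agreement).
#'
#' @param kb a `codel_kb`.
#' @param plan a [proposition()] whose plan contains `rejected`.
#' @param rejected the refused intervention symbol.
#' @param already_rejected intervention names already turned down.
#' @param alternatives_of the intervention whose authored alternative list
#'   is consulted; defaults to `rejected` itself (it differs when `rejected`
#'   is itself a substitute for an earlier component).
#' @return The updated `codel_proposition`.
#' @export
#' @examples
#' kb <- load_kb(system.file("extdata", "af_kb.yaml", package = "codel"))
#' p <- proposition("atrial_fibrillation",
#'                  c("cardiac_angiography", "surgical_ablation"))
#' substitute_alternative(kb, p, "cardiac_angiography")$plan
substitute_alternative <- function(kb, plan, rejected,
                                   already_rejected = character(),
                                   alternatives_of = rejected) {
  stopifnot(inherits(kb, "codel_kb"), inherits(plan, "codel_proposition"))
  if (!rejected %in% plan$plan) {
    codel_stop("codel_unknown_intervention",
               "`%s` is not part of the plan (%s)",
               rejected, paste(plan$plan, collapse = " + "))
  }
  .get_iv(kb, alternatives_of)
  alt <- propose_alternative(kb, alternatives_of, already_rejected)
  idx <- which(plan$plan == rejected)[1L]
  if (!is.null(alt)) {
    plan$plan[idx] <- alt
  } else if (kb$interventions[[alternatives_of]]$optional) {
    plan$plan <- plan$plan[-idx]
  } else {
    codel_stop("codel_no_alternative",
               "no untried alternative for mandatory intervention `%s`",
               alternatives_of)
  }
  plan
}

#' @export
print.codel_session <- function(x, ...) {
  cat(sprintf("<codel_session> status: %s, %d message(s), turn: %s\n",
              x$status, length(x$history),
              if (x$status == "running") whose_turn(x) else "-"))
  invisible(x)
}
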