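#' Decision propositions
#'
#' A proposition is the content a speech act is about: a subject (typically
#' the diagnosed condition) and a plan, an ordered conjunction of
#' intervention names ("cardiac_angiography + surgical_ablation"). Plan order
#' is preserved for display but is not significant for plan equality.
#'
#' @param subject symbol (character scalar), e.g. a disease name.
#' @param plan character vector of intervention symbols; may be a single
#'   contested intervention for rebuttal/persuade content.
#' @return An object of class `codel_proposition`.
#' @export
#' @examples
#' proposition("atrial_fibrillation",
#'             c("cardiac_angiography", "surgical_ablation"))
proposition <- function(subject, plan = character()) {
  stopifnot(is.character(subject), length(subject) == 1L, nzchar(subject))
  plan <- as.character(plan)
  if (anyNA(plan) || any(!nzchar(plan))) {
    stop("plan symbols must be non-empty strings", call. = FALSE)
  }
  structure(list(subject = subject, plan = plan),
            class = "codel_proposition")
}

#' @rdname proposition
#' @param x,y propositions.
#' @return `same_plan` returns TRUE iff the two plans contain the same
#'   interventions, ignoring order.
#' @export
same_plan <- function(x, y) {
  stopifnot(inherits(x, "codel_proposition"), inherits(y, "codel_proposition"))
  setequal(x$plan, y$plan)
}

#' @export
format.codel_proposition <- function(x, ...) {
  if (length(x$plan)) {
    sprintf("%s: %s", x$subject, paste(x$plan, collapse = " + "))
  } else {
    x$subject
  }
}

#' @export
print.codel_proposition <- function(x, ...) {
  cat("<proposition>", format(x), "\n")
  invisible(x)
}

#' Speech-act messages
#'
#' One performative exchanged between the two roles. Structural rules are
#' enforced at construction: an `assert` or `retract` must carry a non-empty
#' plan, `justify` and `persuade` must carry at least one supporting argument
#' reference, and an agent never addresses itself.
#'
#' @param act a speech-act kind (see [speech_act_kinds()]).
#' @param content a [proposition()].
#' @param sender_role,receiver_role role symbols, e.g. `"doctor"`,
#'   `"patient"`; must differ.
#' @param argument_ids character vector of argument identifiers resolving in
#'   the session's guideline knowledge base (may be empty except for
#'   justify/persuade).
#' @param surface_text optional free-text rendering of the message; the
#'   engine operates on the symbolic act and never interprets this.
#' @return An object of class `codel_message`.
#' @export
#' @examples
#' speech_act_message("assert",
#'   proposition("atrial_fibrillation",
#'               c("cardiac_angiography", "surgical_ablation")),
#'   sender_role = "doctor", receiver_role = "patient")
speech_act_message <- function(act, content, sender_role, receiver_role,
                               argument_ids = character(),
                               surface_text = NULL) {
  assert_act_kind(act, "act")
  stopifnot(inherits(content, "codel_proposition"),
            is.character(sender_role), length(sender_role) == 1L,
            is.character(receiver_role), length(receiver_role) == 1L)
  if (identical(sender_role, receiver_role)) {
    stop("sender_role and receiver_role must differ", call. = FALSE)
  }
  argument_ids <- as.character(argument_ids)
  if (act %in% c("justify", "persuade") && length(argument_ids) == 0L) {
    stop(sprintf("a %s message must carry at least one argument reference",
                 act), call. = FALSE)
  }
  if (act %in% c("assert", "retract") && length(content$plan) == 0L) {
    stop(sprintf("a %s message must carry a non-empty plan", act),
         call. = FALSE)
  }
  if (!is.null(surface_text)) {
    stopifnot(is.character(surface_text), length(surface_text) == 1L)
  }
  structure(list(act = act, content = content,
                 sender_role = sender_role, receiver_role = receiver_role,
                 argument_ids = argument_ids, surface_text = surface_text),
            class = "codel_message")
}

#' @export
format.codel_message <- function(x, ...) {
  args <- if (length(x$argument_ids)) {
    sprintf(" [%s]", paste(x$argument_ids, collapse = ", "))
  } else ""
  sprintf("%s -> %s  %s(%s)%s",
          x$sender_role, x$receiver_role, x$act, format(x$content), args)
}

#' @export
print.codel_message <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
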