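# Static analysis of a two-role protocol bundle: message matching, pair
# legality along every then/or path, guard registration, and or-branch
# ambiguity.

.collect_steps <- function(node) {
  if (inherits(node, "codel_step")) {
    list(node)
  } else if (inherits(node, "codel_then")) {
    c(.collect_steps(node$first), .collect_steps(node$rest))
  } else if (inherits(node, "codel_or")) {
    do.call(c, lapply(node$branches, .collect_steps))
  } else {
    stop("unknown protocol AST node", call. = FALSE)
  }
}

# first/last dialogue acts reachable at the start/end of a node
.first_steps <- function(node) {
  if (inherits(node, "codel_step")) list(node)
  else if (inherits(node, "codel_then")) .first_steps(node$first)
  else do.call(c, lapply(node$branches, .first_steps))
}

.last_steps <- function(node) {
  if (inherits(node, "codel_step")) list(node)
  else if (inherits(node, "codel_then")) .last_steps(node$rest)
  else do.call(c, lapply(node$branches, .last_steps))
}

.acts_of <- function(steps) vapply(steps, `[[`, character(1), "act")

.violation <- function(type, severity, detail) {
  data.frame(type = type, severity = severity, detail = detail,
             stringsAsFactors = FALSE)
}

.no_violations <- function() {
  data.frame(type = character(), severity = character(),
             detail = character(), stringsAsFactors = FALSE)
}

.check_pairs_node <- function(node, who) {
  out <- .no_violations()
  if (inherits(node, "codel_then")) {
    out <- rbind(.check_pairs_node(node$first, who),
                 .check_pairs_node(node$rest, who))
    for (a in unique(.acts_of(.last_steps(node$first)))) {
      for (b in unique(.acts_of(.first_steps(node$rest)))) {
        v <- validate_pair(a, b)
        if (!v$legal) {
          out <- rbind(out, .violation(
            "illegal_pair", "error",
            sprintf("%s protocol sequences (%s, %s): %s", who, a, b,
                    v$rationale)))
        }
      }
    }
  } else if (inherits(node, "codel_or")) {
    out <- do.call(rbind, lapply(node$branches, .check_pairs_node, who = who))
    nb <- length(node$branches)
    for (i in seq_len(nb - 1L)) {
      for (j in seq(i + 1L, nb)) {
        fi <- .first_steps(node$branches[[i]])
        fj <- .first_steps(node$branches[[j]])
        for (si in fi) for (sj in fj) {
          if (si$act == sj$act && is.null(si$guard) && is.null(sj$guard)) {
            out <- rbind(out, .violation(
              "ambiguous_choice", "warning",
              sprintf("%s protocol: or-branches %d and %d both start with unguarded '%s'",
                      who, i, j, si$act)))
          }
        }
      }
    }
  }
  out
}

.step_sig <- function(s) sprintf("%s/%d", s$act, length(s$args))

#' Default guard predicate table
#'
#' Guard predicates are resolved by name against a table supplied when a
#' protocol bundle is checked or a session is started; an unregistered
#' predicate is a static error, never a silent default-true. Each entry is a
#' function of `(kb, args)` returning a logical. The defaults cover the
#' bundled protocols:
#' \describe{
#'   \item{interested_in}{the patient wishes to learn more about the plan —
#'     a policy matter at run time, so the predicate itself is always
#'     satisfiable.}
#'   \item{has_support}{every intervention named in the argument terms that
#'     is defined in the KB has at least one supporting argument.}
#'   \item{has_alternative}{the first argument names an intervention with at
#'     least one authored alternative in the KB.}
#' }
#'
#' @return Named list of predicate functions.
#' @export
default_predicates <- function() {
  list(
    interested_in = function(kb, args) TRUE,
    has_support = function(kb, args) {
      ivs <- intersect(unlist(args), names(kb$interventions))
      all(vapply(ivs, function(iv)
        length(find_arguments(kb, iv, "support")) > 0L, logical(1)))
    },
    has_alternative = function(kb, args) {
      iv <- unlist(args)[1]
      iv %in% names(kb$interventions) &&
        length(kb$interventions[[iv]]$alternatives) > 0L
    }
  )
}

#' Statically check a doctor/patient protocol bundle
#'
#' Verifies that the two role protocols can run together: every message one
#' role sends has a matching receive (same act, same argument arity) in the
#' other role's protocol; every consecutive act pair along every `then`/`or`
#' path is a legal interaction pair (see [validate_pair()]); and every guard
#' predicate is registered in the predicate table. Overlapping unguarded
#' `or` branches are flagged as ambiguity warnings.
#'
#' @param doctor,patient `codel_protocol` ASTs for the two roles.
#' @param predicates named list of guard predicates
#'   (default [default_predicates()]).
#' @return A data.frame of violations with columns `type`, `severity`
#'   (`"error"` or `"warning"`) and `detail`; zero rows when the bundle is
#'   clean. Violations are data, not conditions.
#' @export
#' @examples
#' d <- read_protocol(system.file("extdata", "doctor.codel", package = "codel"))
#' p <- read_protocol(system.file("extdata", "patient.codel", package = "codel"))
#' nrow(check_protocol(d, p))  # 0
check_protocol <- function(doctor, patient, predicates = default_predicates()) {
  stopifnot(inherits(doctor, "codel_protocol"),
            inherits(patient, "codel_protocol"))
  out <- .no_violations()

  protos <- list(doctor = doctor, patient = patient)
  for (who in names(protos)) {
    other <- setdiff(names(protos), who)
    steps <- .collect_steps(protos[[who]]$body)
    peer_steps <- .collect_steps(protos[[other]]$body)
    peer_recv <- vapply(Filter(function(s) s$kind == "receive", peer_steps),
                        .step_sig, character(1))
    for (s in Filter(function(s) s$kind == "send", steps)) {
      if (!.step_sig(s) %in% peer_recv) {
        out <- rbind(out, .violation(
          "unmatched_message", "error",
          sprintf("%s protocol sends %s(%d args) but the %s protocol has no matching receive",
                  who, s$act, length(s$args), other)))
      }
    }
    out <- rbind(out, .check_pairs_node(protos[[who]]$body, who))
    for (s in steps) {
      if (!is.null(s$guard) &&
          !s$guard$predicate_name %in% names(predicates)) {
        out <- rbind(out, .violation(
          "unknown_predicate", "error",
          sprintf("%s protocol uses unregistered guard predicate %s/%d",
                  who, s$guard$predicate_name, length(s$guard$args))))
      }
    }
  }
  rownames(out) <- NULL
  out
}
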