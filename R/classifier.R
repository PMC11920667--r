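#' Classify a transcript into a reusable decision mode
#'
#' Labels a finished dialogue with one of four abstract modes built from its
#' speech-act sequence:
#' \describe{
#'   \item{A}{question resolution: `assert (question justify)+ accept`, with
#'     no rebuttal, refusal or retraction. Any number of question-justify
#'     rounds still counts as A.}
#'   \item{B}{successful persuasion: contains a rebuttal and a persuade,
#'     ends in accept, and contains no retract.}
#'   \item{C}{plan substitution: contains a retract (the plan was revised
#'     after a refusal) and ends in accept; always strictly longer than the
#'     four-act cores of A and B.}
#'   \item{X}{everything else, including any session that ends without
#'     agreement.}
#' }
#' The A/B/C predicates are pairwise disjoint by construction, so every
#' legal transcript receives exactly one label.
#'
#' @param t a `codel_transcript` whose adjacent act pairs are all legal
#'   (checked; an illegal transcript is an error).
#' @return An object of class `codel_mode`: list with `label` (`"A"`,
#'   `"B"`, `"C"` or `"X"`) and `evidence` (character vector of matched
#'   pattern elements).
#' @export
#' @examples
#' fx <- build_af_fixture()
#' t1 <- run_session(fx$doctor_ast, fx$patient_ast, fx$kb,
#'                   patient_pol = fx$configs$scenario1$patient_pol)
#' classify_mode(t1)$label  # "A"
classify_mode <- function(t) {
  stopifnot(inherits(t, "codel_transcript"))
  ok <- audit_transcript(t)
  if (!isTRUE(ok)) {
    codel_stop("codel_illegal_transcript",
               "transcript contains illegal interaction pair(s) at position(s) %s",
               paste(attr(ok, "illegal"), collapse = ", "))
  }
  acts <- transcript_acts(t)
  agreed <- length(acts) > 0L && acts[length(acts)] == "accept" &&
    !identical(t$final_status, "no_agreement")

  if (!agreed) {
    return(.mode_label("X", "session did not end in acceptance"))
  }

  code <- paste(acts, collapse = " ")
  # A: assert, one or more question-justify rounds, accept; nothing else
  if (grepl("^assert( question justify)+ accept$", code)) {
    return(.mode_label("A", c(
      "opens with assert",
      sprintf("%d question-justify round(s)", sum(acts == "question")),
      "ends in accept with no rebuttal, refusal or retraction")))
  }
  if ("retract" %in% acts) {
    return(.mode_label("C", c(
      "contains retract: plan substitution occurred",
      "ends in accept")))
  }
  if ("rebuttal" %in% acts && "persuade" %in% acts) {
    return(.mode_label("B", c(
      "contains rebuttal and persuade",
      "ends in accept with no retraction")))
  }
  .mode_label("X", "act sequence matches none of the named modes")
}

.mode_label <- function(label, evidence) {
  structure(list(label = label, evidence = evidence), class = "codel_mode")
}

#' @export
print.codel_mode <- function(x, ...) {
  cat(sprintf("<codel_mode> %s\n", x$label))
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}
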