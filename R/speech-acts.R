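#' Speech-act kinds
#'
#' The eight performatives available to either role in a shared
#' decision-making dialogue. Every message exchanged by the dialogue engine
#' carries exactly one of these kinds, and the legality of a reply is decided
#' purely by the ordered pair (previous kind, next kind) — see
#' [legal_pairs()].
#'
#' The kinds are: `assert` (state a diagnosis and a proposed care plan),
#' `accept` (agree to the plan), `refuse` (reject outright, without
#' discussion), `question` (ask for clarification), `justify` (answer a
#' question with supporting arguments), `rebuttal` (disagree and give
#' reasons), `persuade` (press the original position with supporting
#' arguments), and `retract` (withdraw an earlier assertion).
#'
#' @return Character vector of the 8 speech-act kind names, in canonical
#'   order.
#' @export
#' @examples
#' speech_act_kinds()
speech_act_kinds <- function() {
  c("assert", "accept", "refuse", "question",
    "justify", "rebuttal", "persuade", "retract")
}

#' @rdname speech_act_kinds
#' @param x character scalar to check.
#' @return `is_speech_act_kind` returns TRUE iff `x` names one of the 8 kinds.
#' @export
is_speech_act_kind <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && x %in% speech_act_kinds()
}

assert_act_kind <- function(x, arg = deparse(substitute(x))) {
  if (!is_speech_act_kind(x)) {
    stop(sprintf("`%s` must be one of the 8 speech-act kinds (%s), got %s",
                 arg, paste(speech_act_kinds(), collapse = ", "),
                 deparse(x)), call. = FALSE)
  }
  invisible(x)
}

# The 14 legal interaction pairs. Descriptions are stored as data attached to
# the pair, not encoded in logic, so documentation and the static checker
# share one source of truth. Row 5 of the underlying table is a compound
# (refuse answered by retract, optionally continued by a fresh assert from
# the same speaker); the pair set holds its first half and the continuation
# is a separate convention (see `continuation` below).
.pair_table <- function() {
  d <- rbind(
    c("assert",   "accept",   "The agent that receives the assertion message evaluates that the assertion is reasonable and feasible, and then sends an acceptance message to explicitly express its agreement with the assertion."),
    c("assert",   "refuse",   "When a proxy receives an assertion message, if it cannot accept the assertion result, it sends a rejection message to explicitly indicate that it does not accept the assertion."),
    c("assert",   "question", "The agent that receives the assertion message further explores the rationality of the assertion by sending a challenge message."),
    c("assert",   "rebuttal", "The agent that receives the assertion message sends a rebuttal message if it disagrees with the assertion."),
    c("refuse",   "retract",  "An agent that receives a rejection message should withdraw its previous assertion and choose whether to send a new assertion based on the current alternatives."),
    c("question", "justify",  "An agent that receives a challenge message should send a confirmation message containing supporting arguments to alleviate the agent's challenge."),
    c("justify",  "question", "When a confirming message is received but doubts remain unresolved, further inquiries or questions can be sent to obtain a more comprehensive understanding."),
    c("justify",  "rebuttal", "The agent that receives the confirmation message sends a rebuttal message if it disagrees with the supporting information."),
    c("rebuttal", "persuade", "The agent that receives the rebuttal message sends a persuasive message to try to change the other party's mind and guide the other party to accept its assertion."),
    c("persuade", "question", "When an agent that receives a persuasion message has doubts about the persuasion argument provided, they may send a questioning message."),
    c("persuade", "accept",   "An agent that receives a persuasion message and believes that the persuasive argument provided is valid will send an acceptance message indicating that it has been persuaded and agrees to accept the assertion issued."),
    c("persuade", "refuse",   "An agent that receives a persuasion message and deems the provided persuasive argument to be invalid sends a rejection message indicating that it is not persuaded and refuses to accept the assertion issued."),
    c("justify",  "accept",   "After evaluating the received confirmation message and finding no objection, the agent sends an acceptance message to explicitly indicate its agreement with the assertion."),
    c("justify",  "refuse",   "When an agent evaluates a confirmation message and still cannot accept its contents, it will send a rejection message to explicitly convey that it does not accept the assertion.")
  )
  data.frame(prev = d[, 1], next_ = d[, 2], description = d[, 3],
             stringsAsFactors = FALSE)
}

#' Registry of legal speech-act interaction pairs
#'
#' The constraint table governing every dialogue transition: an ordered pair
#' (previous act, reply act) is legal iff it appears among the 14 registered
#' interaction pairs, or is the one sanctioned same-speaker continuation —
#' a `retract` immediately followed by a new `assert` by the same agent,
#' offered when the speaker withdraws a refused plan and proposes an
#' alternative.
#'
#' Pairs that invert normal conversational logic are deliberately absent:
#' `refuse` expresses a definitive rejection and admits no `persuade` reply,
#' and an `assert` is never answered by a `justify` (one does not volunteer
#' supporting arguments for the *other* party's claim).
#'
#' @return An object of class `codel_pair_registry`, a list with elements:
#'   \describe{
#'     \item{legal}{data.frame with columns `prev`, `next_`, `description`:
#'       the 14 registered pairs with their one-line rationales.}
#'     \item{continuation}{data.frame of same-speaker continuation pairs
#'       (one row: `retract` then `assert`).}
#'     \item{terminal}{character vector of acts with no legal successor
#'       (`accept`).}
#'     \item{decision}{character vector of the two terminal decision acts a
#'       persuaded party can settle on (`accept`, `refuse`).}
#'   }
#' @export
#' @examples
#' reg <- legal_pairs()
#' nrow(reg$legal)            # 14
#' reg$terminal               # "accept"
legal_pairs <- function() {
  legal <- .pair_table()
  continuation <- data.frame(
    prev = "retract", next_ = "assert",
    description = "After withdrawing a refused assertion the same speaker may immediately send a new assertion built from the current alternatives.",
    stringsAsFactors = FALSE)
  successors <- unique(c(legal$prev, continuation$prev))
  structure(
    list(legal = legal,
         continuation = continuation,
         terminal = setdiff(speech_act_kinds(), successors),
         decision = c("accept", "refuse")),
    class = "codel_pair_registry")
}

#' @export
print.codel_pair_registry <- function(x, ...) {
  cat("<codel_pair_registry>\n")
  cat(sprintf("  %d legal interaction pairs, %d same-speaker continuation\n",
              nrow(x$legal), nrow(x$continuation)))
  cat("  terminal acts:", paste(x$terminal, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a speech-act interaction pair
#'
#' Decides whether `next` is a legal reply to `prev`, and why. The
#' same-speaker continuation (`retract` followed by `assert`) counts as
#' legal, so a full transcript can be audited pairwise with this predicate
#' alone.
#'
#' @param prev,next_ speech-act kind names (see [speech_act_kinds()]).
#' @return A list with elements `legal` (logical) and `rationale`
#'   (character): for a legal pair, the registered description; for an
#'   illegal one, a short explanation.
#' @export
#' @examples
#' validate_pair("assert", "question")$legal   # TRUE
#' validate_pair("refuse", "persuade")$legal   # FALSE
#' validate_pair("assert", "justify")$legal    # FALSE
validate_pair <- function(prev, next_) {
  assert_act_kind(prev, "prev")
  assert_act_kind(next_, "next_")
  reg <- legal_pairs()
  rows <- rbind(reg$legal, reg$continuation)
  hit <- which(rows$prev == prev & rows$next_ == next_)
  if (length(hit)) {
    list(legal = TRUE, rationale = rows$description[hit[1L]])
  } else {
    list(legal = FALSE,
         rationale = sprintf(
           "the (%s-%s) interaction pair violates the dialogue's behavioural logic and is prohibited",
           prev, next_))
  }
}

#' Legal responses to a speech act
#'
#' @param prev a speech-act kind name.
#' @return Character vector of all kinds `b` for which
#'   `validate_pair(prev, b)` is legal (possibly empty: `accept` is
#'   terminal). For `retract` this is the same-speaker continuation `assert`.
#' @export
#' @examples
#' allowed_responses("assert")    # accept, refuse, question, rebuttal
#' allowed_responses("persuade")  # question, accept, refuse
#' allowed_responses("accept")    # character(0)
allowed_responses <- function(prev) {
  assert_act_kind(prev, "prev")
  reg <- legal_pairs()
  rows <- rbind(reg$legal, reg$continuation)
  rows$next_[rows$prev == prev]
}

#' Export / import the pair registry
#'
#' The registry can be written to and re-read from a plain CSV file (columns
#' `prev`, `next`, `description`, `kind` where kind is `"pair"` or
#' `"continuation"`) so that external tools and documentation share the same
#' table.
#'
#' @param registry a `codel_pair_registry` (defaults to [legal_pairs()]).
#' @param path file path.
#' @return `write_pair_registry` returns `path` invisibly;
#'   `read_pair_registry` returns a `codel_pair_registry`.
#' @export
write_pair_registry <- function(path, registry = legal_pairs()) {
  stopifnot(inherits(registry, "codel_pair_registry"))
  tab <- rbind(
    cbind(registry$legal, kind = "pair"),
    cbind(registry$continuation, kind = "continuation"))
  names(tab)[names(tab) == "next_"] <- "next"
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_registry
#' @export
read_pair_registry <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("prev", "next.", "description", "kind")
  names(tab)[names(tab) == "next."] <- "next_"
  if (!all(c("prev", "next_", "description", "kind") %in% names(tab))) {
    stop("registry file must have columns prev, next, description, kind",
         call. = FALSE)
  }
  bad <- setdiff(c(tab$prev, tab$next_), speech_act_kinds())
  if (length(bad)) {
    stop("registry file names unknown act kinds: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  legal <- tab[tab$kind == "pair", c("prev", "next_", "description")]
  cont <- tab[tab$kind == "continuation", c("prev", "next_", "description")]
  rownames(legal) <- rownames(cont) <- NULL
  successors <- unique(c(legal$prev, cont$prev))
  structure(
    list(legal = legal, continuation = cont,
         terminal = setdiff(speech_act_kinds(), successors),
         decision = c("accept", "refuse")),
    class = "codel_pair_registry")
}
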