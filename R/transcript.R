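#' Dialogue transcripts
#'
#' The ordered, role-attributed record of one session: every speech-act
#' message exchanged, the terminal status (`agreed`, `no_agreement` or
#' `violated`), and run metadata (protocol roles, seed, profiles, final
#' plan). A session counts as agreed exactly when its last act is `accept`.
#'
#' @param messages list of [speech_act_message()] objects.
#' @param final_status one of `"agreed"`, `"no_agreement"`, `"violated"`,
#'   `"running"`.
#' @param metadata named list of run metadata.
#' @return An object of class `codel_transcript`.
#' @export
transcript <- function(messages, final_status, metadata = list()) {
  stopifnot(is.list(messages),
            all(vapply(messages, inherits, logical(1), "codel_message")),
            final_status %in% c("agreed", "no_agreement", "violated", "running"))
  if (length(messages) && messages[[1L]]$act != "assert") {
    stop("a transcript must open with an assert", call. = FALSE)
  }
  structure(list(messages = messages, final_status = final_status,
                 metadata = metadata),
            class = "codel_transcript")
}

#' @rdname transcript
#' @param t a `codel_transcript`.
#' @return `transcript_acts` returns the character vector of act kinds in
#'   order.
#' @export
transcript_acts <- function(t) {
  stopifnot(inherits(t, "codel_transcript"))
  vapply(t$messages, `[[`, character(1), "act")
}

#' Audit a transcript for pairwise legality
#'
#' Checks every adjacent act pair with [validate_pair()].
#'
#' @param t a `codel_transcript`.
#' @return TRUE if all adjacent pairs are legal, otherwise FALSE with
#'   attribute `"illegal"` listing the offending positions.
#' @export
audit_transcript <- function(t) {
  acts <- transcript_acts(t)
  if (length(acts) < 2L) return(TRUE)
  bad <- integer()
  for (k in seq_len(length(acts) - 1L)) {
    if (!validate_pair(acts[k], acts[k + 1L])$legal) bad <- c(bad, k)
  }
  if (length(bad)) structure(FALSE, illegal = bad) else TRUE
}

#' @export
print.codel_transcript <- function(x, ...) {
  cat(sprintf("<codel_transcript> %d messages, status: %s\n",
              length(x$messages), x$final_status))
  for (k in seq_along(x$messages)) {
    cat(sprintf("  %2d. %s\n", k, format(x$messages[[k]])))
  }
  invisible(x)
}

#' Read / write transcript JSON
#'
#' One object per message: `{turn, sender_role, receiver_role, act, subject,
#' plan[], argument_ids[], surface_text}`, wrapped in
#' `{metadata, messages, final_status}`. Files are validated structurally on
#' read; the format is documented by the JSON Schema shipped at
#' `system.file("extdata", "transcript_schema.json", package = "codel")`.
#'
#' @param t a `codel_transcript`.
#' @param path file path.
#' @return `write_transcript` returns `path` invisibly; `read_transcript`
#'   returns a `codel_transcript`.
#' @export
write_transcript <- function(t, path) {
  stopifnot(inherits(t, "codel_transcript"))
  msgs <- lapply(seq_along(t$messages), function(k) {
    m <- t$messages[[k]]
    list(turn = k, sender_role = m$sender_role,
         receiver_role = m$receiver_role, act = m$act,
         subject = m$content$subject, plan = as.list(m$content$plan),
         argument_ids = as.list(m$argument_ids),
         surface_text = m$surface_text)
  })
  jsonlite::write_json(
    list(metadata = t$metadata, messages = msgs,
         final_status = t$final_status),
    path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("messages", "final_status")) {
    if (is.null(raw[[field]])) {
      stop(sprintf("transcript file is missing required field `%s`", field),
           call. = FALSE)
    }
  }
  msgs <- lapply(raw$messages, function(m) {
    need <- c("sender_role", "receiver_role", "act", "subject")
    miss <- need[vapply(need, function(f) is.null(m[[f]]), logical(1))]
    if (length(miss)) {
      stop("transcript message is missing field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    speech_act_message(
      m$act,
      proposition(m$subject, unlist(m$plan) %||% character()),
      sender_role = m$sender_role, receiver_role = m$receiver_role,
      argument_ids = unlist(m$argument_ids) %||% character(),
      surface_text = m$surface_text)
  })
  transcript(msgs, raw$final_status, raw$metadata %||% list())
}
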