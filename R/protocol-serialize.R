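# Canonical serialization of protocol ASTs. The printer is a pure function
# of the tree, so serialize(parse(serialize(x))) == serialize(x) and parsing
# the output reproduces the tree (positions aside).

.ser_term <- function(term) paste(term, collapse = " + ")

.ser_header <- function(h) {
  sprintf("a(%s(%s), %s)", h$role, paste(h$knowledge, collapse = ", "), h$var)
}

.ser_guard <- function(g) {
  sprintf(" <- %s(%s)", g$predicate_name,
          paste(vapply(g$args, .ser_term, character(1)), collapse = ", "))
}

.ser_step <- function(s) {
  sprintf("%s(%s) %s %s%s",
          s$act,
          paste(vapply(s$args, .ser_term, character(1)), collapse = ", "),
          if (s$kind == "send") "=>" else "<=",
          .ser_header(s$peer),
          if (is.null(s$guard)) "" else .ser_guard(s$guard))
}

.ser_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (inherits(node, "codel_step")) {
    paste0(pad, .ser_step(node))
  } else if (inherits(node, "codel_then")) {
    first <- node$first
    first_txt <- if (inherits(first, "codel_step")) {
      paste0(pad, .ser_step(first))
    } else {
      # parenthesize a non-step head so the grouping survives reparsing
      .ser_node_parens(first, indent)
    }
    paste0(first_txt, " then\n", .ser_node(node$rest, indent))
  } else if (inherits(node, "codel_or")) {
    .ser_node_parens(node, indent)
  } else {
    stop("unknown protocol AST node", call. = FALSE)
  }
}

.ser_node_parens <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (inherits(node, "codel_or")) {
    inner <- vapply(node$branches, .ser_node, character(1), indent = indent + 1L)
    paste0(pad, "(\n",
           paste(inner, collapse = paste0("\n", pad, "  or\n")),
           "\n", pad, ")")
  } else {
    paste0(pad, "(\n", .ser_node(node, indent + 1L), "\n", pad, ")")
  }
}

#' Serialize a protocol AST back to CoDeL source
#'
#' Produces canonical, deterministically formatted source: reparsing it
#' yields a structurally identical AST, and serializing again yields the
#' same text (one normalization pass is idempotent).
#'
#' @param ast a `codel_protocol` from [parse_protocol()] or
#'   [proto_protocol()].
#' @return A single string of CoDeL source.
#' @export
#' @examples
#' src <- "a(patient(), P) :: assert(disease, s1 + s2) <= a(doctor(), D)"
#' cat(serialize_protocol(parse_protocol(src)))
serialize_protocol <- function(ast) {
  stopifnot(inherits(ast, "codel_protocol"))
  paste0(.ser_header(ast$header), " ::\n", .ser_node(ast$body, 1L), "\n")
}

#' @rdname serialize_protocol
#' @param path file path to write (`.codel`).
#' @export
write_protocol <- function(ast, path) {
  writeLines(serialize_protocol(ast), path, sep = "")
  invisible(path)
}

#' @export
print.codel_protocol <- function(x, ...) {
  cat(serialize_protocol(x))
  invisible(x)
}
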