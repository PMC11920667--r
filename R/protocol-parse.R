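#' @title The CoDeL protocol notation
#' @description
#' A protocol file defines, for one role, the messages it sends and receives
#' and how steps compose. The ASCII dialect used here transliterates the
#' original glyph notation: `=>` sends a message to the peer, `<=` receives
#' one, `<-` attaches a guard constraint that must hold for the clause to
#' execute, `then` sequences clauses, `or` marks a committed choice between
#' alternative branches (exactly one is taken), and `a(role(knowledge), V)`
#' is an agent header naming the role, its intrinsic knowledge and an agent
#' variable. Plan conjunctions are written `surgery1 + surgery2`. Line
#' comments start with `#`.
#'
#' Example step, as received by the patient:
#' \preformatted{assert(disease, surgery1 + surgery2) <= a(doctor(), D)}
#' and a guarded send:
#' \preformatted{question(disease, surgery1 + surgery2) => a(doctor(), D)
#'     <- interested_in(disease, surgery1 + surgery2)}
#' @name codel_notation
NULL

# ---- tokenizer ------------------------------------------------------------

.token_spec <- list(
  c("WS",     "^[ \t\r]+"),
  c("COMMENT","^#[^\n]*"),
  c("NL",     "^\n"),
  c("DCOLON", "^::"),
  c("SEND",   "^=>"),
  c("RECV",   "^<="),
  c("GUARD",  "^<-"),
  c("LP",     "^\\("),
  c("RP",     "^\\)"),
  c("COMMA",  "^,"),
  c("PLUS",   "^\\+"),
  c("IDENT",  "^[A-Za-z_][A-Za-z0-9_]*")
)

.tokenize <- function(text) {
  toks <- list(); line <- 1L; col <- 1L
  while (nchar(text) > 0L) {
    matched <- FALSE
    for (spec in .token_spec) {
      m <- regexpr(spec[2], text)
      if (m == 1L) {
        len <- attr(m, "match.length")
        val <- substr(text, 1L, len)
        type <- spec[1]
        if (type == "NL") {
          line <- line + 1L; col <- 1L
        } else {
          if (!type %in% c("WS", "COMMENT")) {
            kw <- if (type == "IDENT" && val %in% c("then", "or"))
              toupper(val) else type
            toks[[length(toks) + 1L]] <-
              list(type = kw, value = val, line = line, col = col)
          }
          col <- col + len
        }
        text <- substr(text, len + 1L, nchar(text))
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("syntax error at line %d, column %d: unexpected character '%s'",
                   line, col, substr(text, 1L, 1L)), call. = FALSE)
    }
  }
  toks[[length(toks) + 1L]] <- list(type = "EOF", value = "", line = line, col = col)
  toks
}

# ---- parser state ---------------------------------------------------------

.pstate <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env
}

.peek <- function(st) st$tokens[[st$i]]

.advance <- function(st) {
  tok <- st$tokens[[st$i]]
  st$i <- st$i + 1L
  tok
}

.expect <- function(st, type, what = type) {
  tok <- .peek(st)
  if (tok$type != type) {
    stop(sprintf("syntax error at line %d, column %d: expected %s, got '%s'",
                 tok$line, tok$col, what,
                 if (tok$type == "EOF") "end of input" else tok$value),
         call. = FALSE)
  }
  .advance(st)
}

# ---- AST constructors -----------------------------------------------------

#' Construct protocol AST nodes programmatically
#'
#' These constructors build the same abstract syntax tree that
#' [parse_protocol()] produces, for tests and generated protocols.
#' `proto_then` chains are right-associated; `proto_or` requires at least two
#' branches.
#'
#' @param role role name symbol.
#' @param knowledge character vector of intrinsic-knowledge symbols.
#' @param var agent variable identifier.
#' @return `proto_header` returns a `codel_header`.
#' @export
proto_header <- function(role, var, knowledge = character()) {
  stopifnot(is.character(role), length(role) == 1L, nzchar(role),
            is.character(var), length(var) == 1L, nzchar(var))
  structure(list(role = role, knowledge = as.character(knowledge), var = var),
            class = "codel_header")
}

#' @rdname proto_header
#' @param kind `"send"` or `"receive"`.
#' @param act a speech-act kind.
#' @param args list of terms; each term a character vector (a plan
#'   conjunction, length 1 for a plain symbol).
#' @param peer the peer's `codel_header`.
#' @param guard optional guard, from `proto_guard`.
#' @export
proto_step <- function(kind = c("send", "receive"), act, args, peer,
                       guard = NULL) {
  kind <- match.arg(kind)
  assert_act_kind(act, "act")
  stopifnot(is.list(args), inherits(peer, "codel_header"))
  args <- lapply(args, as.character)
  if (!is.null(guard)) stopifnot(inherits(guard, "codel_guard"))
  structure(list(kind = kind, act = act, args = args, peer = peer,
                 guard = guard),
            class = "codel_step")
}

#' @rdname proto_header
#' @param predicate_name guard predicate symbol.
#' @export
proto_guard <- function(predicate_name, args = list()) {
  stopifnot(is.character(predicate_name), length(predicate_name) == 1L)
  structure(list(predicate_name = predicate_name,
                 args = lapply(args, as.character)),
            class = "codel_guard")
}

#' @rdname proto_header
#' @param first,rest nodes (steps or combinators); `proto_then(first, rest)`
#'   runs `first` and continues with `rest`.
#' @export
proto_then <- function(first, rest) {
  structure(list(first = first, rest = rest), class = "codel_then")
}

#' @rdname proto_header
#' @param branches list of >= 2 nodes; exactly one branch is taken.
#' @export
proto_or <- function(branches) {
  stopifnot(is.list(branches), length(branches) >= 2L)
  structure(list(branches = branches), class = "codel_or")
}

#' @rdname proto_header
#' @param header the protocol's own agent header.
#' @param body the root body node.
#' @export
proto_protocol <- function(header, body) {
  stopifnot(inherits(header, "codel_header"))
  structure(list(header = header, body = body), class = "codel_protocol")
}

# ---- grammar --------------------------------------------------------------

.parse_header <- function(st) {
  tok <- .peek(st)
  if (tok$type != "IDENT" || tok$value != "a") {
    stop(sprintf("malformed agent header at line %d, column %d: expected 'a(role(...), Var)'",
                 tok$line, tok$col), call. = FALSE)
  }
  .advance(st)
  .expect(st, "LP", "'('")
  role <- .expect(st, "IDENT", "role name")$value
  .expect(st, "LP", "'('")
  knowledge <- character()
  if (.peek(st)$type == "IDENT") {
    knowledge <- .expect(st, "IDENT")$value
    while (.peek(st)$type == "COMMA") {
      .advance(st)
      knowledge <- c(knowledge, .expect(st, "IDENT", "knowledge symbol")$value)
    }
  }
  .expect(st, "RP", "')'")
  .expect(st, "COMMA", "','")
  var <- .expect(st, "IDENT", "agent variable")$value
  .expect(st, "RP", "')'")
  proto_header(role, var, knowledge)
}

.parse_term <- function(st) {
  sym <- .expect(st, "IDENT", "symbol")$value
  while (.peek(st)$type == "PLUS") {
    .advance(st)
    sym <- c(sym, .expect(st, "IDENT", "symbol")$value)
  }
  sym
}

.parse_termlist <- function(st) {
  args <- list(.parse_term(st))
  while (.peek(st)$type == "COMMA") {
    .advance(st)
    args[[length(args) + 1L]] <- .parse_term(st)
  }
  args
}

.parse_step <- function(st) {
  tok <- .peek(st)
  act <- .expect(st, "IDENT", "speech-act kind")$value
  if (!is_speech_act_kind(act)) {
    stop(sprintf("unknown act kind '%s' at line %d, column %d",
                 act, tok$line, tok$col), call. = FALSE)
  }
  .expect(st, "LP", "'('")
  args <- if (.peek(st)$type == "RP") list() else .parse_termlist(st)
  .expect(st, "RP", "')'")
  dir <- .peek(st)
  if (!dir$type %in% c("SEND", "RECV")) {
    stop(sprintf("syntax error at line %d, column %d: expected '=>' or '<=' after message",
                 dir$line, dir$col), call. = FALSE)
  }
  .advance(st)
  peer <- .parse_header(st)
  guard <- NULL
  if (.peek(st)$type == "GUARD") {
    .advance(st)
    pred <- .expect(st, "IDENT", "guard predicate")$value
    .expect(st, "LP", "'('")
    gargs <- if (.peek(st)$type == "RP") list() else .parse_termlist(st)
    .expect(st, "RP", "')'")
    guard <- proto_guard(pred, gargs)
  }
  step <- proto_step(if (dir$type == "SEND") "send" else "receive",
                     act, args, peer, guard)
  attr(step, "srcpos") <- c(line = tok$line, col = tok$col)
  step
}

.parse_unit <- function(st) {
  if (.peek(st)$type == "LP") {
    .advance(st)
    node <- .parse_orexpr(st)
    .expect(st, "RP", "')'")
    node
  } else {
    .parse_step(st)
  }
}

.parse_thenexpr <- function(st) {
  units <- list(.parse_unit(st))
  while (.peek(st)$type == "THEN") {
    .advance(st)
    units[[length(units) + 1L]] <- .parse_unit(st)
  }
  # right-associate
  node <- units[[length(units)]]
  for (k in rev(seq_len(length(units) - 1L))) {
    node <- proto_then(units[[k]], node)
  }
  node
}

.parse_orexpr <- function(st) {
  branches <- list(.parse_thenexpr(st))
  while (.peek(st)$type == "OR") {
    .advance(st)
    branches[[length(branches) + 1L]] <- .parse_thenexpr(st)
  }
  if (length(branches) == 1L) branches[[1L]] else proto_or(branches)
}

#' Parse CoDeL protocol source
#'
#' Parses one role's protocol (see [codel_notation]) into an abstract syntax
#' tree of steps composed with `then` (sequence) and `or` (committed
#' choice). Syntax errors report line and column; unknown act kinds and
#' malformed agent headers are rejected.
#'
#' @param text CoDeL source as a single string or character vector of lines.
#' @return A `codel_protocol`: list with `header` (a `codel_header`) and
#'   `body` (the root step/combinator node).
#' @seealso [serialize_protocol()], [check_protocol()]
#' @export
#' @examples
#' p <- parse_protocol(
#'   "a(patient(), P) :: assert(disease, s1 + s2) <= a(doctor(), D)")
#' p$body$act
parse_protocol <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) {
    stop("syntax error: empty protocol source", call. = FALSE)
  }
  st <- .pstate(.tokenize(text))
  header <- .parse_header(st)
  .expect(st, "DCOLON", "'::'")
  body <- .parse_orexpr(st)
  .expect(st, "EOF", "end of input")
  proto_protocol(header, body)
}

#' @rdname parse_protocol
#' @param path path to a `.codel` file (UTF-8, `#` line comments).
#' @export
read_protocol <- function(path) {
  parse_protocol(readLines(path, encoding = "UTF-8", warn = FALSE))
}
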