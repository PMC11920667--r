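# Shared helpers: random protocol ASTs for roundtrip properties, random
# knowledge bases, and hand-built transcripts.

rand_symbol <- function() {
  paste0(sample(letters, 1L), paste(sample(c(letters, 0:9), sample(2:6, 1L),
                                           replace = TRUE), collapse = ""))
}

rand_term <- function() replicate(sample(1:3, 1L), rand_symbol())

rand_header <- function() {
  proto_header(rand_symbol(), toupper(rand_symbol()),
               knowledge = replicate(sample(0:2, 1L), rand_symbol()))
}

rand_step <- function(peer) {
  guard <- if (runif(1) < 0.3) {
    proto_guard(rand_symbol(),
                replicate(sample(0:2, 1L), rand_term(), simplify = FALSE))
  }
  proto_step(sample(c("send", "receive"), 1L),
             sample(speech_act_kinds(), 1L),
             replicate(sample(1:3, 1L), rand_term(), simplify = FALSE),
             peer, guard)
}

rand_node <- function(peer, depth = 3L) {
  if (depth <= 0L || runif(1) < 0.4) return(rand_step(peer))
  if (runif(1) < 0.5) {
    proto_then(rand_node(peer, depth - 1L), rand_node(peer, depth - 1L))
  } else {
    proto_or(replicate(sample(2:3, 1L), rand_node(peer, depth - 1L),
                       simplify = FALSE))
  }
}

rand_protocol <- function(depth = 3L) {
  proto_protocol(rand_header(), rand_node(rand_header(), depth))
}

# structural AST equality, ignoring source-position attributes
strip_srcpos <- function(x) {
  attr(x, "srcpos") <- NULL
  if (is.list(x)) {
    cls <- class(x)
    x <- lapply(x, strip_srcpos)
    class(x) <- cls
  }
  x
}

expect_same_ast <- function(a, b) {
  expect_identical(strip_srcpos(a), strip_srcpos(b))
}

rand_kb <- function(n_iv = 3L) {
  nms <- replicate(n_iv, rand_symbol())
  while (anyDuplicated(nms)) nms <- replicate(n_iv, rand_symbol())
  mk_args <- function(prefix, n) {
    lapply(seq_len(n), function(k)
      list(id = paste0(prefix, k), text = paste("arg", prefix, k),
           weight = round(runif(1, 0.5, 2), 2)))
  }
  ivs <- lapply(seq_along(nms), function(i) {
    list(rationale = paste("rationale for", nms[i]),
         optional = runif(1) < 0.3,
         alternatives = if (i > 1L && runif(1) < 0.5) nms[1L] else character(),
         support = mk_args(paste0(nms[i], "_s"), sample(1:4, 1L)),
         against = mk_args(paste0(nms[i], "_a"), sample(0:3, 1L)))
  })
  names(ivs) <- nms
  guideline_kb(rand_symbol(), ivs, nms[1L])
}

# Build a transcript from an act sequence, alternating doctor/patient
# speakers (doctor first; a retract keeps the floor for the next act).
make_transcript <- function(acts, status = NULL,
                            subject = "condition", plan = c("s1", "s2")) {
  roles <- character(length(acts))
  who <- "doctor"
  for (k in seq_along(acts)) {
    roles[k] <- who
    who <- if (acts[k] == "retract") who else setdiff(c("doctor", "patient"), who)
  }
  msgs <- lapply(seq_along(acts), function(k) {
    speech_act_message(
      acts[k], proposition(subject, plan),
      sender_role = roles[k],
      receiver_role = setdiff(c("doctor", "patient"), roles[k]),
      argument_ids = if (acts[k] %in% c("justify", "persuade")) "a1"
      else character())
  })
  if (is.null(status)) {
    status <- if (acts[length(acts)] == "accept") "agreed" else "no_agreement"
  }
  transcript(msgs, status)
}

af_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- build_af_fixture()
    fx
  }
})

dep_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- build_depression_fixture()
    fx
  }
})
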