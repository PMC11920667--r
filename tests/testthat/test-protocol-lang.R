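test_that("parsing a single receive step captures act, plan and peer", {
  p <- parse_protocol(
    "a(patient(), P) :: assert(disease, surgery1 + surgery2) <= a(doctor(), D)")
  expect_s3_class(p, "codel_protocol")
  expect_equal(p$header$role, "patient")
  expect_equal(p$header$var, "P")
  s <- p$body
  expect_s3_class(s, "codel_step")
  expect_equal(s$kind, "receive")
  expect_equal(s$act, "assert")
  expect_equal(s$args, list("disease", c("surgery1", "surgery2")))
  expect_equal(s$peer$role, "doctor")
  expect_null(s$guard)
})

test_that("guards parse to predicate-with-arguments", {
  p <- parse_protocol(paste(
    "a(patient(), P) ::",
    "question(disease, surgery1 + surgery2) => a(doctor(), D)",
    "<- interested_in(disease, surgery1 + surgery2)"))
  s <- p$body
  expect_equal(s$kind, "send")
  expect_equal(s$guard$predicate_name, "interested_in")
  expect_length(s$guard$args, 2L)
  expect_equal(s$guard$args[[2L]], c("surgery1", "surgery2"))
})

test_that("then is right-associated and or requires parenthesized grouping", {
  p <- parse_protocol(paste(
    "a(doctor(), D) ::",
    "assert(d, s1) => a(patient(), P) then",
    "( accept(s1) <= a(patient(), P)",
    "  or refuse(s1) <= a(patient(), P) then retract(s1) => a(patient(), P) )"))
  expect_s3_class(p$body, "codel_then")
  branch <- p$body$rest
  expect_s3_class(branch, "codel_or")
  expect_length(branch$branches, 2L)
  expect_s3_class(branch$branches[[2L]], "codel_then")

  chain <- parse_protocol(paste(
    "a(doctor(), D) :: assert(d, s1) => a(patient(), P) then",
    "retract(s1) => a(patient(), P) then assert(d, s2) => a(patient(), P)"))
  expect_s3_class(chain$body$rest, "codel_then")       # right-assoc
  expect_s3_class(chain$body$first, "codel_step")
})

test_that("malformed sources are rejected with positioned errors", {
  expect_error(parse_protocol(""), "empty")
  expect_error(parse_protocol("   \n  # only a comment\n"), "empty|expected")
  expect_error(parse_protocol("a(doctor(), D) :: agree(d, s1) => a(patient(), P)"),
               "unknown act kind 'agree' at line 1")
  expect_error(parse_protocol("doctor(D) :: assert(d, s1) => a(patient(), P)"),
               "malformed agent header")
  expect_error(parse_protocol("a(doctor(), D) :: assert(d, s1) ="),
               "line 1")
  expect_error(parse_protocol("a(doctor(), D) :: assert(d s1) => a(patient(), P)"),
               "expected")
})

test_that("bundled protocols roundtrip and normalization is idempotent", {
  for (f in c("doctor.codel", "patient.codel")) {
    path <- system.file("extdata", f, package = "codel")
    ast <- read_protocol(path)
    src1 <- serialize_protocol(ast)
    ast2 <- parse_protocol(src1)
    expect_same_ast(ast, ast2)
    expect_identical(serialize_protocol(ast2), src1)   # byte-stable
  }
})

test_that("parse-serialize roundtrip holds on randomly generated ASTs", {
  set.seed(42)
  for (k in 1:150) {
    ast <- rand_protocol()
    back <- parse_protocol(serialize_protocol(ast))
    expect_same_ast(back, ast)
  }
})

test_that("the bundled doctor-patient bundle passes the static checker", {
  fx <- af_fixture()
  v <- check_protocol(fx$doctor_ast, fx$patient_ast)
  expect_equal(nrow(v), 0L)
})

test_that("the checker flags illegal pairs, unmatched sends and unknown guards", {
  doctor <- read_protocol(system.file("extdata", "doctor.codel",
                                      package = "codel"))
  # patient answering an assert with a justify
  bad_patient <- parse_protocol(paste(
    "a(patient(), P) :: assert(disease, s1 + s2) <= a(doctor(), D) then",
    "justify(disease, s1 + s2, arg) => a(doctor(), D)"))
  v <- check_protocol(doctor, bad_patient)
  expect_true(any(v$type == "illegal_pair" &
                  grepl("(assert, justify)", v$detail, fixed = TRUE)))

  # doctor sending persuade with no matching receive
  d2 <- parse_protocol(paste(
    "a(doctor(), D) :: assert(d, s1) => a(patient(), P) then",
    "( rebuttal(s1) <= a(patient(), P) then persuade(s1, arg) => a(patient(), P)",
    "  or accept(s1) <= a(patient(), P) )"))
  p2 <- parse_protocol(paste(
    "a(patient(), P) :: assert(d, s1) <= a(doctor(), D) then",
    "( rebuttal(s1) => a(doctor(), D) or accept(s1) => a(doctor(), D) )"))
  v2 <- check_protocol(d2, p2)
  expect_equal(sum(v2$type == "unmatched_message" &
                   grepl("persuade", v2$detail)), 1L)

  # unregistered guard predicate
  d3 <- parse_protocol(
    "a(doctor(), D) :: assert(d, s1) => a(patient(), P) <- feels_like(s1)")
  p3 <- parse_protocol(
    "a(patient(), P) :: assert(d, s1) <= a(doctor(), D)")
  v3 <- check_protocol(d3, p3)
  expect_true(any(v3$type == "unknown_predicate" &
                  grepl("feels_like", v3$detail)))
})

test_that("overlapping unguarded or-branches draw an ambiguity warning", {
  d <- parse_protocol(paste(
    "a(doctor(), D) ::",
    "( accept(s1) <= a(patient(), P) or accept(s1) <= a(patient(), P) )"))
  p <- parse_protocol(
    "a(patient(), P) :: accept(s1) => a(doctor(), D)")
  v <- check_protocol(d, p)
  expect_true(any(v$type == "ambiguous_choice" & v$severity == "warning"))
  # act-disjoint branches are fine
  fx <- af_fixture()
  expect_false(any(check_protocol(fx$doctor_ast,
                                  fx$patient_ast)$type == "ambiguous_choice"))
})
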