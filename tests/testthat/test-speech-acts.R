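test_that("the pair registry holds the 14 legal interaction pairs", {
  reg <- legal_pairs()
  expect_s3_class(reg, "codel_pair_registry")
  expect_equal(nrow(reg$legal), 14L)
  expect_false(anyDuplicated(paste(reg$legal$prev, reg$legal$next_)) > 0)
  expect_true(all(nzchar(reg$legal$description)))
  # repeated calls return equal registries
  expect_identical(reg, legal_pairs())

  has <- function(a, b) any(reg$legal$prev == a & reg$legal$next_ == b)
  expect_true(has("assert", "question"))
  expect_true(has("rebuttal", "persuade"))
  expect_true(has("refuse", "retract"))
  expect_false(has("refuse", "persuade"))
  expect_false(has("assert", "justify"))
})

test_that("prohibited pairs validate illegal, legal pairs carry rationales", {
  expect_true(validate_pair("assert", "question")$legal)
  expect_match(validate_pair("question", "justify")$rationale, "challenge")
  expect_false(validate_pair("refuse", "persuade")$legal)
  expect_false(validate_pair("assert", "justify")$legal)
  # the registry is directional where behaviour demands it
  expect_true(validate_pair("question", "justify")$legal)
  expect_true(validate_pair("justify", "question")$legal)
})

test_that("the retract-assert same-speaker continuation is legal", {
  expect_true(validate_pair("retract", "assert")$legal)
  expect_equal(allowed_responses("retract"), "assert")
  reg <- legal_pairs()
  expect_equal(nrow(reg$continuation), 1L)
})

test_that("allowed responses match the registry for every act kind", {
  expect_setequal(allowed_responses("assert"),
                  c("accept", "refuse", "question", "rebuttal"))
  expect_setequal(allowed_responses("persuade"),
                  c("question", "accept", "refuse"))
  expect_length(allowed_responses("accept"), 0L)
  expect_equal(legal_pairs()$terminal, "accept")

  # brute force over all 64 ordered pairs
  for (a in speech_act_kinds()) {
    by_scan <- Filter(function(b) validate_pair(a, b)$legal,
                      speech_act_kinds())
    expect_setequal(allowed_responses(a), by_scan)
  }
})

test_that("nothing outside the 8-kind enumeration is accepted", {
  expect_length(speech_act_kinds(), 8L)
  expect_error(validate_pair("assert", "agree"), "8 speech-act kinds")
  expect_error(allowed_responses("ASSERT"), "8 speech-act kinds")
  expect_false(is_speech_act_kind("inform"))
  expect_error(speech_act_message("inform", proposition("d", "s"),
                                  "doctor", "patient"))
})

test_that("the registry roundtrips through its file form", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_pair_registry(path)
  back <- read_pair_registry(path)
  orig <- legal_pairs()
  expect_equal(back$legal, orig$legal)
  expect_equal(back$continuation, orig$continuation)
  expect_equal(back$terminal, orig$terminal)
})

test_that("message structural rules are enforced", {
  p <- proposition("af", c("s1", "s2"))
  expect_error(speech_act_message("justify", p, "doctor", "patient"),
               "argument reference")
  expect_error(speech_act_message("persuade", p, "doctor", "patient"),
               "argument reference")
  expect_error(speech_act_message("assert", proposition("af"),
                                  "doctor", "patient"), "non-empty plan")
  expect_error(speech_act_message("assert", p, "doctor", "doctor"),
               "must differ")
  m <- speech_act_message("rebuttal", proposition("af", "s1"),
                          "patient", "doctor")
  expect_s3_class(m, "codel_message")
  expect_true(same_plan(proposition("af", c("s1", "s2")),
                        proposition("af", c("s2", "s1"))))
})
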