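fresh_session <- function(fx = af_fixture(), scenario = "scenario1") {
  cfg <- fx$configs[[scenario]]
  session_start(fx$doctor_ast, fx$patient_ast, fx$kb,
                cfg$doctor_pol, cfg$patient_pol)
}

test_that("the three canonical policies reproduce the scenario sequences", {
  fx <- af_fixture()
  t1 <- run_fixture_scenario(fx, "scenario1")
  expect_equal(transcript_acts(t1),
               c("assert", "question", "justify", "accept"))
  expect_equal(t1$final_status, "agreed")

  t2 <- run_fixture_scenario(fx, "scenario2")
  expect_equal(transcript_acts(t2),
               c("assert", "rebuttal", "persuade", "accept"))
  expect_equal(t2$final_status, "agreed")

  t3 <- run_fixture_scenario(fx, "scenario3")
  expect_equal(transcript_acts(t3),
               c("assert", "rebuttal", "persuade", "refuse",
                 "retract", "assert", "accept"))
  expect_equal(t3$final_status, "agreed")
  expect_equal(t3$metadata$final_plan,
               c("cardiac_ultrasound", "surgical_ablation"))
})

test_that("stepping enforces turn order and pair legality", {
  s <- fresh_session()
  plan <- s$kb$recommended_plan
  d_assert <- speech_act_message("assert",
    proposition(s$kb$condition, plan), "doctor", "patient")

  # patient cannot open the dialogue
  expect_error(session_step(s, speech_act_message("question",
    proposition(s$kb$condition, plan), "patient", "doctor")),
    class = "codel_not_your_turn")

  s1 <- session_step(s, d_assert)
  expect_equal(s1$status, "running")
  expect_length(s1$history, 1L)

  # answering an assert with a justify is an illegal pair
  expect_error(session_step(s1, speech_act_message("justify",
    proposition(s$kb$condition, plan), "patient", "doctor",
    argument_ids = "ca_s1")),
    class = "codel_illegal_pair")

  # a persuade answered by accept closes the session agreed
  s2 <- session_step(s1, speech_act_message("rebuttal",
    proposition(s$kb$condition, plan[1]), "patient", "doctor"))
  s3 <- session_step(s2, speech_act_message("persuade",
    proposition(s$kb$condition, plan[1]), "doctor", "patient",
    argument_ids = "ca_s1"))
  s4 <- session_step(s3, speech_act_message("accept",
    proposition(s$kb$condition, plan), "patient", "doctor"))
  expect_equal(s4$status, "agreed")
  expect_error(session_step(s4, d_assert), class = "codel_session_over")
})

test_that("only the retracting speaker may continue with the new assert", {
  s <- fresh_session()
  plan <- s$kb$recommended_plan
  cond <- s$kb$condition
  acts <- list(
    speech_act_message("assert", proposition(cond, plan), "doctor", "patient"),
    speech_act_message("refuse", proposition(cond, plan[1]), "patient", "doctor"),
    speech_act_message("retract", proposition(cond, plan), "doctor", "patient"))
  for (m in acts) s <- session_step(s, m)
  # after retract the floor stays with the doctor
  expect_equal(whose_turn(s), "doctor")
  expect_error(session_step(s, speech_act_message("assert",
    proposition(cond, plan), "patient", "doctor")),
    class = "codel_not_your_turn")
  s <- session_step(s, speech_act_message("assert",
    proposition(cond, c("cardiac_ultrasound", plan[2])), "doctor", "patient"))
  expect_equal(s$status, "running")
})

test_that("every engine transcript passes the pairwise legality audit", {
  fx <- af_fixture()
  dep <- dep_fixture()
  runs <- c(lapply(names(fx$configs), run_fixture_scenario, fixture = fx),
            lapply(names(dep$configs), run_fixture_scenario, fixture = dep))
  kb_ids <- function(kb) {
    unlist(lapply(kb$interventions, function(iv)
      vapply(c(iv$support, iv$against), `[[`, character(1), "id")))
  }
  kbs <- c(rep(list(fx$kb), length(fx$configs)),
           rep(list(dep$kb), length(dep$configs)))
  for (i in seq_along(runs)) {
    t <- runs[[i]]
    expect_true(isTRUE(audit_transcript(t)))
    expect_equal(transcript_acts(t)[1L], "assert")
    expect_equal(t$messages[[1L]]$sender_role, "doctor")
    expect_equal(t$final_status == "agreed",
                 transcript_acts(t)[length(t$messages)] == "accept")
    # every cited argument id resolves in the session's knowledge base
    cited <- unlist(lapply(t$messages, `[[`, "argument_ids"))
    expect_true(all(cited %in% kb_ids(kbs[[i]])))
  }
})

test_that("identical inputs and seed give byte-identical transcripts", {
  fx <- af_fixture()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_transcript(run_fixture_scenario(fx, "scenario3", seed = 7L), f1)
  write_transcript(run_fixture_scenario(fx, "scenario3", seed = 7L), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("sessions halt within the turn limit", {
  fx <- dep_fixture()
  cfg <- fx$configs$emily
  # full run needs 12 messages; a tight limit trips the loop guard
  expect_error(run_session(fx$doctor_ast, fx$patient_ast, fx$kb,
                           cfg$doctor_pol, cfg$patient_pol, max_turns = 3L),
               class = "codel_turn_limit")
  for (limit in c(12L, 50L)) {
    t <- run_session(fx$doctor_ast, fx$patient_ast, fx$kb,
                     cfg$doctor_pol, cfg$patient_pol, max_turns = limit)
    expect_lte(length(t$messages), limit)
  }
})

test_that("a firm refusal with no alternative ends without agreement", {
  fx <- af_fixture()
  # the patient opposes the ablation, which has no authored alternative
  pol <- patient_policy(question_budget = 0L, oppose = "surgical_ablation",
                        rebut_budget = 1L, profile = "persistent")
  t <- run_session(fx$doctor_ast, fx$patient_ast, fx$kb,
                   patient_pol = pol)
  expect_equal(t$final_status, "no_agreement")
  expect_equal(transcript_acts(t)[length(t$messages)], "refuse")
  expect_true(isTRUE(audit_transcript(t)))
})

test_that("policies referencing unknown interventions are rejected", {
  fx <- af_fixture()
  expect_error(run_session(fx$doctor_ast, fx$patient_ast, fx$kb,
                           patient_pol = patient_policy(oppose = "leeches")),
               class = "codel_unknown_intervention")
})

test_that("substitute_alternative replaces in place, drops optionals, errors otherwise", {
  kb <- af_fixture()$kb
  p <- proposition("atrial_fibrillation",
                   c("cardiac_angiography", "surgical_ablation"))
  out <- substitute_alternative(kb, p, "cardiac_angiography")
  expect_equal(out$plan, c("cardiac_ultrasound", "surgical_ablation"))

  dep <- dep_fixture()$kb
  pe <- proposition("major_depression", c("cbt", "antidepressant"))
  dropped <- substitute_alternative(dep, pe, "antidepressant",
                                    already_rejected = "ssri")
  expect_equal(dropped$plan, "cbt")

  expect_error(substitute_alternative(kb, p, "cardiac_ultrasound"),
               class = "codel_unknown_intervention")
  expect_error(substitute_alternative(kb, p, "surgical_ablation"),
               class = "codel_no_alternative")
})

test_that("transcript JSON roundtrips and is validated on read", {
  fx <- af_fixture()
  t <- run_fixture_scenario(fx, "scenario2")
  path <- withr::local_tempfile(fileext = ".json")
  write_transcript(t, path)
  back <- read_transcript(path)
  expect_equal(transcript_acts(back), transcript_acts(t))
  expect_equal(back$final_status, t$final_status)
  expect_equal(back$metadata$seed, t$metadata$seed)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"messages": [{"act": "assert"}]}', bad)
  expect_error(read_transcript(bad), "missing")
})
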