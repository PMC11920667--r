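# Guideline knowledge base for the major-depression consultation case.
# Argument texts are drawn from the case's clinical-guideline prose on
# cognitive behavioural therapy (CBT), antidepressants and SSRIs.
condition: major_depression
recommended_plan:
  - cbt
  - antidepressant
interventions:
  cbt:
    rationale: "A type of talking therapy that helps individuals manage problems by changing the way they think and behave."
    optional: no
    alternatives: []
    support:
      - id: cbt_s1
        text: "Helps individuals manage problems by changing the way they think and behave."
      - id: cbt_s2
        text: "Most commonly used to treat anxiety and depression."
      - id: cbt_s3
        text: "Can also be effective for other mental and physical health issues."
    against:
      - id: cbt_a1
        text: "Requires sustained commitment to sessions and homework."
  antidepressant:
    rationale: "Medication to manage the symptoms of moderate or severe depression."
    optional: yes
    alternatives:
      - ssri
    support:
      - id: ad_s1
        text: "Most people with moderate or severe depression benefit from antidepressants."
    against:
      - id: ad_a1
        text: "Can cause nausea, headaches, dry mouth, fatigue, sleep problems, and sexual issues."
      - id: ad_a2
        text: "Not everyone responds to medication in the same way."
  ssri:
    rationale: "A selective serotonin reuptake inhibitor, the modern first-choice antidepressant."
    optional: yes
    alternatives: []
    support:
      - id: ssri_s1
        text: "As effective as older antidepressants with fewer side effects."
      - id: ssri_s2
        text: "Generally well-tolerated and considered a safe option."
    against:
      - id: ssri_a1
        text: "Side effects can include nausea, headaches and sleep problems, though these usually improve over time."
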