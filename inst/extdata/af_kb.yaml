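# Guideline knowledge base for the atrial-fibrillation consultation case.
# Argument texts are transcribed verbatim from the case's surgery
# information table (advantages / disadvantages and side effects columns).
condition: atrial_fibrillation
recommended_plan:
  - cardiac_angiography
  - surgical_ablation
interventions:
  cardiac_angiography:
    rationale: "The type, duration, and frequency of atrial fibrillation can be determined, while the presence of potential cardiovascular problems can be assessed."
    optional: no
    alternatives:
      - cardiac_ultrasound
    support:
      - id: ca_s1
        text: "Provides detailed information about the structure of the heart."
      - id: ca_s2
        text: "Make an accurate diagnosis."
      - id: ca_s3
        text: "Helps to plan surgical procedures."
      - id: ca_s4
        text: "Improves the success rate of surgery and reduces the risk."
    against:
      - id: ca_a1
        text: "Invasive surgery."
      - id: ca_a2
        text: "There are potential complications, such as vascular damage, infection, and contrast agent toxicity to the kidney."
      - id: ca_a3
        text: "Slight pain (which was aggravated by David's last experience)."
      - id: ca_a4
        text: "Vascular injury."
      - id: ca_a5
        text: "Infection."
      - id: ca_a6
        text: "Contrast agent toxicity."
  surgical_ablation:
    rationale: "Interventional therapy to target and eliminate abnormal atrial conduction tissue."
    optional: no
    alternatives: []
    support:
      - id: sa_s1
        text: "Effectively restoring normal heart rhythm."
      - id: sa_s2
        text: "Eliminates arrhythmia symptoms."
      - id: sa_s3
        text: "Improves the quality of life."
    against:
      - id: sa_a1
        text: "Invasive surgery."
      - id: sa_a2
        text: "There is a risk of bleeding, blood clots, and infection."
      - id: sa_a3
        text: "It may cause pain."
      - id: sa_a4
        text: "Bleeding and infection."
  cardiac_ultrasound:
    rationale: "To assess heart structure and function using noninvasive ultrasound imaging."
    optional: no
    alternatives: []
    support:
      - id: cu_s1
        text: "Noninvasive procedures."
      - id: cu_s2
        text: "Provides real-time imaging of the heart."
      - id: cu_s3
        text: "Helps assess heart function."
      - id: cu_s4
        text: "Assists in the development of treatment plans."
    against:
      - id: cu_a1
        text: "Limited ability to visualize certain structures."
      - id: cu_a2
        text: "It takes expertise to explain it accurately."
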