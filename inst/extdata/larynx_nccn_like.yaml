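# Packaged guideline-flavored rule set for the laryngeal-carcinoma treatment
# model. The two surgery probabilities for (T2, N2a, M0/M1, tolerant) are
# fixed anchors; every other value is an elicited, guideline-flavored
# reconstruction (see the package vignette), not a published table.
#
# Rule semantics: per CPT cell the matching rule with the highest priority
# wins; among equal priorities the last listed wins; unmatched cells fall
# back to the per-treatment default. Omitted t_states/n_states/m_states/
# tolerance fields mean "any".
defaults:
  larynx_surgery: 0.5
  radiotherapy: 0.4
  radiochemotherapy: 0.3
  chemotherapy: 0.1
  immunotherapy: 0.1
rules:
  # --- larynx surgery -------------------------------------------------
  - treatment: larynx_surgery
    t_states: [TIS, T1, T1a, T1b, T2]
    m_states: [M0]
    p_true: 0.85
    priority: 1
  - treatment: larynx_surgery
    t_states: [T3, T4a]
    m_states: [M0]
    p_true: 0.75
    priority: 1
  - treatment: larynx_surgery
    t_states: [T4b]
    m_states: [MX, M0]
    p_true: 0.15
    priority: 2
  - treatment: larynx_surgery
    m_states: [M1]
    p_true: 0.15
    priority: 2
  # fixed anchors
  - treatment: larynx_surgery
    t_states: [T2]
    n_states: [N2a]
    m_states: [M0]
    tolerance: tolerant
    p_true: 0.74
    priority: 5
  - treatment: larynx_surgery
    t_states: [T2]
    n_states: [N2a]
    m_states: [M1]
    tolerance: tolerant
    p_true: 0.17
    priority: 5
  # --- radiotherapy ---------------------------------------------------
  - treatment: radiotherapy
    t_states: [TIS, T1, T1a, T1b, T2]
    n_states: [N0]
    m_states: [M0]
    p_true: 0.8
    priority: 1
  - treatment: radiotherapy
    t_states: [TIS, T1, T1a, T1b, T2]
    n_states: [N1, N2a, N2b, N2c, N3a, N3b]
    m_states: [M0]
    p_true: 0.4
    priority: 1
  - treatment: radiotherapy
    t_states: [T3, T4a]
    m_states: [M0]
    p_true: 0.35
    priority: 1
  - treatment: radiotherapy
    t_states: [T4b]
    m_states: [MX, M0]
    p_true: 0.5
    priority: 2
  - treatment: radiotherapy
    m_states: [M1]
    p_true: 0.3
    priority: 2
  # --- radiochemotherapy ----------------------------------------------
  - treatment: radiochemotherapy
    t_states: [TIS, T1, T1a, T1b, T2]
    n_states: [N0]
    m_states: [M0]
    p_true: 0.1
    priority: 1
  - treatment: radiochemotherapy
    t_states: [TIS, T1, T1a, T1b, T2]
    n_states: [N1, N2a, N2b, N2c, N3a, N3b]
    m_states: [M0]
    p_true: 0.55
    priority: 1
  - treatment: radiochemotherapy
    t_states: [T3, T4a]
    m_states: [M0]
    p_true: 0.7
    priority: 1
  - treatment: radiochemotherapy
    t_states: [T4b]
    m_states: [MX, M0]
    p_true: 0.75
    priority: 2
  - treatment: radiochemotherapy
    m_states: [M1]
    p_true: 0.25
    priority: 2
  # hard prerequisite: no systemic chemotherapy component when intolerant
  - treatment: radiochemotherapy
    tolerance: intolerant
    p_true: 0.0
    priority: 3
  # --- chemotherapy ---------------------------------------------------
  - treatment: chemotherapy
    m_states: [M0]
    p_true: 0.05
    priority: 1
  - treatment: chemotherapy
    t_states: [T4b]
    m_states: [M0]
    p_true: 0.3
    priority: 2
  - treatment: chemotherapy
    m_states: [M1]
    p_true: 0.7
    priority: 2
  - treatment: chemotherapy
    tolerance: intolerant
    p_true: 0.0
    priority: 3
  # --- immunotherapy --------------------------------------------------
  - treatment: immunotherapy
    m_states: [M0]
    p_true: 0.08
    priority: 1
  - treatment: immunotherapy
    t_states: [T4b]
    m_states: [M0]
    p_true: 0.25
    priority: 2
  - treatment: immunotherapy
    m_states: [M1]
    p_true: 0.6
    priority: 2
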