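Package: cadcea
Title: Cost-Effectiveness Analysis of Ischemia-Based Diagnostic Strategies for Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic comparison of two ischemia-based strategies for
    diagnosing hemodynamically significant coronary artery disease: perfusion
    cardiovascular magnetic resonance followed by invasive coronary angiography
    in ischemia-positive patients, versus first-line angiography with fractional
    flow reserve measurement in stenosed patients. Provides closed-form
    per-patient effectiveness and expected-cost equations built on Bayes'
    theorem, cost-effectiveness ratio curves over the pre-test likelihood of
    disease, crossing-point location between strategies, one-way sensitivity
    analyses, a calibratable link between ischemia prevalence and angiographic
    stenosis prevalence, and a patient-level microsimulation that serves as an
    independent stochastic check on the closed forms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
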