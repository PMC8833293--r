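Package: ernarank
Title: Contact Ranking for Subthalamic Deep Brain Stimulation from
    Evoked and Spontaneous Neural Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for guiding contact selection on quadripolar deep brain
    stimulation (DBS) leads implanted in the subthalamic nucleus (STN).
    Computes evoked resonant neural activity (ERNA) power from
    burst-stimulation recordings, beta (13-30 Hz) and high-frequency
    oscillation (HFO, 200-400 Hz) band power from resting local field
    potentials, and anatomical proximity of contacts to a red-nucleus
    landmark target; ranks contacts per hemisphere by each factor; and
    relates rankings to per-contact motor benefit with linear mixed-effects
    models, best-subset AIC comparison, blocked repeated-measures ANOVA
    with Tukey comparisons, and concordance summaries. A synthetic-data
    module generates complete studies (multichannel recordings, lead
    geometry, clinical outcomes, ground truth) with the statistical
    structure the analysis assumes, so the whole pipeline is testable
    without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    car,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
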