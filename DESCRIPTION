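Package: insulinrl
Title: Model-Based Reinforcement Learning for Inpatient Insulin Dose Titration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning and evaluating dynamic subcutaneous insulin
    dosing policies for hospitalized type 2 diabetes patients from
    seven-timeslot-per-day glucose trajectories. Provides a learned patient
    model (sequence encoder, latent dynamics and glucose/within-target-range
    prediction heads), a dosing policy trained with a joint supervised and
    policy-gradient objective, K-step beam-search planning over the learned
    dynamics, importance-sampling off-policy evaluation with effective sample
    size, guideline titration baselines for premixed, basal and basal-bolus
    regimens, a Magni-risk-based reward, glycemic evaluation metrics, and a
    seeded synthetic inpatient cohort simulator with known ground-truth
    insulin response for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: graphics, jsonlite, stats, utils, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
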