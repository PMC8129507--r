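Package: emovoice
Title: Synthesis and Acoustic Analysis of Emotional Voice in the PAD Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Synthesizes voiced utterances with independently controlled
    fundamental frequency, pitch variability, jitter, shimmer,
    harmonics-to-noise ratio and intensity; extracts the seven acoustic
    features used in gender-by-emotion voice studies (speech velocity,
    mean F0, F0 SD, intensity, jitter percent, shimmer percent, HNR) from
    mono WAV audio via autocorrelation pitch-period detection; and fits
    the two-way mixed-design (split-plot) ANOVA with one between-subjects
    factor (gender) and one within-subjects factor (the nine emotional
    states of the pleasure-arousal-dominance model), including
    Greenhouse-Geisser sphericity correction, partial omega-squared effect
    sizes, simple main effects and pairwise post hoc orderings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
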