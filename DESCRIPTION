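Package: ternuseye
Title: Oculomotor and Pupillometric Analysis of Audiovisual Ternus Displays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline for studying the crossmodal freezing effect in
    audiovisual Ternus apparent-motion experiments. Provides builders for the
    four experiment designs, a synthetic-data generator emulating fixational
    eye movements (drift, microsaccades with a realistic main sequence,
    stimulus-locked oculomotor inhibition), pupil dilation responses and
    logistic psychometric behavior; microsaccade detection with median-based
    velocity thresholds and duration/interval filters; causal-kernel event
    rate estimation with segment summaries; pupillometry preprocessing (blink
    interpolation, session normalization, baseline correction); psychometric
    function fitting with PSE and JND extraction; and nonparametric
    cluster-based permutation tests for paired condition differences over
    time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
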