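Package: ewat
Title: Elephant Welfare Assessment Tool Scoring, Validity and Reliability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring engine and psychometric validation toolkit for a
    structured welfare assessment instrument for tourist-camp Asian
    elephants, organised by the Five Domains framework (Nutrition,
    Environment, Health, Behavior and Mental State). Ships the versioned
    instrument codebook (36 final / 39 initial measures, 0-2 Likert
    rubrics for animal- and resource-based measures), reads and validates
    assessment score sheets, and aggregates item scores to measure,
    domain, elephant and camp level with welfare-concern flagging.
    Implements the content-validity pipeline (dichotomised expert
    relevance ratings, I-CVI, universal agreement, S-CVI/UA and
    S-CVI/Average, threshold-based item retention) and inter-rater /
    test-retest reliability via the two-way random-effects
    absolute-agreement intraclass correlation coefficient, with ANOVA
    mean squares, McGraw-Wong F-based confidence intervals and Koo-Li
    interpretation bands. Includes deterministic generators for synthetic
    expert panels, score sheets and two-way rating matrices with known
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
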