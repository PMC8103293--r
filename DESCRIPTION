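Package: motorcube
Title: Gamified Fine Motor Skill Assessment with a Sensor-Augmented Cube
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing children's fine
    motor skills from games played on a sensor-augmented cube toy. Provides the
    cube surface topology, deterministic engines for a speed game (roadrunner)
    and a precision game (maze), a synthetic child-player generator with a
    latent motor-skill parameter that drives inertial measurement unit streams
    and game-event logs, zero-phase low-pass filtering and feature extraction
    (total acceleration, angular velocity, jerk, angular jerk, dot-alignment
    cosine similarity, maze correctness), stratified minority-driven k-fold
    cross-validation of four classifiers, and paired Wilcoxon signed-rank
    comparison grids over fold-wise scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
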