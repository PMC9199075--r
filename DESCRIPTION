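Package: pdestride
Title: Stability Selection for Learning Differential Equations from Noisy Spatio-Temporal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Robust identification of governing partial differential equations
    and reaction networks from limited, noisy spatio-temporal data. Candidate
    terms (polynomial nonlinearities, spatial derivatives and their products)
    are assembled into a regression dictionary, sparsity-promoting solvers
    (LASSO, randomized LASSO, iterative hard thresholding with and without
    debiasing, sequential threshold ridge regression, orthogonal matching
    pursuit) are run over regularization paths on random half-subsamples of
    the data, and the model is selected by thresholding the resulting
    component importance profiles (stability selection). Includes benchmark
    simulators (1-D Burgers, 2-D lid-driven cavity vorticity transport, 3-D
    Gray-Scott reaction-diffusion, and a two-species protein-interaction ODE),
    an additive-noise model, truncated-SVD denoising, and an achievability
    harness for estimating sample complexity of exact support recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
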