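Package: blastoabc
Title: Compartment Models of Blastocyst Lineage Allocation with
    Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic and stochastic compartment models of cell-fate
    allocation in the preimplantation mouse embryo (8-cell morula to late
    blastocyst) and of embryonic stem cell chimera formation. Provides
    ordinary differential equation models of blastomere, trophectoderm,
    unspecified inner cell mass, primitive endoderm and epiblast
    dynamics with FGF4 and primitive-endoderm feedbacks; chimera model
    variants with donor-cell growth, FGF4 induction and crowding
    displacement; exact Gillespie stochastic simulation of the same
    reaction networks; a state-space (time-implicit) summary statistic
    for comparing trajectories with per-embryo cell-count snapshots;
    ABC-MCMC posterior sampling and rejection-ABC Bayes-factor model
    comparison; synthetic count-data generators; and endpoint chimera
    analysis including k-means chimerism classification with
    silhouette-based model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
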