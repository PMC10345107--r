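Package: spoolsim
Title: Coarse-Grained Simulation of Sperm Chromatin Spooling in a
    Deformable Nuclear Envelope
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Langevin-dynamics simulator of a semiflexible, self-avoiding
    chromatin fiber confined in a triangulated elastic shell representing
    the nuclear envelope, together with the developmental protocols of
    insect spermiogenesis (histone-to-protamine rigidification, either
    uniform or nucleated with cis-spreading; antipodal nuclear elongation;
    torsional twisting; decondensation) and a quantification stack:
    Landau-de Gennes Q-tensor nematic order parameters, radial density
    profiles, worm-like-chain persistence-length estimation, and a
    structure-tensor image pipeline for 2D fiber-orientation analysis of
    micrograph-like sections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    png,
    rmarkdown,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
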