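Package: epletrisk
Title: HLA Eplet Mismatch and Allosensitization Risk After Kidney
    Transplant Failure
Version: 0.1.0
Authors@R:
    person("Histocompatibility", "Informatics", email = "hla@example.org",
           role = c("aut", "cre"))
Description: Tools for transplant immunogenetics analyses of
    allosensitization after kidney allograft failure. Computes
    donor-against-recipient HLA eplet mismatch counts per locus group
    from a pluggable eplet registry, calls unacceptable antigens and de
    novo donor-specific antibodies from single-antigen-bead panels,
    derives calculated panel reactive antibody (cPRA) against an
    explicit donor reference panel together with the donor-pool-reduction
    statistic that defines a meaningful cPRA increase, classifies
    post-failure maintenance immunosuppression as maintained or reduced,
    and provides self-contained exact and parametric association tests.
    A synthetic-cohort generator emulates every input so the full
    pipeline is testable without confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
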