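Package: dcnet
Title: Differential Gene Co-Expression Network Analysis for Two-Condition RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-condition differential gene co-expression analysis of
    bulk RNA-seq count data: counts-per-million normalisation and transcript/sample
    filtering, weighted co-expression networks (soft-threshold selection,
    topological overlap, module detection, hub genes, bootstrap module stability),
    differential co-expression testing (Fisher's Z difference test for links, a
    binomial tail model for differentially co-expressed genes, resampling
    stability), adjusted-mutual-information comparison of differential networks,
    hypergeometric over-representation analysis against GMT gene sets, and
    cross-validated gradient-boosted prediction of condition labels. A synthetic
    data generator with planted modules and planted differential pairs supports
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    fitdistrplus,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    pROC
Config/testthat/edition: 3
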