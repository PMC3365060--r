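Package: discosca
Title: Common and Distinctive Components for Linked Omics Data Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simultaneous component analysis of two or more data blocks that
    share one mode (e.g. genes by time points measured in several organisms,
    or metabolites by culture samples measured on several platforms), with
    orthogonal rotation to a partially specified target that separates
    processes common to all blocks from processes distinctive for a single
    block (DISCO-SCA). Also provides the generalized singular value
    decomposition (GSVD) of two linked blocks in its full ("naive") and
    rank-restricted least-squares ("adapted") forms, variation-accounted-for
    accounting, model selection over all candidate common/distinctive
    targets, a simulation-study generator with known ground truth, and
    Tucker-congruence recovery scoring with permutation and reflection
    matching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
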