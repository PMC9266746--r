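Package: rnasespec
Title: Dinucleotide-Specific Ribonuclease Cleavage Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for profiling the dinucleotide-specific cleavage
    preferences of endoribonucleases from oligonucleotide digestion
    products. Provides RNA oligonucleotide mass chemistry with
    post-transcriptional modification codes and 2',3'-cyclic phosphate
    termini, design and validation of probe substrates covering all 16
    dinucleotide combinations, in-silico partial digestion under an
    independent-cut model with missed-cleavage enumeration, c/y/w/a-B
    fragment ladders and ppm-tolerance peak matching, a per-bond cleavage
    efficiency estimator (100*x/(x+y)) with replicate aggregation and
    four-level categorization, and a digestion simulator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
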