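# Writes the synthetic supplementary-layout fixtures shipped with the
# package: a 519-amplicon / 53-gene panel and a 42 + 3 antibody table.
# Both are synthetic stand-ins generated from the package's own defaults.
library(clonepulse)
panel <- default_panel()
readr::write_csv(panel, "inst/extdata/synthetic_panel.csv")
readr::write_csv(default_antibodies(), "inst/extdata/synthetic_antibodies.csv")
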