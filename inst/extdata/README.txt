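Drop-in location for non-redistributable reproduction inputs:

  source_data.xlsx          the article's source-data workbook; enables
                            convertSupplementary() + panelAnova()
                            recomputation of the figure-legend ANOVAs.

  pure_reference_fpkm.tsv   gene x sample FPKM (readExprTable layout,
                            columns neuron_1..neuron_3,
                            astrocyte_1..astrocyte_3) derived from the
                            deposited pure-culture RNA-seq (E-MTAB-8058).

  mixed_culture_fpkm.tsv    gene x sample FPKM (columns Con_*, KCl_*)
                            derived from the deposited +/-KCl mixed-culture
                            RNA-seq (GSE93682).

With these present, the corresponding acceptance tests in
tests/testthat/test-acceptance.R run the published composition and ANOVA
reproductions.
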