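# Loaded by testthat before the test files: attach the package (so the
# suite also runs under test_dir()) and alias the internal helpers that
# the white-box tests exercise.
library(mirmeta)
soft_threshold <- mirmeta:::soft_threshold
derive_seed <- mirmeta:::derive_seed
condition_scores <- mirmeta:::condition_scores
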