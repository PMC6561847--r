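# report every expectation: simulation-backed blocks can accumulate several
# informative failures and later blocks must still run
options(testthat.progress.max_fails = 100L)
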