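# Report every failure instead of aborting mid-suite: the Monte-Carlo
# acceptance checks assert many sub-conditions and must not mask the rest
# of the suite when several of them miss their bands.
options(testthat.progress.max_fails = 1e6)
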