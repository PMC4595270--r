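# route figure drawing that targets the active device into a null device
pdf(NULL)
withr::defer(grDevices::dev.off(), teardown_env())
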