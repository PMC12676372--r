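# 12-echo gradient-echo acquisition, echo times in ms
echo_times: [2, 4, 6, 8, 10, 12, 14, 16, 18, 20, 22, 24]
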