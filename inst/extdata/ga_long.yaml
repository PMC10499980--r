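# Gibberellin transport, long-cell (mature-zone) file preset.
preset: ga_long
plasmodesmata: true
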