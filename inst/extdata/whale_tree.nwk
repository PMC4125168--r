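(((((killer_whale,bottlenose_dolphin),finless_porpoise),baiji),(minke_whale,fin_whale)),cow,pig);
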