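((((((human,chimpanzee),gorilla),orangutan),((rhesus_macaque,olive_baboon),green_monkey)),(squirrel_monkey,marmoset)),tarsier,((mouse_lemur,aye_aye),galago));
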