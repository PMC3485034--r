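"country","vaccine","year","source","coverage"
"egy","dtp3",2004,"reported",97
"egy","dtp3",2005,"reported",96
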