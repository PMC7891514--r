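component,variance,sd
between,44.08928170717064,6.639976032123206
within,3.2100997605732675,1.7916751269617122
total,47.299381467743906,6.877454577657631
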