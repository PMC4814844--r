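well_id,n_empty,n_nhej,n_wt_plus,n_hdr_plus,n_anomalous
A01,6421,296,8204,79,0
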