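# Cell types not expected in solid tumor tissue; excluded when
# exclude_non_solid is set. One name per line; extend as needed.
pro-B cells
Hematopoietic stem cells
Common lymphoid progenitors
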