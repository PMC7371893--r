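id,iq,severity,kind,exon_start,exon_end
case-1,42,moderate,deletion,45,52
case-2,55,mild,deletion,45,52
case-3,57,mild,deletion,45,49
case-4,65,mild,deletion,45,52
case-5,66,mild,deletion,20,44
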