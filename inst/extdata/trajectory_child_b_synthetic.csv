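child_id,age_months,score,event
child-B-synthetic,3,11,
child-B-synthetic,6,14,
child-B-synthetic,9,17,
child-B-synthetic,12,21,
child-B-synthetic,15,25,
child-B-synthetic,18,26,
child-B-synthetic,21,26,
child-B-synthetic,24,27,
child-B-synthetic,28,27,
child-B-synthetic,32,28,
child-B-synthetic,36,29,
child-B-synthetic,40,31,
child-B-synthetic,44,37,cochlear implant activation (41 months)
child-B-synthetic,48,43,
child-B-synthetic,52,48,
child-B-synthetic,56,52,cochlear implant activation (56 months)
child-B-synthetic,60,56,
child-B-synthetic,64,59,
child-B-synthetic,68,61,
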