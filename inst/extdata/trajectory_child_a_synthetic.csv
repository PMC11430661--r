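child_id,age_months,score,event
child-A-synthetic,3,2,
child-A-synthetic,6,3,
child-A-synthetic,9,10,cochlear implant activation (7 months)
child-A-synthetic,12,19,
child-A-synthetic,15,26,
child-A-synthetic,18,32,
child-A-synthetic,21,38,
child-A-synthetic,24,43,
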