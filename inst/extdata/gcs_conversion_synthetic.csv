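missing,eye,verbal,motor
verbal,1,1,1
verbal,1,2,2
verbal,1,2,3
verbal,1,2,4
verbal,1,3,5
verbal,1,4,6
verbal,2,2,1
verbal,2,2,2
verbal,2,2,3
verbal,2,3,4
verbal,2,4,5
verbal,2,4,6
verbal,3,2,1
verbal,3,2,2
verbal,3,3,3
verbal,3,4,4
verbal,3,4,5
verbal,3,4,6
verbal,4,2,1
verbal,4,3,2
verbal,4,4,3
verbal,4,4,4
verbal,4,4,5
verbal,4,5,6
motor,1,1,1
motor,1,2,2
motor,1,3,3
motor,1,4,3
motor,1,5,4
motor,2,1,2
motor,2,2,3
motor,2,3,3
motor,2,4,4
motor,2,5,5
motor,3,1,3
motor,3,2,3
motor,3,3,4
motor,3,4,5
motor,3,5,5
motor,4,1,3
motor,4,2,4
motor,4,3,5
motor,4,4,5
motor,4,5,6
eye,1,1,1
eye,1,2,1
eye,1,3,1
eye,2,4,1
eye,2,5,1
eye,1,1,2
eye,1,2,2
eye,2,3,2
eye,2,4,2
eye,3,5,2
eye,1,1,3
eye,2,2,3
eye,2,3,3
eye,3,4,3
eye,3,5,3
eye,2,1,4
eye,2,2,4
eye,3,3,4
eye,3,4,4
eye,3,5,4
eye,2,1,5
eye,3,2,5
eye,3,3,5
eye,3,4,5
eye,4,5,5
eye,3,1,6
eye,3,2,6
eye,3,3,6
eye,4,4,6
eye,4,5,6
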