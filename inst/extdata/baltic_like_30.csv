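prey,predator
sp01,sp11
sp01,sp18
sp01,sp20
sp01,sp29
sp02,sp01
sp02,sp11
sp02,sp18
sp02,sp20
sp03,sp01
sp03,sp06
sp03,sp08
sp03,sp09
sp03,sp11
sp03,sp16
sp03,sp20
sp03,sp21
sp03,sp24
sp04,sp01
sp04,sp08
sp04,sp11
sp04,sp16
sp04,sp18
sp04,sp20
sp04,sp21
sp04,sp29
sp05,sp01
sp05,sp06
sp05,sp08
sp05,sp09
sp05,sp11
sp05,sp16
sp05,sp20
sp05,sp21
sp05,sp24
sp06,sp01
sp06,sp08
sp06,sp09
sp06,sp11
sp06,sp16
sp06,sp20
sp06,sp21
sp06,sp24
sp06,sp29
sp07,sp02
sp08,sp01
sp08,sp11
sp08,sp16
sp08,sp18
sp08,sp20
sp08,sp21
sp08,sp29
sp09,sp01
sp09,sp06
sp09,sp08
sp09,sp11
sp09,sp16
sp09,sp20
sp09,sp21
sp09,sp24
sp09,sp29
sp10,sp02
sp10,sp26
sp11,sp01
sp11,sp16
sp11,sp18
sp11,sp20
sp11,sp29
sp11,sp30
sp12,sp01
sp12,sp11
sp12,sp16
sp12,sp18
sp12,sp20
sp12,sp29
sp13,sp02
sp13,sp26
sp14,sp02
sp14,sp13
sp15,sp02
sp15,sp04
sp15,sp22
sp16,sp01
sp16,sp06
sp16,sp08
sp16,sp11
sp16,sp20
sp16,sp21
sp16,sp24
sp16,sp29
sp17,sp02
sp17,sp04
sp17,sp21
sp17,sp22
sp18,sp25
sp19,sp01
sp19,sp02
sp19,sp03
sp19,sp08
sp19,sp09
sp19,sp11
sp19,sp16
sp19,sp20
sp19,sp21
sp19,sp23
sp19,sp24
sp20,sp01
sp20,sp11
sp20,sp18
sp20,sp29
sp21,sp01
sp21,sp06
sp21,sp08
sp21,sp09
sp21,sp11
sp21,sp16
sp21,sp20
sp21,sp24
sp21,sp29
sp22,sp01
sp22,sp02
sp22,sp03
sp22,sp05
sp22,sp08
sp22,sp11
sp22,sp16
sp22,sp19
sp22,sp20
sp22,sp21
sp22,sp23
sp23,sp01
sp23,sp03
sp23,sp08
sp23,sp09
sp23,sp11
sp23,sp16
sp23,sp20
sp23,sp21
sp23,sp24
sp24,sp01
sp24,sp06
sp24,sp08
sp24,sp09
sp24,sp11
sp24,sp16
sp24,sp20
sp24,sp21
sp24,sp29
sp26,sp01
sp26,sp03
sp26,sp08
sp26,sp09
sp26,sp11
sp26,sp16
sp26,sp19
sp26,sp20
sp26,sp21
sp26,sp24
sp27,sp01
sp27,sp11
sp27,sp18
sp27,sp20
sp28,sp01
sp28,sp02
sp28,sp03
sp28,sp05
sp28,sp11
sp28,sp16
sp28,sp19
sp28,sp20
sp28,sp21
sp28,sp23
sp29,sp01
sp29,sp11
sp29,sp18
sp29,sp25
sp30,sp01
sp30,sp11
sp30,sp18
sp30,sp20
sp30,sp29
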