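- parameter: X1
  sign: positive
  value_code: 3.0
  exponent: 5.0
- parameter: X2
  sign: positive
  value_code: 3.0
  exponent: 5.0
- parameter: X3
  sign: positive
  value_code: 3.0
  exponent: 4.0
- parameter: X4
  sign: positive
  value_code: 2.0
  exponent: 3.0
- parameter: X5
  sign: positive
  value_code: 2.0
  exponent: 2.0
- parameter: X6
  sign: positive
  value_code: 1.0
  exponent: 1.0
- parameter: X7
  sign: positive
  value_code: 1.0
  exponent: 1.0
- parameter: X8
  sign: positive
  value_code: 1.0
  exponent: 1.0
- parameter: X9
  sign: positive
  value_code: 1.0
  exponent: 1.0
- parameter: X10
  sign: positive
  value_code: 1.0
  exponent: 1.0
- parameter: Y1
  sign: negative
  value_code: 3.0
  exponent: 10.0
- parameter: Y2
  sign: negative
  value_code: 3.0
  exponent: 9.0
- parameter: Y3
  sign: negative
  value_code: 3.0
  exponent: 9.0
- parameter: Y4
  sign: negative
  value_code: 2.0
  exponent: 8.0
- parameter: Y5
  sign: negative
  value_code: 2.0
  exponent: 8.0
- parameter: Y6
  sign: negative
  value_code: 1.0
  exponent: 7.0
- parameter: Y7
  sign: negative
  value_code: 3.0
  exponent: 6.0
- parameter: Y8
  sign: negative
  value_code: 2.0
  exponent: 5.0
- parameter: Y9
  sign: negative
  value_code: 1.0
  exponent: 4.0
- parameter: Y10
  sign: negative
  value_code: 2.0
  exponent: 3.0
- parameter: Y11
  sign: negative
  value_code: 2.0
  exponent: 3.0
- parameter: Y12
  sign: negative
  value_code: 2.0
  exponent: 3.0
- parameter: Y13
  sign: negative
  value_code: 2.0
  exponent: 3.0
- parameter: Y14
  sign: negative
  value_code: 1.0
  exponent: 2.0
- parameter: Y15
  sign: negative
  value_code: 1.0
  exponent: 1.0
- parameter: Y16
  sign: negative
  value_code: 1.0
  exponent: 0.0
- parameter: Y17
  sign: negative
  value_code: 1.0
  exponent: 0.0
- parameter: Y18
  sign: negative
  value_code: 1.0
  exponent: 0.0
- parameter: Y19
  sign: negative
  value_code: 1.0
  exponent: 0.0
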