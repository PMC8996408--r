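{
  "version": "1.0",
  "changelog": [
    "1.0: initial transcription of the eight published GEP equations; tokens F1/F3/F4/F6/F8/F9 in three equations kept literal and flagged"
  ],
  "notes": "Each equation is the sum of its four bracketed gene terms. Division is protected (x/0 -> 1); '^' is protected power (negative base with non-integer exponent uses the absolute base); sin/cos in radians. Tokens F1..F9 are undefined in the source and are flagged; an opt-in policy substitutes Fk -> Xk.",
  "equations": [
    {
      "genotype": "Chandler",
      "response": "PR",
      "flags": [],
      "terms": [
        "X3 - ((cos((X8/X1) * 6.178))^3 * X5 * X6)",
        "X6 + (8.010 - ((cos(X4) * 0.989) / cos(X8 + X3)))",
        "-3.539 - sin(((5.549 + X1) * (-0.883) * X4) + (X7 - X9 + (X2 - 3.579)))",
        "X4 + (X7 - cos(((X2 * X1) * (-8.741) * X7) * X1 * X5))"
      ]
    },
    {
      "genotype": "Chandler",
      "response": "CW",
      "flags": [],
      "terms": [
        "4.719 * (X1 / ((5.715)^X1 - (X8^4.879 + 6.250/X8)))",
        "cos(-4.432 - ((X9 - X3 - 0.208) * ((X5^X5) * 10.590)))",
        "((7.082 - 6.718*X4) / ((X6 - 6.287)^3)) * (X3 - X7*X4)",
        "(cos(X9 - (cos((4.957 - X2) - cos(X4)))^4))^2"
      ]
    },
    {
      "genotype": "Chandler",
      "response": "STN",
      "flags": [],
      "terms": [
        "-5.448 * sin(X7 * (X7 + ((X5 + 5.490) * (X1*X4))))",
        "7.232 * (3.087 - ((sin(X2 - X6))^2 * sin(X5 - 3.272)))",
        "(X7 * (X7 - X3 + X2)) * (X8 + sin(3.793*X9))",
        "X6 * (X9 + (X8 + (X7 * (X8^2 - 6.451))))"
      ]
    },
    {
      "genotype": "Chandler",
      "response": "Vit",
      "flags": ["F8", "F9"],
      "terms": [
        "sin(X6 - (X2 * (1.392*(X1^(F8^3)) + 1.334*X9)))",
        "sin(X1) + X1 + X1^3 + ((X9/X7) * 2*X8)",
        "cos((2*X1 + X2) * (X1 + X4 - X3^3))",
        "X5^(F9^(((6.882 - X5)/(X2 + X5)) * sin(X7^X1)))"
      ]
    },
    {
      "genotype": "Rayen",
      "response": "PR",
      "flags": [],
      "terms": [
        "(sin(cos((X2^3) * ((X4 + X6) * (-2.567/X9)))))^9",
        "X1 + (sin((cos(X3*X1)) - (sin(X3^X9))) + 3.955)",
        "(X6 * (sin(X5) / (sin(X7) + X5^X9))) + X3",
        "sin(X5 * (X8^39.898)) - 0.108*X7"
      ]
    },
    {
      "genotype": "Rayen",
      "response": "CW",
      "flags": [],
      "terms": [
        "sin(sin((((X9/X6) + 1.351*X7) - (cos(X5)/(-2.359))) ) / (-1.721))",
        "sin(cos(((sin(X7) + 0.566)^2)^((X6^3) * (X3/(-7.132)))))",
        "(cos(0.089 + (cos(X6/(X4 - 3.919)))))^X2",
        "sin((X1 - X5 + 0.282) * (cos(X1)/(-1.095 - X8)))"
      ]
    },
    {
      "genotype": "Rayen",
      "response": "STN",
      "flags": ["F1"],
      "terms": [
        "6.002 * ((cos((3.862*X3 + X9 - X1) * (sin(X7)))) - X4)",
        "(X2 * (X3 + cos(X2 * (X8 - X8 + 3.742))))^2",
        "(((X9 - 4.711)^2) - (X6 * X4 * X1)) + 45.170",
        "cos(F1) / ((X5 - 1.460) - (cos(X2) * (X2^X1)))"
      ]
    },
    {
      "genotype": "Rayen",
      "response": "Vit",
      "flags": ["F1", "F3", "F4", "F6"],
      "terms": [
        "X4 / sin(F1 * (9.069 + F4*F6 - F4*F3))",
        "X2 + ((X1^3) - (((X8 + X5)^(-2.497*X9)) + X1))",
        "8.504 + ((X7^X7) * (((X9^(-1.651)) - X6) * (X3 - X6)))",
        "(X8 * (sin(X2 - X6) * (X9 * (X2 - X5)))) / sin(X7)"
      ]
    }
  ]
}
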