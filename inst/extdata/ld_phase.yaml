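# Liquid-disordered phase: bare interaction constants and default
# simulation geometry for the membrane-stack Monte Carlo.
interaction:
  A: 1.9953e+08      # hydration amplitude, Pa (10^8.3)
  lam: 1.37          # hydration decay length, A
  H: 4.08            # Hamaker coefficient, zJ
simulation:
  K_c: 44            # bending rigidity, zJ
  P: 0               # osmotic pressure, Pa
  N: 12
  M: 8
  L: 700
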