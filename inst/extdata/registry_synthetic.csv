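name,formula,class,notes
npar-like#1,C26H38N4O12,NPAR,synthetic stand-in formula for a nucleoside-bearing paratoside
npar-like#2,C25H36N4O12,NPAR,synthetic stand-in formula
pasc-like#9,C20H33NO9,PASC,synthetic stand-in formula for an amino-acid-bearing ascaroside
pasc-like#1,C22H37NO9,PASC,synthetic stand-in formula
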